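#' Construct a ligand-dependent gating scheme
#'
#' A gating scheme is a continuous-time Markov model of a single channel whose
#' states belong to one of two conductance classes (`"closed"` or `"open"`) and
#' whose transition rates may be proportional to the concentration of a single
#' activating ligand (here PIP2). Each transition carries a rate coefficient
#' and a ligand order: the effective rate at ligand concentration `L` (uM) is
#' `coefficient * L^ligand_order`, so order-0 rates are concentration
#' independent (per ms) and order-1 rates are pseudo-first-order
#' (per ms per uM).
#'
#' @param states A data frame with columns `label` (character, unique) and
#'   `class` (`"closed"` or `"open"`). At least one state of each class is
#'   required.
#' @param transitions A data frame with columns `from`, `to` (state labels),
#'   `coefficient` (non-negative rate coefficient) and `ligand_order`
#'   (0 or 1). Self-transitions are not allowed and the transition graph must
#'   be connected.
#'
#' @return An object of class `gating_scheme`: a list with tibbles `states`
#'   and `transitions`.
#' @seealso [co_scheme()], [coo_scheme()] for the two schemes used throughout,
#'   [generator_matrix()], [open_probability()], [sojourn_means()].
#' @export
#' @examples
#' s <- gating_scheme(
#'   states = data.frame(label = c("C", "O"), class = c("closed", "open")),
#'   transitions = data.frame(
#'     from = c("C", "O"), to = c("O", "C"),
#'     coefficient = c(0.001, 0.01), ligand_order = c(1, 0)
#'   )
#' )
#' open_probability(s, L = 20)
gating_scheme <- function(states, transitions) {
  states <- tibble::as_tibble(states)
  transitions <- tibble::as_tibble(transitions)

  stopifnot(all(c("label", "class") %in% names(states)))
  stopifnot(all(c("from", "to", "coefficient", "ligand_order") %in%
                  names(transitions)))
  states$label <- as.character(states$label)
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)

  if (anyDuplicated(states$label)) {
    rlang::abort("state labels must be unique")
  }
  if (!all(states$class %in% c("closed", "open"))) {
    rlang::abort("state class must be 'closed' or 'open'")
  }
  if (!any(states$class == "closed") || !any(states$class == "open")) {
    rlang::abort("scheme needs at least one closed and one open state")
  }
  if (!all(transitions$from %in% states$label) ||
      !all(transitions$to %in% states$label)) {
    rlang::abort("transition endpoints must be state labels")
  }
  if (any(transitions$from == transitions$to)) {
    rlang::abort("self-transitions are not allowed")
  }
  if (any(!is.finite(transitions$coefficient)) ||
      any(transitions$coefficient < 0)) {
    rlang::abort("rate coefficients must be finite and >= 0")
  }
  if (!all(transitions$ligand_order %in% c(0L, 1L))) {
    rlang::abort("ligand_order must be 0 or 1")
  }
  if (anyDuplicated(transitions[, c("from", "to")])) {
    rlang::abort("duplicate transitions for the same state pair")
  }

  scheme <- structure(
    list(states = states, transitions = transitions),
    class = "gating_scheme"
  )
  if (!scheme_connected(scheme)) {
    rlang::abort("transition graph must be connected")
  }
  scheme
}

# undirected connectivity over the listed transitions
scheme_connected <- function(scheme) {
  labels <- scheme$states$label
  n <- length(labels)
  if (n == 1L) return(TRUE)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(nrow(scheme$transitions))) {
    a <- scheme$transitions$from[i]
    b <- scheme$transitions$to[i]
    adj[a, b] <- TRUE
    adj[b, a] <- TRUE
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    nxt <- which(adj[i, ] & !seen)
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

#' Two-state ligand-gated scheme (closed-open)
#'
#' The simplest model of channel activation by PIP2: a pseudo-first-order
#' opening step whose rate is proportional to ligand concentration, and a
#' concentration-independent closing step.
#'
#' \deqn{C \underset{k_{-1}}{\overset{k_1 [L]}{\rightleftharpoons}} O}
#'
#' Under this scheme the mean open time `1/k_-1` does not depend on ligand
#' concentration, and the equilibrium dose-response has Hill coefficient 1.
#'
#' @param k1 Opening rate coefficient, per ms per uM (ligand order 1).
#' @param k_1 Closing rate, per ms (ligand order 0).
#' @return A [gating_scheme()] with states `C` and `O`.
#' @export
#' @examples
#' sojourn_means(co_scheme(0.001, 0.01), L = 20)
co_scheme <- function(k1, k_1) {
  if (!is.numeric(k1) || length(k1) != 1L || !is.finite(k1) || k1 <= 0 ||
      !is.numeric(k_1) || length(k_1) != 1L || !is.finite(k_1) || k_1 <= 0) {
    rlang::abort("k1 and k_1 must be single positive numbers")
  }
  gating_scheme(
    states = tibble::tibble(label = c("C", "O"),
                            class = c("closed", "open")),
    transitions = tibble::tibble(
      from = c("C", "O"), to = c("O", "C"),
      coefficient = c(k1, k_1), ligand_order = c(1L, 0L)
    )
  )
}

#' Three-state scheme with two sequential ligand-binding steps
#'
#' A linear chain `C = O1 = O2` in which binding of the first PIP2 opens the
#' channel and binding of a second stabilizes the open conformation. Both
#' forward rates are proportional to ligand concentration; both backward
#' rates are concentration independent:
#'
#' \deqn{C \underset{k_{-1}}{\overset{k_1 [L]}{\rightleftharpoons}} O_1
#'       \underset{k_{-2}}{\overset{k_2 [L]}{\rightleftharpoons}} O_2}
#'
#' Because the open class aggregates two states, the open dwell-time density
#' is a two-exponential mixture and the mean open time grows linearly with
#' ligand concentration, `1/k_-1 + (k2/(k_-2 k_-1)) L`, while the mean closed
#' time is `1/(k1 L)`. The equilibrium dose-response is steeper than the
#' two-state scheme but its local Hill slope is bounded above by 2 (see
#' [hill_slope_local()]).
#'
#' @param k1,k2 Forward (binding) rate coefficients, per ms per uM.
#' @param k_1,k_2 Backward rates, per ms.
#' @return A [gating_scheme()] with states `C`, `O1`, `O2`.
#' @export
#' @examples
#' sch <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
#' open_probability(sch, L = 20) # 6/7
coo_scheme <- function(k1, k_1, k2, k_2) {
  vals <- c(k1 = k1, k_1 = k_1, k2 = k2, k_2 = k_2)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all four rate coefficients must be positive")
  }
  gating_scheme(
    states = tibble::tibble(label = c("C", "O1", "O2"),
                            class = c("closed", "open", "open")),
    transitions = tibble::tibble(
      from = c("C", "O1", "O1", "O2"),
      to = c("O1", "C", "O2", "O1"),
      coefficient = c(k1, k_1, k2, k_2),
      ligand_order = c(1L, 0L, 1L, 0L)
    )
  )
}

#' @export
print.gating_scheme <- function(x, ...) {
  n_open <- sum(x$states$class == "open")
  cat(sprintf(
    "<gating_scheme> %d states (%d closed, %d open), %d transitions\n",
    nrow(x$states), nrow(x$states) - n_open, n_open, nrow(x$transitions)
  ))
  tr <- x$transitions
  for (i in seq_len(nrow(tr))) {
    unit <- if (tr$ligand_order[i] == 1L) "/ms/uM (x [L])" else "/ms"
    cat(sprintf("  %s -> %s : %g %s\n", tr$from[i], tr$to[i],
                tr$coefficient[i], unit))
  }
  invisible(x)
}

#' Write or read a gating scheme as JSON
#'
#' Schemes serialize to a plain JSON document with a `states` array
#' (`label`, `class`) and a `transitions` array (`from`, `to`, `coefficient`,
#' `ligand_order`), so model definitions can be stored alongside results.
#'
#' @param scheme A [gating_scheme()].
#' @param path File path.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()` returns
#'   a `gating_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "gating_scheme"))
  jsonlite::write_json(
    list(states = scheme$states, transitions = scheme$transitions),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  gating_scheme(doc$states, doc$transitions)
}
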