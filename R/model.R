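#' All-closed cluster state
#'
#' A cluster state is a plain integer vector with one entry in `{-1, +1}` per
#' subunit (4 per channel), ordered channel-major: subunit `s` of channel `c`
#' sits at flat index `(c - 1) * 4 + s + 1`, with `s` in `0:3` in ring order.
#'
#' @param graph A `coupling_graph`.
#' @return Integer vector of `-1`s, length `4 * n_channels`.
#' @export
new_cluster_state <- function(graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  rep(-1L, 4L * graph$n_channels)
}

validate_cluster_state <- function(state, graph) {
  if (length(state) != 4L * graph$n_channels)
    stop("state length must be 4 * n_channels")
  if (!all(state %in% c(-1L, 1L))) stop("subunit states must be -1 or +1")
  invisible(state)
}

subunit_index <- function(graph, channel, subunit) {
  if (length(channel) != 1L || is.na(channel) ||
      channel < 1L || channel > graph$n_channels)
    stop("unknown channel address")
  if (length(subunit) != 1L || is.na(subunit) || !(subunit %in% 0:3))
    stop("unknown subunit address (must be 0..3)")
  (as.integer(channel) - 1L) * 4L + as.integer(subunit) + 1L
}

## Per-subunit neighbour tables (flat 1-based indices; NA = missing contact).
## Intra neighbours are the ring positions (s-1, s+1) mod 4; inter neighbours
## come from the graph's edge list, at most 2 per subunit.
graph_adjacency <- function(graph) {
  n <- 4L * graph$n_channels
  s <- rep(0:3, graph$n_channels)
  base <- rep((seq_len(graph$n_channels) - 1L) * 4L, each = 4L)
  prev <- base + (s + 3L) %% 4L + 1L
  nxt <- base + (s + 1L) %% 4L + 1L
  inter_idx <- matrix(NA_integer_, n, 2L)
  inter_w <- matrix(0, n, 2L)
  e <- graph$inter_edges
  if (nrow(e) > 0) {
    a <- (e$c1 - 1L) * 4L + e$s1 + 1L
    b <- (e$c2 - 1L) * 4L + e$s2 + 1L
    slot <- integer(n)
    for (i in seq_along(a)) {
      for (end in list(c(a[i], b[i]), c(b[i], a[i]))) {
        k <- end[1L]
        slot[k] <- slot[k] + 1L
        if (slot[k] > 2L) stop("subunit has more than 2 inter-channel contacts")
        inter_idx[k, slot[k]] <- end[2L]
        inter_w[k, slot[k]] <- e$w[i]
      }
    }
  }
  list(prev = prev, nxt = nxt, inter_idx = inter_idx, inter_w = inter_w,
       channel_of = rep(seq_len(graph$n_channels), each = 4L))
}

#' Per-channel open flags and open-channel count
#'
#' A channel conducts when at least `open_subunit_min` of its four subunits
#' are open (default majority rule: 3 of 4). The count `n_open` drives the
#' dyadic calcium concentration via [local_calcium()].
#'
#' @param state Cluster state vector (see [new_cluster_state()]).
#' @param graph A `coupling_graph`.
#' @param params A [rate_params()] object.
#' @return List with `open` (logical per channel) and `n_open` (integer).
#' @export
channel_open_flags <- function(state, graph, params) {
  validate_cluster_state(state, graph)
  validate_rate_params(params)
  cnt <- colSums(matrix(state == 1L, nrow = 4L))
  open <- cnt >= params$open_subunit_min
  list(open = open, n_open = as.integer(sum(open)))
}

#' Cooperativity factor of one subunit
#'
#' `gamma_i = exp(delta * (s_prev + s_next) + sum_b w_b * s_b)`: the two ring
#' neighbours contribute with the intra-tetramer mismatch penalty `delta`,
#' and the subunit's surviving inter-channel contacts (0, 1 or 2 of them)
#' contribute with their edge weight `sigma`, an energetic coupling strength
#' on the same dimensionless (beta * J) scale as `delta`; a missing contact
#' contributes nothing. Opening rates are multiplied by `gamma`, closing
#' rates divided by it, so conformational mismatch with neighbours is
#' penalised symmetrically and detailed balance is preserved at fixed calcium.
#'
#' @param state Cluster state vector.
#' @param graph A `coupling_graph`.
#' @param params A [rate_params()] object (supplies `delta`).
#' @param channel Channel index (1-based).
#' @param subunit Subunit index in `0:3` (ring order).
#' @return Positive scalar `gamma`.
#' @examples
#' g <- build_oblique(1, 1)
#' coupling_factor(new_cluster_state(g), g, rate_params(delta = 0.5), 1, 0)
#' @export
coupling_factor <- function(state, graph, params, channel, subunit) {
  validate_cluster_state(state, graph)
  validate_rate_params(params)
  k <- subunit_index(graph, channel, subunit)
  adj <- graph_adjacency(graph)
  inter <- 0
  for (j in 1:2) {
    b <- adj$inter_idx[k, j]
    if (!is.na(b)) inter <- inter + adj$inter_w[k, j] * state[b]
  }
  exp(params$delta * (state[adj$prev[k]] + state[adj$nxt[k]]) + inter)
}

#' Transition rate of one subunit
#'
#' A closed subunit opens at `kfo * Ca * gamma_i` with `Ca` the current dyadic
#' calcium (recomputed from the global open-channel count, including the
#' subunit's own channel); an open subunit closes at `kb / gamma_i`.
#'
#' @inheritParams coupling_factor
#' @return Rate in 1/ms.
#' @export
transition_rate <- function(state, graph, params, channel, subunit) {
  k <- subunit_index(graph, channel, subunit)
  gam <- coupling_factor(state, graph, params, channel, subunit)
  n_open <- channel_open_flags(state, graph, params)$n_open
  ca <- local_calcium(n_open, params)
  if (state[k] == -1L) params$kfo * ca * gam else params$kb / gam
}

#' All per-subunit transition rates at once
#'
#' Vectorised evaluation used by the stochastic engine's reference
#' implementation and by bookkeeping checks: returns every subunit's current
#' flip rate together with its cooperativity factor.
#'
#' @inheritParams channel_open_flags
#' @return List with `rates`, `gamma`, `opening` (logical: TRUE where the flip
#'   would open the subunit), `n_open`, and `ca` (uM).
#' @export
subunit_rates <- function(state, graph, params) {
  validate_cluster_state(state, graph)
  validate_rate_params(params)
  adj <- graph_adjacency(graph)
  inter <- numeric(length(state))
  for (j in 1:2) {
    has <- !is.na(adj$inter_idx[, j])
    inter[has] <- inter[has] +
      adj$inter_w[has, j] * state[adj$inter_idx[has, j]]
  }
  gam <- exp(params$delta * (state[adj$prev] + state[adj$nxt]) + inter)
  n_open <- channel_open_flags(state, graph, params)$n_open
  ca <- local_calcium(n_open, params)
  closed <- state == -1L
  rates <- ifelse(closed, params$kfo * ca * gam, params$kb / gam)
  list(rates = rates, gamma = gam, opening = closed,
       n_open = n_open, ca = ca)
}
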