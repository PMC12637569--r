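## Brute-force master-equation machinery for small clusters. States are
## indexed 0 .. 2^(4M)-1; bit k (0-based, channel-major subunit order) set
## means subunit k is open (+1), clear means closed (-1).

oracle_max_channels <- 3L  # 4096 states; the single-flip hypercube fills in badly beyond this

#' Enumerate the state space of a small cluster
#'
#' @param graph A `coupling_graph` with at most 3 channels.
#' @return List with `n_channels`, `n_subunits`, `n_states`, and `bits`, an
#'   `n_states x n_subunits` 0/1 matrix (bit k of the state index = subunit k
#'   open).
#' @export
state_space <- function(graph) {
  stopifnot(inherits(graph, "coupling_graph"))
  m <- graph$n_channels
  if (m > oracle_max_channels)
    stop(sprintf("state space too large: %d channels (max %d)",
                 m, oracle_max_channels))
  n_sub <- 4L * m
  states <- 0:(2L^n_sub - 1L)
  bits <- vapply(seq_len(n_sub) - 1L,
                 function(k) bitwAnd(bitwShiftR(states, k), 1L),
                 integer(length(states)))
  list(n_channels = m, n_subunits = n_sub, n_states = length(states),
       bits = bits)
}

oracle_pieces <- function(graph, params) {
  validate_rate_params(params)
  ss <- state_space(graph)
  adj <- graph_adjacency(graph)
  s <- 2L * ss$bits - 1L                       # n_states x n_sub, entries +/-1
  cnt <- matrix(0L, ss$n_states, graph$n_channels)
  for (c in seq_len(graph$n_channels))
    cnt[, c] <- rowSums(ss$bits[, (c - 1L) * 4L + 1:4, drop = FALSE])
  n_open <- rowSums(cnt >= params$open_subunit_min)
  ca <- params$c0 + params$g * n_open
  expo <- matrix(0, ss$n_states, ss$n_subunits)
  for (k in seq_len(ss$n_subunits)) {
    e <- params$delta * (s[, adj$prev[k]] + s[, adj$nxt[k]])
    for (j in 1:2) {
      b <- adj$inter_idx[k, j]
      if (!is.na(b)) e <- e + adj$inter_w[k, j] * s[, b]
    }
    expo[, k] <- e
  }
  list(ss = ss, s = s, n_open = n_open, ca = ca, expo = expo)
}

#' Exact generator matrix of a small cluster
#'
#' Assembles the full continuous-time Markov generator over all `2^(4M)`
#' subunit configurations: off-diagonal entries are the single-flip rates
#' (with calcium feedback evaluated in the source state), rows sum to zero.
#'
#' @param graph A `coupling_graph` with at most 3 channels.
#' @param params A [rate_params()] object.
#' @return A sparse `dgCMatrix` of size `2^(4M) x 2^(4M)`.
#' @export
generator_matrix <- function(graph, params) {
  op <- oracle_pieces(graph, params)
  n <- op$ss$n_states
  states <- 0:(n - 1L)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (k in seq_len(op$ss$n_subunits)) {
    closed <- op$s[, k] == -1L
    rate <- ifelse(closed,
                   params$kfo * op$ca * exp(op$expo[, k]),
                   params$kb * exp(-op$expo[, k]))
    target <- bitwXor(states, bitwShiftL(1L, k - 1L))
    ii <- c(ii, states + 1L)
    jj <- c(jj, target + 1L)
    xx <- c(xx, rate)
  }
  q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::Diagonal(n, -Matrix::rowSums(q)) + q
}

#' Stationary distribution of a small cluster
#'
#' Left null vector of the generator, normalised to a probability vector.
#' With `g = 0` (no calcium feedback) the chain is reversible and this equals
#' the Boltzmann distribution of [boltzmann_weights()]; with `g > 0` the
#' chain is irreversible but the stationary solve still applies.
#'
#' @param graph A `coupling_graph` with at most 3 channels (dense solve).
#' @param params A [rate_params()] object with `kfo * c0 > 0` (irreducible).
#' @return Probability vector over the `2^(4M)` states.
#' @export
stationary_distribution <- function(graph, params) {
  if (graph$n_channels > 3L)
    stop("stationary solve limited to 3 channels")
  if (params$kfo * params$c0 <= 0)
    stop("chain is reducible when kfo * c0 = 0")
  q <- as.matrix(generator_matrix(graph, params))
  n <- nrow(q)
  a <- t(q)
  a[n, ] <- 1
  pi <- solve(a, c(rep(0, n - 1L), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("stationary solve produced negative probabilities")
  pi / sum(pi)
}

#' Boltzmann weights of the zero-feedback chain
#'
#' With `g = 0` every single-subunit flip satisfies detailed balance against
#' the energy `E(s) = -(delta * sum_ring s s' + sum_inter w s s' + h * sum s)`
#' with field `h = 0.5 * log(kfo * c0 / kb)`, so the stationary distribution
#' is proportional to `exp(-E)`.
#'
#' @inheritParams generator_matrix
#' @return Unnormalised weight per state (same indexing as [state_space()]).
#' @export
boltzmann_weights <- function(graph, params) {
  if (params$g != 0) stop("Boltzmann form requires g = 0 (fixed calcium)")
  if (params$kfo * params$c0 <= 0) stop("requires kfo * c0 > 0")
  op <- oracle_pieces(graph, params)
  adj <- graph_adjacency(graph)
  h <- 0.5 * log(params$kfo * params$c0 / params$kb)
  n <- op$ss$n_states
  energy_term <- numeric(n)
  for (k in seq_len(op$ss$n_subunits)) {
    # each intra ring edge counted twice across subunits -> halve
    energy_term <- energy_term + 0.5 * params$delta * op$s[, k] *
      (op$s[, adj$prev[k]] + op$s[, adj$nxt[k]])
  }
  e <- graph$inter_edges
  if (nrow(e) > 0) {
    a <- (e$c1 - 1L) * 4L + e$s1 + 1L
    b <- (e$c2 - 1L) * 4L + e$s2 + 1L
    for (i in seq_len(nrow(e)))
      energy_term <- energy_term + e$w[i] * op$s[, a[i]] * op$s[, b[i]]
  }
  exp(energy_term + h * rowSums(op$s))
}

#' Exact mean first-passage time to the spark threshold
#'
#' Solves the linear hitting-time system `Q_tt %*% tau = -1` over the
#' transient states (those with fewer than `nc` open channels) and returns
#' the expected time from the all-closed state. This is the deterministic
#' ground truth the Gillespie engine is validated against.
#'
#' @param graph A `coupling_graph` with at most 3 channels.
#' @param params A [rate_params()] object.
#' @param nc Spark threshold on the open-channel count (default from
#'   `params`).
#' @return Expected hitting time in ms (0 if the start state is absorbing).
#' @export
mfpt_exact <- function(graph, params, nc = params$nc) {
  op <- oracle_pieces(graph, params)
  absorbing <- op$n_open >= nc
  if (!any(absorbing)) stop("absorbing set empty: no state reaches nc")
  if (all(absorbing)) stop("absorbing set is the whole state space")
  if (absorbing[1L]) return(0)       # state 1 = all closed
  q <- generator_matrix(graph, params)
  tr <- which(!absorbing)
  qtt <- q[tr, tr, drop = FALSE]
  tau <- Matrix::solve(qtt, rep(-1, length(tr)))
  as.numeric(tau[match(1L, tr)])
}
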