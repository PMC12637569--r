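# Small graphs used across the suite; everything is built in code.

tetramer <- function(sigma = 0.5) build_oblique(1, 1, sigma = sigma)

# 1 x n row of channels
channel_row <- function(n, topology = "oblique", sigma = 0.5) {
  lattice_to_graph(channel_lattice(1, n, cbind(0:(n - 1L), 0L)),
                   topology, sigma)
}

random_state <- function(graph) {
  sample(c(-1L, 1L), 4L * graph$n_channels, replace = TRUE)
}

# hand evaluation of one subunit's flip rate from the model definition
hand_rate <- function(state, graph, params, channel, subunit) {
  adj <- ryrspark:::graph_adjacency(graph)
  k <- (channel - 1L) * 4L + subunit + 1L
  inter <- 0
  for (j in 1:2) {
    b <- adj$inter_idx[k, j]
    if (!is.na(b)) inter <- inter + adj$inter_w[k, j] * state[b]
  }
  gam <- exp(params$delta * (state[adj$prev[k]] + state[adj$nxt[k]]) + inter)
  cnt <- colSums(matrix(state == 1L, nrow = 4L))
  ca <- params$c0 + params$g * sum(cnt >= params$open_subunit_min)
  if (state[k] == -1L) params$kfo * ca * gam else params$kb / gam
}
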