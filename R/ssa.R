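## Convert a graph's adjacency tables to the 0-based form the C++ core takes.
engine_inputs <- function(graph) {
  adj <- graph_adjacency(graph)
  ii <- adj$inter_idx - 1L
  ii[is.na(ii)] <- -1L
  list(intra_prev = adj$prev - 1L, intra_next = adj$nxt - 1L,
       inter_idx = ii, inter_w = adj$inter_w,
       channel_of = adj$channel_of - 1L)
}

run_core <- function(graph, params, t_stop, seed, event_cap,
                     stop_at_threshold, record, paranoid = FALSE) {
  validate_rate_params(params)
  if (!is.numeric(t_stop) || length(t_stop) != 1L || is.na(t_stop) || t_stop < 0)
    stop("'t_stop' must be non-negative")
  ei <- engine_inputs(graph)
  if (!is.null(seed)) set.seed(seed)
  ssa_core(ei$intra_prev, ei$intra_next, ei$inter_idx, ei$inter_w,
           ei$channel_of, graph$n_channels,
           params$kfo, params$kb, params$delta, params$g, params$c0,
           params$open_subunit_min, params$nc,
           t_stop, event_cap, stop_at_threshold, record, paranoid)
}

#' Waiting time to a spontaneous calcium spark
#'
#' Runs the Gillespie direct method from the all-closed state until the
#' open-channel count first reaches the spark threshold `nc` (the waiting
#' time `T`), the time horizon `t_max` is exhausted (censored run, `T` is
#' reported as the lower bound `t_max`), or the event cap is hit.
#'
#' @param graph A `coupling_graph`.
#' @param params A [rate_params()] object.
#' @param t_max Censoring horizon in ms (default 1e8).
#' @param seed Integer seed; identical seeds reproduce the run bit-for-bit.
#' @param event_cap Safety stop on the number of subunit flips (default 1e9),
#'   reported distinctly from time censoring.
#' @return An object of class `first_passage`: list with `T` (ms), `fired`,
#'   `censored`, `capped`, `absorbing`, `n_events`, `final_n_open`, `seed`,
#'   `t_max`.
#' @examples
#' g <- build_oblique(3, 3, sigma = 0.5)
#' first_passage_time(g, rate_params(c0 = 50), t_max = 1e5, seed = 1)
#' @export
first_passage_time <- function(graph, params, t_max = 1e8, seed = NULL,
                               event_cap = 1e9) {
  if (t_max <= 0) stop("'t_max' must be positive")
  out <- run_core(graph, params, t_stop = t_max, seed = seed,
                  event_cap = event_cap, stop_at_threshold = TRUE,
                  record = FALSE)
  structure(list(
    T = out$t, fired = out$fired,
    censored = out$censored || out$absorbing || out$capped,
    capped = out$capped, absorbing = out$absorbing,
    n_events = out$n_events, final_n_open = out$n_open,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    t_max = t_max
  ), class = "first_passage")
}

#' @method print first_passage
#' @export
print.first_passage <- function(x, ...) {
  if (x$fired) {
    cat(sprintf("spark at T = %g ms (%g events, seed %s)\n",
                x$T, x$n_events, x$seed))
  } else {
    why <- if (x$capped) "event cap" else if (x$absorbing) "absorbing state"
           else "time horizon"
    cat(sprintf("censored at %s: T >= %g ms (lower bound; %g events, seed %s)\n",
                why, x$T, x$n_events, x$seed))
  }
  invisible(x)
}

#' Simulate an open-channel-count trajectory
#'
#' Full Gillespie run to `t_end` with the open-channel count `n_open`
#' recorded at every change — the raw material of spark-initiation
#' diagnostics, where `n_open` fluctuates near zero until a large fluctuation
#' triggers explosive, cluster-wide activation.
#'
#' @inheritParams first_passage_time
#' @param t_end End time of the recording, ms.
#' @return A data.frame of class `ryr_trajectory` with columns `time` (ms)
#'   and `n_open`, starting at `(0, 0)`; attributes `seed`, `t_end`,
#'   `n_events`.
#' @export
simulate_trajectory <- function(graph, params, t_end, seed = NULL,
                                event_cap = 1e9) {
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end < 0)
    stop("'t_end' must be non-negative")
  out <- run_core(graph, params, t_stop = t_end, seed = seed,
                  event_cap = event_cap, stop_at_threshold = FALSE,
                  record = TRUE)
  tr <- data.frame(time = out$traj_t, n_open = out$traj_n)
  structure(tr, class = c("ryr_trajectory", "data.frame"),
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
            t_end = t_end, n_events = out$n_events)
}

#' One Gillespie step (reference implementation)
#'
#' Draws a single event from the current state: the waiting increment
#' `dt ~ Exponential(total rate)` and a subunit chosen with probability
#' proportional to its flip rate. This pure-R step recomputes every rate from
#' scratch and consumes the RNG exactly as the compiled engine does (one
#' uniform for the time, one for the selection), so it doubles as an
#' independent cross-check of the engine's incremental bookkeeping.
#'
#' @inheritParams channel_open_flags
#' @return List with `k` (flat subunit index flipped, or `NA` if the state is
#'   absorbing), `dt` (ms, `Inf` if absorbing), `state` (the updated state),
#'   `total_rate`.
#' @export
ssa_step <- function(state, graph, params) {
  sr <- subunit_rates(state, graph, params)
  r_open <- params$kfo * sr$ca * sum(sr$gamma[sr$opening])
  r_close <- params$kb * sum(1 / sr$gamma[!sr$opening])
  r_tot <- r_open + r_close
  if (r_tot <= 0)
    return(list(k = NA_integer_, dt = Inf, state = state, total_rate = 0))
  dt <- -log(stats::runif(1)) / r_tot
  u <- stats::runif(1) * r_tot
  if (u < r_open) {
    pool <- which(sr$opening)
    acc <- cumsum(sr$gamma[pool])
    k <- pool[which(acc >= u / (params$kfo * sr$ca))[1L]]
    if (is.na(k)) k <- pool[length(pool)]
  } else {
    pool <- which(!sr$opening)
    acc <- cumsum(1 / sr$gamma[pool])
    k <- pool[which(acc >= (u - r_open) / params$kb)[1L]]
    if (is.na(k)) k <- pool[length(pool)]
  }
  state[k] <- -state[k]
  list(k = k, dt = dt, state = state, total_rate = r_tot)
}

## Pure-R first-passage engine: same draw structure as ssa_core, rates
## recomputed from scratch each event. Used in tests as the slow reference.
fpt_reference <- function(graph, params, t_max, seed, max_events = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  state <- new_cluster_state(graph)
  t <- 0
  n_events <- 0
  times <- numeric(0)
  ks <- integer(0)
  repeat {
    step <- ssa_step(state, graph, params)
    if (!is.finite(step$dt))
      return(list(T = t, fired = FALSE, censored = TRUE,
                  n_events = n_events, times = times, ks = ks))
    t <- t + step$dt
    if (t >= t_max)
      return(list(T = t_max, fired = FALSE, censored = TRUE,
                  n_events = n_events, times = times, ks = ks))
    state <- step$state
    n_events <- n_events + 1
    times <- c(times, t)
    ks <- c(ks, step$k)
    n_open <- channel_open_flags(state, graph, params)$n_open
    if (n_open >= params$nc)
      return(list(T = t, fired = TRUE, censored = FALSE,
                  n_events = n_events, times = times, ks = ks))
    if (n_events >= max_events)
      return(list(T = t, fired = FALSE, censored = TRUE,
                  n_events = n_events, times = times, ks = ks))
  }
}
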