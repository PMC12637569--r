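## Fixed seed-splitting rule: gating and morphology randomness get separate,
## recorded streams derived from one master seed, so any run of any ensemble
## can be regenerated exactly from the CSV/JSON metadata.
derive_seeds <- function(master_seed, n_runs, stream = c("gating", "graph")) {
  stream <- match.arg(stream)
  off <- if (stream == "gating") 1000003 else 2000003
  as.integer((as.numeric(master_seed) + off * seq_len(n_runs)) %% 2147483647)
}

#' Ensemble mean waiting time to a spontaneous spark
#'
#' Runs [first_passage_time()] `n_runs` times and reports the ensemble mean
#' and an error estimate computed as the standard deviation of the means of
#' `n_sets` equal subsets (default 5 sets of `n_runs / 5` runs). Censored
#' runs enter the mean at their lower bound `t_max` and are counted, so a
#' censor-contaminated mean is itself a lower bound.
#'
#' @param graph A `coupling_graph`, or a generator `function(seed)` returning
#'   a fresh `coupling_graph` per run (used for bond-dilution and
#'   preferential-attachment ensembles, where morphology is part of the
#'   randomness).
#' @param params A [rate_params()] object.
#' @param n_runs Number of independent runs (must be divisible by `n_sets`).
#' @param master_seed Integer master seed; per-run gating and morphology
#'   seeds are derived by a fixed splitting rule and recorded.
#' @param t_max Censoring horizon per run, ms.
#' @param n_sets Number of subsets for the error estimate.
#' @param event_cap Per-run event safety stop.
#' @param runner Engine function with the signature of
#'   [first_passage_time()]; replaceable by a stub for estimator checks.
#' @return Object of class `spark_ensemble`: list with `mean_T`, `se_T`,
#'   `times`, `censored`, `n_runs`, `n_censored`, `seeds`, `graph_seeds`,
#'   `lower_bound` (TRUE when any run was censored), `t_max`, `master_seed`.
#' @export
mean_waiting_time <- function(graph, params, n_runs = 50L, master_seed = 1L,
                              t_max = 1e8, n_sets = 5L, event_cap = 1e9,
                              runner = first_passage_time) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("'n_runs' must be positive")
  if (n_runs %% n_sets != 0L)
    stop(sprintf("'n_runs' (%d) must be divisible into %d sets", n_runs, n_sets))
  seeds <- derive_seeds(master_seed, n_runs, "gating")
  graph_seeds <- if (is.function(graph))
    derive_seeds(master_seed, n_runs, "graph") else rep(NA_integer_, n_runs)

  times <- numeric(n_runs)
  cens <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    g_i <- if (is.function(graph)) graph(graph_seeds[i]) else graph
    fp <- runner(g_i, params, t_max = t_max, seed = seeds[i],
                 event_cap = event_cap)
    times[i] <- fp$T
    cens[i] <- fp$censored
  }
  if (all(cens))
    stop(sprintf(
      "all %d runs censored at t_max = %g ms: mean waiting time > %g ms",
      n_runs, t_max, t_max))
  set_id <- rep(seq_len(n_sets), each = n_runs %/% n_sets)
  set_means <- tapply(times, set_id, mean)
  structure(list(
    mean_T = mean(times), se_T = stats::sd(set_means),
    times = times, censored = cens,
    n_runs = n_runs, n_censored = sum(cens),
    seeds = seeds, graph_seeds = graph_seeds,
    lower_bound = any(cens), t_max = t_max,
    master_seed = as.integer(master_seed), n_sets = as.integer(n_sets)
  ), class = "spark_ensemble")
}

#' @method print spark_ensemble
#' @export
print.spark_ensemble <- function(x, ...) {
  cat(sprintf("spark waiting-time ensemble: %d runs, master seed %d\n",
              x$n_runs, x$master_seed))
  cat(sprintf("  mean T = %g ms (se %g, sd of %d set means)%s\n",
              x$mean_T, x$se_T, x$n_sets,
              if (x$lower_bound)
                sprintf("; LOWER BOUND, %d run(s) censored", x$n_censored)
              else ""))
  invisible(x)
}

condition_graph <- function(base, c0 = NULL, sigma = NULL, p = NULL,
                            alpha = NULL) {
  topology <- base$topology
  sig <- if (is.null(sigma)) base$sigma else sigma
  if (!is.null(alpha)) {
    force(sig)
    function(seed) {
      lat <- grow_preferential(base$n_channels, base$rows, base$cols,
                               alpha = alpha, seed = seed)
      lattice_to_graph(lat, topology, sigma = sig)
    }
  } else {
    full <- lattice_to_graph(full_lattice(base$rows, base$cols), topology, sig)
    if (!is.null(p) && p < 1) {
      function(seed) dilute_bonds(full, p, seed = seed)
    } else if (!is.null(p)) {
      function(seed) dilute_bonds(full, 1, seed = seed)  # fresh (identity) draw per run
    } else {
      full
    }
  }
}

#' Sweep the mean spark waiting time along one parameter axis
#'
#' Repeats [mean_waiting_time()] over a grid of one of: bulk calcium `c0`,
#' inter-channel coupling `sigma`, bond-survival probability `p`, or
#' clustering parameter `alpha`. For `p` and `alpha` a fresh random graph is
#' generated per run from a recorded morphology seed stream, so the reported
#' mean averages over the morphology ensemble as well as gating noise.
#'
#' @param axis One of `"c0"`, `"sigma"`, `"p"`, `"alpha"`.
#' @param grid Numeric vector of axis values (non-empty).
#' @param base Named list describing the fixed condition: `topology`
#'   (`"adjoining"`/`"oblique"`), `rows`, `cols`, and for `alpha` sweeps
#'   `n_channels`; optional `sigma` (defaults to `params$sigma`) and `p`.
#' @param params A [rate_params()] object (its `c0`/`sigma` are overridden on
#'   the swept axis).
#' @param n_runs Runs per grid value.
#' @param master_seed Master seed; each grid value uses `master_seed + 1000 *
#'   (index - 1)` so conditions are independent but reproducible.
#' @param t_max Censoring horizon, ms.
#' @param n_sets Subsets for the error estimate.
#' @return A data.frame of class `sweep_result`, one row per grid value, with
#'   columns `topology, rows, cols, n_channels, c0_uM, sigma, p, alpha,
#'   n_runs, n_censored, mean_T_ms, se_T_ms, master_seed`; per-run times are
#'   kept in the `"ensembles"` attribute.
#' @export
sweep_waiting_time <- function(axis = c("c0", "sigma", "p", "alpha"),
                               grid, base, params, n_runs = 50L,
                               master_seed = 1L, t_max = 1e8, n_sets = 5L) {
  axis <- match.arg(axis)
  if (length(grid) < 1L) stop("'grid' must be non-empty")
  stopifnot(is.list(base), !is.null(base$topology),
            !is.null(base$rows), !is.null(base$cols))
  if (axis == "alpha" && is.null(base$n_channels))
    stop("alpha sweeps need base$n_channels")
  if (is.null(base$sigma)) base$sigma <- params$sigma

  rows_out <- vector("list", length(grid))
  ensembles <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    v <- grid[i]
    p_i <- params
    cond <- list(c0 = NULL, sigma = NULL, p = base$p, alpha = NULL)
    if (axis == "c0") p_i$c0 <- v
    if (axis == "sigma") cond$sigma <- v
    if (axis == "p") cond$p <- v
    if (axis == "alpha") cond$alpha <- v
    g <- condition_graph(base, sigma = cond$sigma, p = cond$p,
                         alpha = cond$alpha)
    ms <- as.integer(master_seed) + 1000L * (i - 1L)
    ens <- mean_waiting_time(g, p_i, n_runs = n_runs, master_seed = ms,
                             t_max = t_max, n_sets = n_sets)
    n_chan <- if (axis == "alpha") base$n_channels else base$rows * base$cols
    rows_out[[i]] <- data.frame(
      topology = base$topology, rows = base$rows, cols = base$cols,
      n_channels = n_chan, c0_uM = p_i$c0,
      sigma = if (is.null(cond$sigma)) base$sigma else cond$sigma,
      p = if (is.null(cond$p)) NA_real_ else cond$p,
      alpha = if (is.null(cond$alpha)) NA_real_ else cond$alpha,
      n_runs = ens$n_runs, n_censored = ens$n_censored,
      mean_T_ms = ens$mean_T, se_T_ms = ens$se_T, master_seed = ms)
    ensembles[[i]] <- ens
  }
  out <- do.call(rbind, rows_out)
  structure(out, class = c("sweep_result", "data.frame"),
            ensembles = ensembles, axis = axis)
}

#' Spontaneous spark frequency
#'
#' The reciprocal of the mean waiting time, per ms. If the underlying
#' ensemble contained censored runs its mean is a lower bound, so the
#' frequency is flagged (attribute `upper_bound`) as an upper bound.
#'
#' @param x A `spark_ensemble`, a `sweep_result` (vectorised over rows), or a
#'   numeric mean waiting time in ms.
#' @return Frequency per ms (numeric, possibly with `upper_bound` attribute).
#' @examples
#' spark_frequency(1000)  # 0.001 sparks/ms
#' @export
spark_frequency <- function(x) {
  if (inherits(x, "spark_ensemble")) {
    f <- 1 / x$mean_T
    if (x$lower_bound) attr(f, "upper_bound") <- TRUE
    return(f)
  }
  if (inherits(x, "sweep_result")) {
    f <- 1 / x$mean_T_ms
    if (any(x$n_censored > 0)) attr(f, "upper_bound") <- x$n_censored > 0
    return(f)
  }
  if (!is.numeric(x) || any(x <= 0)) stop("mean waiting time must be positive")
  1 / x
}

#' Write a sweep to CSV
#'
#' One row per condition, in the fixed column order used across the package.
#'
#' @param sweep A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep (with per-run times and seeds) to JSON
#'
#' JSON mirror of the CSV that additionally records every run's waiting time,
#' censoring flag and seeds, so any row can be regenerated exactly.
#'
#' @inheritParams write_sweep_csv
#' @return `path`, invisibly.
#' @export
write_sweep_json <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  ens <- attr(sweep, "ensembles")
  doc <- lapply(seq_len(nrow(sweep)), function(i) {
    c(as.list(as.data.frame(sweep)[i, ]),
      list(times_ms = ens[[i]]$times, censored = ens[[i]]$censored,
           seeds = ens[[i]]$seeds, graph_seeds = ens[[i]]$graph_seeds))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
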