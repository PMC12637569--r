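## Flat key = value run configuration: the reproducibility shell around the
## simulator. Defaults are the reference parameter set; a config file
## overrides defaults and CLI flags override the file.

config_defaults <- function() {
  list(
    kfo = 0.005, kb = 0.3, delta = 0.5, sigma = 0.5, g = 25, c0 = 0.1,
    open_subunit_min = 3L, nc = 5L,
    topology = "oblique", rows = 10L, cols = 10L,
    n_channels = NA_integer_, grid = NA_integer_, alpha = NA_real_,
    p = NA_real_,
    t_max = 1e8, t_end = 1000, n_runs = 50L, master_seed = 1L,
    out = NA_character_
  )
}

config_numeric_keys <- c("kfo", "kb", "delta", "sigma", "g", "c0", "alpha",
                         "p", "t_max", "t_end")
config_integer_keys <- c("open_subunit_min", "nc", "rows", "cols",
                         "n_channels", "grid", "n_runs", "master_seed")
config_string_keys <- c("topology", "out")

#' Parse a run configuration
#'
#' Reads a flat `key = value` document (one pair per line, `#` comments),
#' fills unspecified keys with the package defaults, and validates every
#' constraint of the underlying types. Unknown keys are rejected. Specifying
#' both a full grid (`rows`/`cols` alone) and a grown morphology
#' (`n_channels` + `alpha`) is ambiguous and rejected.
#'
#' @param text Character vector of lines, or (if `path` given) ignored.
#' @param path Optional file to read instead of `text`.
#' @param overrides Named list applied after the document (CLI flags).
#' @return A validated list of class `run_config`.
#' @examples
#' parse_config(c("c0 = 5.0", "topology = adjoining"))
#' @export
parse_config <- function(text = character(), path = NULL, overrides = list()) {
  if (!is.null(path)) text <- readLines(path, warn = FALSE)
  cfg <- config_defaults()
  given <- character(0)

  apply_kv <- function(key, value) {
    if (!key %in% names(cfg)) stop(sprintf("unknown config key '%s'", key))
    if (key %in% config_integer_keys) {
      v <- suppressWarnings(as.integer(value))
      if (is.na(v)) stop(sprintf("config key '%s' must be an integer", key))
    } else if (key %in% config_numeric_keys) {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v)) stop(sprintf("config key '%s' must be numeric", key))
    } else {
      v <- as.character(value)
    }
    cfg[[key]] <<- v
    given <<- union(given, key)
  }

  for (line in text) {
    line <- sub("#.*$", "", line)
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(m) != 3L) stop(sprintf("malformed config line: '%s'", line))
    apply_kv(m[2L], m[3L])
  }
  for (key in names(overrides)) {
    if (is.null(overrides[[key]])) next
    apply_kv(key, overrides[[key]])
  }

  # geometry spec: full grid (rows/cols) or grown morphology
  # (n_channels + grid + alpha); mixing the two is ambiguous
  grown <- any(c("n_channels", "alpha", "grid") %in% given)
  if (grown) {
    if (any(c("rows", "cols") %in% given))
      stop("ambiguous geometry: give rows/cols alone or n_channels + grid + alpha")
    if (is.na(cfg$n_channels) || is.na(cfg$alpha) || is.na(cfg$grid))
      stop("grown morphologies need 'n_channels', 'grid' and 'alpha'")
    if (cfg$grid < 1L) stop("'grid' must be positive")
    cfg$rows <- cfg$cols <- cfg$grid
    if (cfg$n_channels > cfg$rows * cfg$cols)
      stop("'n_channels' exceeds the grid capacity")
    if (cfg$alpha < 0) stop("'alpha' must be non-negative")
  }
  validate_rate_params(list(kfo = cfg$kfo, kb = cfg$kb, delta = cfg$delta,
                            sigma = cfg$sigma, g = cfg$g, c0 = cfg$c0,
                            open_subunit_min = cfg$open_subunit_min,
                            nc = cfg$nc))
  if (cfg$rows < 1L || cfg$cols < 1L) stop("grid dimensions must be positive")
  if (!is.na(cfg$p) && (cfg$p < 0 || cfg$p > 1))
    stop("'p' must be a probability in [0, 1]")
  if (cfg$t_max <= 0 || cfg$t_end < 0) stop("time horizons must be positive")
  if (cfg$n_runs < 1L) stop("'n_runs' must be positive")
  if (!cfg$topology %in% c("adjoining", "oblique"))
    stop("'topology' must be 'adjoining' or 'oblique'")
  structure(cfg, class = "run_config", given = given)
}

#' Rate parameters from a run configuration
#' @param cfg A `run_config`.
#' @return A [rate_params()] object.
#' @export
config_params <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rate_params(kfo = cfg$kfo, kb = cfg$kb, delta = cfg$delta,
              sigma = cfg$sigma, g = cfg$g, c0 = cfg$c0,
              open_subunit_min = cfg$open_subunit_min, nc = cfg$nc)
}

#' Coupling graph from a run configuration
#'
#' Builds the geometry the config describes: a full `rows x cols` grid of the
#' given topology, diluted to bond-survival `p` if set, or a
#' preferential-attachment morphology when `n_channels`/`alpha` are set.
#'
#' @param cfg A `run_config`.
#' @param seed Optional seed for the random geometry steps (defaults to the
#'   config's `master_seed`).
#' @return A `coupling_graph`.
#' @export
config_graph <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(seed)) seed <- cfg$master_seed
  if (!is.na(cfg$n_channels)) {
    lat <- grow_preferential(cfg$n_channels, cfg$rows, cfg$cols,
                             alpha = cfg$alpha, seed = seed)
    g <- lattice_to_graph(lat, cfg$topology, sigma = cfg$sigma)
  } else {
    g <- lattice_to_graph(full_lattice(cfg$rows, cfg$cols), cfg$topology,
                          sigma = cfg$sigma)
  }
  if (!is.na(cfg$p)) g <- dilute_bonds(g, cfg$p, seed = seed + 1L)
  g
}

#' @method print run_config
#' @export
print.run_config <- function(x, ...) {
  cat(format_config(x), sep = "\n")
  invisible(x)
}

#' Render the fully resolved configuration as `key = value` lines
#' @param cfg A `run_config`.
#' @return Character vector, one line per key.
#' @export
format_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  vapply(names(unclass(cfg)), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.na(v)) "NA" else format(v, digits = 15))
  }, character(1))
}
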