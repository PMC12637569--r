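#' Channel lattice: occupied sites of a 2-D RyR2 cluster
#'
#' Channels sit on a rectangular grid; each occupied site holds one tetramer
#' (a ~30 nm square). Sites are addressed `(nx, ny)`, 0-based, with `nx` the
#' column and `ny` the row.
#'
#' @param rows,cols Grid dimensions.
#' @param sites Integer matrix with columns `nx`, `ny`, one row per channel.
#' @return An object of class `channel_lattice`.
#' @export
channel_lattice <- function(rows, cols, sites) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("grid dimensions must be positive")
  sites <- matrix(as.integer(sites), ncol = 2L,
                  dimnames = list(NULL, c("nx", "ny")))
  if (nrow(sites) < 1L) stop("at least one channel required")
  if (any(sites[, "nx"] < 0L) || any(sites[, "nx"] >= cols) ||
      any(sites[, "ny"] < 0L) || any(sites[, "ny"] >= rows))
    stop("site out of bounds")
  if (anyDuplicated(sites[, "ny"] * cols + sites[, "nx"]))
    stop("duplicate occupied site")
  structure(list(rows = rows, cols = cols, sites = sites,
                 alpha = NA_real_, seed = NA_integer_),
            class = "channel_lattice")
}

#' Fully occupied rectangular lattice
#'
#' @param rows,cols Grid dimensions.
#' @return A `channel_lattice` with every site occupied, row-major order.
#' @export
full_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("grid dimensions must be positive")
  g <- expand.grid(nx = 0:(cols - 1L), ny = 0:(rows - 1L))
  channel_lattice(rows, cols, cbind(g$nx, g$ny))
}

#' @method print channel_lattice
#' @export
print.channel_lattice <- function(x, ...) {
  cat(sprintf("channel_lattice: %d channels on a %d x %d grid\n",
              nrow(x$sites), x$rows, x$cols))
  if (!is.na(x$alpha)) cat(sprintf("  grown with clustering parameter alpha = %g\n", x$alpha))
  invisible(x)
}

## Subunit corner convention: within a channel the four subunits sit at the
## corners of the square footprint, indexed in ring order
##   0 = NW, 1 = NE, 2 = SE, 3 = SW
## so ring neighbours of subunit s are (s-1) mod 4 and (s+1) mod 4.
## East = nx+1, South = ny+1.
##
## Adjoining contacts: the two facing corners across the shared edge.
##   east pair : (A,1)-(B,0) and (A,2)-(B,3)
##   south pair: (A,3)-(B,0) and (A,2)-(B,1)
## Oblique contacts: one diagonally facing corner pair per shared edge, the
## contacted subunit being the ring-opposite of its partner, so every subunit
## has at most one inter-channel contact (E->1, W->3, S->2, N->0).
##   east pair : (A,1)-(B,3)
##   south pair: (A,2)-(B,0)
.contact_rules <- list(
  adjoining = list(east = rbind(c(1L, 0L), c(2L, 3L)),
                   south = rbind(c(3L, 0L), c(2L, 1L))),
  oblique = list(east = rbind(c(1L, 3L)),
                 south = rbind(c(2L, 0L)))
)

#' Couple the channels of a lattice into a subunit-level graph
#'
#' Applies the contact rule of the requested topology to every pair of
#' occupied, laterally adjacent (4-neighbourhood) sites. Isolated channels get
#' no inter-channel edges; the intra-tetramer ring is implicit and always
#' present.
#'
#' @param lattice A [channel_lattice()].
#' @param topology `"adjoining"` (two contacts per adjacent pair, inter-degree
#'   up to 2 per subunit) or `"oblique"` (one contact per adjacent pair,
#'   inter-degree at most 1).
#' @param sigma Coupling weight stored on every inter-channel edge.
#' @return An object of class `coupling_graph`.
#' @export
lattice_to_graph <- function(lattice, topology = c("adjoining", "oblique"),
                             sigma = 0.5) {
  stopifnot(inherits(lattice, "channel_lattice"))
  topology <- match.arg(topology)
  rule <- .contact_rules[[topology]]
  sites <- lattice$sites
  m <- nrow(sites)
  idx <- matrix(NA_integer_, lattice$rows, lattice$cols)
  idx[cbind(sites[, "ny"] + 1L, sites[, "nx"] + 1L)] <- seq_len(m)

  c1 <- s1 <- c2 <- s2 <- integer(0)
  add <- function(a, b, pairs) {
    c1 <<- c(c1, rep.int(a, nrow(pairs)))
    s1 <<- c(s1, pairs[, 1L])
    c2 <<- c(c2, rep.int(b, nrow(pairs)))
    s2 <<- c(s2, pairs[, 2L])
  }
  for (a in seq_len(m)) {
    nx <- sites[a, "nx"]; ny <- sites[a, "ny"]
    if (nx + 1L < lattice$cols) {
      b <- idx[ny + 1L, nx + 2L]
      if (!is.na(b)) add(a, b, rule$east)
    }
    if (ny + 1L < lattice$rows) {
      b <- idx[ny + 2L, nx + 1L]
      if (!is.na(b)) add(a, b, rule$south)
    }
  }
  edges <- data.frame(c1 = c1, s1 = s1, c2 = c2, s2 = s2,
                      w = rep.int(as.numeric(sigma), length(c1)))
  new_coupling_graph(lattice, topology, sigma, edges)
}

new_coupling_graph <- function(lattice, topology, sigma, edges,
                               p = NA_real_, seed = NA_integer_) {
  g <- structure(list(
    rows = lattice$rows, cols = lattice$cols,
    topology = topology, sigma = as.numeric(sigma),
    channels = lattice$sites, n_channels = nrow(lattice$sites),
    inter_edges = edges,
    alpha = lattice$alpha, p = p, seed = seed
  ), class = "coupling_graph")
  validate_coupling_graph(g)
  g
}

validate_coupling_graph <- function(g) {
  e <- g$inter_edges
  stopifnot(is.data.frame(e),
            all(c("c1", "s1", "c2", "s2", "w") %in% names(e)))
  if (nrow(e) > 0) {
    stopifnot(all(e$c1 >= 1L), all(e$c1 <= g$n_channels),
              all(e$c2 >= 1L), all(e$c2 <= g$n_channels),
              all(e$s1 %in% 0:3), all(e$s2 %in% 0:3),
              all(e$c1 != e$c2))
    a <- (e$c1 - 1L) * 4L + e$s1
    b <- (e$c2 - 1L) * 4L + e$s2
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) stop("duplicate inter-channel edge")
    deg <- tabulate(c(a, b) + 1L, nbins = 4L * g$n_channels)
    cap <- if (identical(g$topology, "oblique")) 1L else 2L
    if (max(deg) > cap)
      stop(sprintf("subunit inter-degree exceeds %d for %s topology",
                   cap, g$topology))
  }
  invisible(g)
}

#' @method print coupling_graph
#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("coupling_graph: %d channels (%d subunits) on %d x %d grid, %s topology\n",
              x$n_channels, 4L * x$n_channels, x$rows, x$cols, x$topology))
  cat(sprintf("  %d inter-channel edges, sigma = %g", nrow(x$inter_edges), x$sigma))
  if (!is.na(x$p)) cat(sprintf(", bond-survival p = %g", x$p))
  if (!is.na(x$alpha)) cat(sprintf(", alpha = %g", x$alpha))
  cat("\n")
  invisible(x)
}

#' Adjoining cluster on a fully occupied grid
#'
#' Every laterally adjacent channel pair is joined by two subunit contacts
#' (the facing corners of the shared edge), so interior subunits carry two
#' inter-channel contacts — one horizontal, one vertical.
#'
#' @param rows,cols Grid dimensions.
#' @param sigma Inter-channel coupling weight.
#' @return A `coupling_graph`.
#' @examples
#' build_adjoining(2, 2)  # 8 inter-channel edges
#' @export
build_adjoining <- function(rows, cols, sigma = 0.5) {
  lattice_to_graph(full_lattice(rows, cols), "adjoining", sigma)
}

#' Oblique cluster on a fully occupied grid
#'
#' The staggered geometry gives one subunit contact per adjacent channel pair,
#' pairing ring-opposite subunit indices, and every subunit has at most one
#' inter-channel contact.
#'
#' @inheritParams build_adjoining
#' @return A `coupling_graph`.
#' @examples
#' build_oblique(2, 2)  # 4 inter-channel edges
#' @export
build_oblique <- function(rows, cols, sigma = 0.5) {
  lattice_to_graph(full_lattice(rows, cols), "oblique", sigma)
}

#' Randomly break inter-channel bonds
#'
#' Each inter-channel edge survives independently with probability `p`; the
#' intra-tetramer rings are structural and never broken. `p = 1` leaves the
#' cluster fully connected, `p = 0` dissociates it completely.
#'
#' @param graph A `coupling_graph`.
#' @param p Bond-survival probability in \[0, 1\].
#' @param seed Optional integer seed for reproducible dilution.
#' @return A `coupling_graph` with the surviving edges; records `p` and `seed`.
#' @export
dilute_bonds <- function(graph, p, seed = NULL) {
  stopifnot(inherits(graph, "coupling_graph"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(nrow(graph$inter_edges)) < p
  graph$inter_edges <- graph$inter_edges[keep, , drop = FALSE]
  rownames(graph$inter_edges) <- NULL
  graph$p <- p
  graph$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  graph
}

#' Grow a heterogeneous cluster by preferential attachment
#'
#' Channels are placed sequentially on an empty grid. At each step an empty
#' site is drawn with probability proportional to `1 + ne^alpha`, where `ne`
#' is its number of occupied 4-neighbourhood sites (with `0^0 := 1`, so
#' `alpha = 0` is exactly uniform placement). Large `alpha` yields compact
#' clusters; `alpha = 0` scatters channels at random.
#'
#' @param n_channels Number of channels to place (at most `rows * cols`).
#' @param rows,cols Grid dimensions.
#' @param alpha Clustering parameter (>= 0).
#' @param seed Optional integer seed.
#' @param weight_form `"power"` uses `1 + ne^alpha` (default); `"linear"` uses
#'   `1 + ne * alpha`. Both are uniform at `alpha = 0`.
#' @return A `channel_lattice` with sites in placement order.
#' @export
grow_preferential <- function(n_channels, rows, cols, alpha, seed = NULL,
                              weight_form = c("power", "linear")) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  n_channels <- as.integer(n_channels)
  weight_form <- match.arg(weight_form)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("grid dimensions must be positive")
  if (n_channels < 1L || n_channels > rows * cols)
    stop("'n_channels' must be between 1 and rows * cols")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("'alpha' must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  n_sites <- rows * cols
  occupied <- logical(n_sites)          # site id = ny * cols + nx + 1
  ne <- integer(n_sites)                # occupied 4-neighbour count
  placed <- integer(n_channels)
  for (k in seq_len(n_channels)) {
    empty <- which(!occupied)
    w <- if (weight_form == "power") 1 + ne[empty]^alpha else 1 + ne[empty] * alpha
    pick <- if (length(empty) == 1L) empty else
      empty[sample.int(length(empty), 1L, prob = w)]
    occupied[pick] <- TRUE
    placed[k] <- pick
    ny <- (pick - 1L) %/% cols; nx <- (pick - 1L) %% cols
    if (nx > 0L) ne[pick - 1L] <- ne[pick - 1L] + 1L
    if (nx < cols - 1L) ne[pick + 1L] <- ne[pick + 1L] + 1L
    if (ny > 0L) ne[pick - cols] <- ne[pick - cols] + 1L
    if (ny < rows - 1L) ne[pick + cols] <- ne[pick + cols] + 1L
  }
  sites <- cbind(nx = (placed - 1L) %% cols, ny = (placed - 1L) %/% cols)
  lat <- channel_lattice(rows, cols, sites)
  lat$alpha <- as.numeric(alpha)
  lat$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  lat
}

#' Count laterally adjacent occupied site pairs
#'
#' A compactness summary for generated morphologies: the number of unordered
#' occupied pairs sharing a grid edge.
#'
#' @param lattice A `channel_lattice`.
#' @return Integer pair count.
#' @export
adjacent_pair_count <- function(lattice) {
  stopifnot(inherits(lattice, "channel_lattice"))
  occ <- matrix(FALSE, lattice$rows, lattice$cols)
  occ[cbind(lattice$sites[, "ny"] + 1L, lattice$sites[, "nx"] + 1L)] <- TRUE
  horiz <- if (lattice$cols > 1L) sum(occ[, -1L] & occ[, -lattice$cols]) else 0L
  vert <- if (lattice$rows > 1L) sum(occ[-1L, ] & occ[-lattice$rows, ]) else 0L
  as.integer(horiz + vert)
}

#' Serialize a coupling graph to JSON
#'
#' The document stores grid dimensions, topology, sigma, occupied sites and
#' the inter-channel edge list with 0-based channel indices, so graphs can be
#' regenerated or exchanged with other tools.
#'
#' @param graph A `coupling_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_graph <- function(graph, path) {
  stopifnot(inherits(graph, "coupling_graph"))
  e <- graph$inter_edges
  doc <- list(
    rows = graph$rows, cols = graph$cols,
    topology = graph$topology, sigma = graph$sigma,
    channels = unname(lapply(seq_len(graph$n_channels), function(i)
      c(graph$channels[i, "nx"], graph$channels[i, "ny"]))),
    inter_edges = unname(lapply(seq_len(nrow(e)), function(i)
      list(c(e$c1[i] - 1L, e$s1[i]), c(e$c2[i] - 1L, e$s2[i]), e$w[i]))),
    alpha = graph$alpha, p = graph$p, seed = graph$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a coupling graph from JSON
#'
#' @param path File written by [write_cluster_graph()].
#' @return A `coupling_graph`.
#' @export
read_cluster_graph <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  sites <- do.call(rbind, lapply(doc$channels, function(x)
    c(as.integer(x[[1]]), as.integer(x[[2]]))))
  lat <- channel_lattice(doc$rows, doc$cols, sites)
  if (!is.null(doc$alpha) && !is.na(doc$alpha)) lat$alpha <- as.numeric(doc$alpha)
  ne <- length(doc$inter_edges)
  edges <- data.frame(
    c1 = integer(ne), s1 = integer(ne), c2 = integer(ne), s2 = integer(ne),
    w = numeric(ne))
  for (i in seq_len(ne)) {
    x <- doc$inter_edges[[i]]
    edges$c1[i] <- as.integer(x[[1]][[1]]) + 1L
    edges$s1[i] <- as.integer(x[[1]][[2]])
    edges$c2[i] <- as.integer(x[[2]][[1]]) + 1L
    edges$s2[i] <- as.integer(x[[2]][[2]])
    edges$w[i] <- as.numeric(x[[3]])
  }
  new_coupling_graph(lat, doc$topology, doc$sigma, edges,
                     p = if (is.null(doc$p)) NA_real_ else as.numeric(doc$p),
                     seed = if (is.null(doc$seed)) NA_integer_ else as.integer(doc$seed))
}
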