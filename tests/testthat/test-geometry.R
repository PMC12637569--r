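test_that("adjoining lattices have two contacts per adjacent pair, degree cap 2", {
  expect_identical(nrow(build_adjoining(1, 1)$inter_edges), 0L)
  expect_identical(nrow(build_adjoining(2, 2)$inter_edges), 8L)
  g <- build_adjoining(10, 10)
  expect_identical(nrow(g$inter_edges), 360L)  # 2 * 10 * 9 pairs * 2 contacts
  deg <- tabulate(c((g$inter_edges$c1 - 1L) * 4L + g$inter_edges$s1 + 1L,
                    (g$inter_edges$c2 - 1L) * 4L + g$inter_edges$s2 + 1L),
                  nbins = 4L * g$n_channels)
  expect_identical(max(deg), 2L)
  # a corner subunit carries 2 contacts iff its channel is interior in both
  # of that corner's directions: 9 * 9 channels for each of the 4 subunits
  expect_identical(sum(deg == 2L), 4L * 81L)
})

test_that("oblique lattices have one contact per adjacent pair, degree cap 1", {
  expect_identical(nrow(build_oblique(1, 1)$inter_edges), 0L)
  expect_identical(nrow(build_oblique(2, 2)$inter_edges), 4L)
  g <- build_oblique(10, 10)
  expect_identical(nrow(g$inter_edges), 180L)  # one per adjacent pair
  deg <- tabulate(c((g$inter_edges$c1 - 1L) * 4L + g$inter_edges$s1 + 1L,
                    (g$inter_edges$c2 - 1L) * 4L + g$inter_edges$s2 + 1L),
                  nbins = 4L * g$n_channels)
  expect_identical(max(deg), 1L)
  # oblique contacts pair ring-opposite subunit indices (the staggered pattern)
  expect_true(all((g$inter_edges$s1 - g$inter_edges$s2) %% 4L == 2L))
  expect_identical(nrow(build_oblique(20, 20)$inter_edges), 760L)
  expect_error(build_oblique(0, 3), "positive")
})

test_that("partial lattices couple only occupied adjacent sites", {
  # horizontal domino: one shared edge
  dom <- channel_lattice(3, 3, rbind(c(0L, 0L), c(1L, 0L)))
  expect_identical(nrow(lattice_to_graph(dom, "adjoining", 1)$inter_edges), 2L)
  expect_identical(nrow(lattice_to_graph(dom, "oblique", 1)$inter_edges), 1L)
  # fully dispersed: no two channels adjacent
  disp <- channel_lattice(3, 3, rbind(c(0L, 0L), c(2L, 0L), c(0L, 2L), c(2L, 2L)))
  expect_identical(nrow(lattice_to_graph(disp, "oblique", 1)$inter_edges), 0L)
  expect_error(lattice_to_graph(dom, "hexagonal"))
  expect_error(channel_lattice(2, 2, rbind(c(0L, 0L), c(0L, 0L))), "duplicate")
  expect_error(channel_lattice(2, 2, rbind(c(2L, 0L))), "bounds")
})

test_that("bond dilution keeps each inter edge independently with probability p", {
  g <- build_adjoining(10, 10, sigma = 1)
  expect_identical(dilute_bonds(g, 1, seed = 1)$inter_edges, g$inter_edges)
  expect_identical(nrow(dilute_bonds(g, 0, seed = 1)$inter_edges), 0L)
  expect_error(dilute_bonds(g, 1.5), "probability")
  expect_error(dilute_bonds(g, -0.1), "probability")
  # reproducibility and subsetting (never invents edges)
  d1 <- dilute_bonds(g, 0.5, seed = 99)
  d2 <- dilute_bonds(g, 0.5, seed = 99)
  expect_identical(d1$inter_edges, d2$inter_edges)
  key <- function(e) paste(e$c1, e$s1, e$c2, e$s2)
  expect_true(all(key(d1$inter_edges) %in% key(g$inter_edges)))
  # surviving count is Binomial(360, p): check the mean over seeds
  p <- 0.5
  counts <- vapply(1:300, function(s) nrow(dilute_bonds(g, p, seed = s)$inter_edges), 0L)
  se <- sqrt(360 * p * (1 - p) / 300)
  expect_lt(abs(mean(counts) - 360 * p), 4 * se)
})

test_that("preferential attachment places the requested number of channels", {
  lat <- grow_preferential(50, 20, 20, alpha = 5, seed = 3)
  expect_identical(nrow(lat$sites), 50L)
  expect_identical(grow_preferential(1, 5, 5, alpha = 2, seed = 1)$sites |> nrow(), 1L)
  expect_error(grow_preferential(26, 5, 5, alpha = 0), "between 1 and")
  expect_error(grow_preferential(10, 5, 5, alpha = -1), "non-negative")
  expect_identical(grow_preferential(30, 10, 10, alpha = 4, seed = 7)$sites,
                   grow_preferential(30, 10, 10, alpha = 4, seed = 7)$sites)
})

test_that("alpha = 0 placement is uniform over sites", {
  counts <- integer(400)
  for (s in 1:300) {
    lat <- grow_preferential(50, 20, 20, alpha = 0, seed = 10000 + s)
    id <- lat$sites[, "ny"] * 20L + lat$sites[, "nx"] + 1L
    counts[id] <- counts[id] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("expected compactness increases with the clustering parameter", {
  mean_pairs <- function(alpha, n_seeds = 150) {
    mean(vapply(seq_len(n_seeds), function(s)
      adjacent_pair_count(grow_preferential(50, 20, 20, alpha, seed = 5000 + s)),
      0L))
  }
  m <- vapply(c(0, 2, 8), mean_pairs, 0)
  expect_true(all(diff(m) > 0))
  expect_gt(m[3], m[1])  # compact at alpha = 8 vs dispersed at alpha = 0
})

test_that("cluster graphs survive a JSON round trip", {
  g <- dilute_bonds(lattice_to_graph(grow_preferential(12, 5, 5, alpha = 3, seed = 2),
                                     "adjoining", sigma = 0.8),
                    p = 0.7, seed = 5)
  path <- tempfile(fileext = ".json")
  write_cluster_graph(g, path)
  g2 <- read_cluster_graph(path)
  expect_identical(g2$channels, g$channels)
  expect_equal(g2$inter_edges, g$inter_edges)
  expect_identical(g2$topology, g$topology)
  expect_equal(g2$sigma, g$sigma)
  expect_equal(g2$p, g$p)
})
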