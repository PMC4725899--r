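test_that("uniform and near-uniform grids label as expected", {
  all_AA <- make_grid(rep(2L, 100), 10, 10, "g4")
  lab <- label_clusters(all_AA)
  expect_identical(nrow(lab$clusters), 1L)
  expect_identical(lab$clusters$size, 100L)
  expect_identical(lab$clusters$genotype, "AA")

  one_defect <- make_grid(c(rep(2L, 44), 0L, rep(2L, 55)), 10, 10, "g4")
  lab <- label_clusters(one_defect)
  expect_setequal(lab$clusters$size, c(99L, 1L))
})

test_that("an AA/aa checkerboard under g4 is all singleton clusters", {
  g <- as.integer(2L * ((outer(1:10, 1:10, `+`) %% 2L)))
  grid <- make_grid(as.integer(t(matrix(g, 10, 10))), 10, 10, "g4")
  lab <- label_clusters(grid)
  expect_identical(nrow(lab$clusters), 100L)
  expect_true(all(lab$clusters$size == 1L))
  dist <- cluster_size_distribution(lab)
  expect_identical(sum(dist$n_clusters), 100L)
  expect_true(all(dist$size == 1L))
})

test_that("clusters wrap across the periodic seam", {
  # one aa band spanning the vertical seam: columns 1 and 8 of every row
  g <- matrix(2L, 6, 8)
  g[, c(1, 8)] <- 0L
  grid <- make_grid(as.integer(t(g)), 6, 8, "g4")
  lab <- label_clusters(grid)
  expect_identical(sort(lab$clusters$size), c(12L, 36L))
  expect_identical(nrow(lab$clusters), 2L)  # the band is one wrapped cluster
})

test_that("labels are dense, row-major ordered, and conserve site counts", {
  set.seed(71)
  for (topo in c("g4", "g6", "g8")) {
    grid <- initialize_population(sim_params(rows = 8, cols = 7,
                                             topology = topo, p0 = 0.5))
    lab <- label_clusters(grid, topo)
    labs_used <- sort(unique(as.vector(lab$label[lab$label > 0])))
    expect_identical(labs_used, seq_along(lab$clusters$label))
    # first encounters in row-major order carry increasing labels
    row_major <- as.vector(t(lab$label))
    expect_false(is.unsorted(match(labs_used, row_major)))
    expect_identical(sum(lab$clusters$size) + lab$n_het,
                     nrow(grid) * ncol(grid))
    # same-genotype neighbours share labels; different genotypes never do
    for (lbl in labs_used) {
      geno <- unique(as.integer(grid)[as.vector(lab$label) == lbl])
      expect_identical(length(geno), 1L)
    }
  }
})

test_that("labelling matches a brute-force flood fill", {
  set.seed(72)
  cases <- list(c("g4", 12, 12), c("g6", 10, 9), c("g8", 20, 20),
                c("g4", 20, 15))
  for (cs in cases) {
    topo <- cs[1]; rows <- as.integer(cs[2]); cols <- as.integer(cs[3])
    grid <- initialize_population(sim_params(rows = rows, cols = cols,
                                             topology = topo, p0 = 0.5))
    # evolve a little so real clusters exist
    for (i in 1:15) grid <- step_generation(grid)
    lab <- label_clusters(grid, topo)
    mat <- matrix(as.integer(grid), rows, cols)
    oracle <- oracle_flood_fill(mat, topo)
    expect_identical(max(oracle), nrow(lab$clusters), info = topo)
    expect_identical(label_sizes(lab$label, mat), label_sizes(oracle, mat),
                     info = topo)
    # identical partitions: label maps agree up to renaming
    pairs <- table(lab$label[lab$label > 0], oracle[oracle > 0])
    expect_true(all(rowSums(pairs > 0) == 1) && all(colSums(pairs > 0) == 1),
                info = topo)
  }
})

test_that("panmixia has no spatial clusters to label", {
  grid <- make_grid(rep(2L, 16), 4, 4, "gnf")
  expect_error(label_clusters(grid), "spatial topology")
  expect_error(boundary_heterozygote_fraction(grid), "spatial topology")
})

test_that("boundary heterozygote fractions match hand constructions", {
  all_het <- make_grid(rep(1L, 64), 8, 8, "g4")
  bd <- boundary_heterozygote_fraction(all_het)
  expect_equal(bd$frac_between, 0)
  expect_equal(bd$frac_adjacent, 0)

  # vertical AA | Aa | aa stripes: every heterozygote sits between clusters
  g <- matrix(0L, 10, 10)
  g[, 1:4] <- 2L
  g[, 5] <- 1L
  grid <- make_grid(as.integer(t(g)), 10, 10, "g4")
  bd <- boundary_heterozygote_fraction(grid)
  expect_equal(bd$frac_between, 1)
  expect_equal(bd$frac_adjacent, 1)
  expect_identical(bd$n_het, 10L)

  grid_fixed <- make_grid(rep(2L, 36), 6, 6, "g4")
  bd <- boundary_heterozygote_fraction(grid_fixed)
  expect_true(bd$no_heterozygotes)
  expect_equal(bd$frac_between, 0)

  # determinism: repeated calls agree
  set.seed(73)
  grid <- initialize_population(sim_params(size = 9, topology = "g8",
                                           p0 = 0.5))
  expect_identical(boundary_heterozygote_fraction(grid),
                   boundary_heterozygote_fraction(grid))
})

test_that("spatial constraint builds clusters beyond a shuffled control", {
  # largest-cluster fraction after 120 generations at N=400 under g4,
  # against the same genotype counts randomly re-arranged
  set.seed(74)
  diffs <- vapply(1:25, function(i) {
    tr <- run_to_fixation(sim_params(size = 20, topology = "g4", p0 = 0.5,
                                     max_generations = 120), record = FALSE)
    grid <- tr$final
    frac <- function(g) {
      lab <- label_clusters(g, "g4")
      if (nrow(lab$clusters) == 0) 0 else max(lab$clusters$size) / 400
    }
    shuffled <- make_grid(sample(as.integer(grid)), 20, 20, "g4")
    frac(grid) - frac(shuffled)
  }, numeric(1))
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})
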