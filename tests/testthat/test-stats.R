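counts_tbl <- function(n_AA, n_Aa, n_aa) {
  tibble::tibble(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa)
}

test_that("allele frequency counts gene copies", {
  expect_equal(allele_frequency(counts_tbl(10, 0, 0)), 1)
  expect_equal(allele_frequency(counts_tbl(1, 2, 1)), 0.5)
  expect_equal(allele_frequency(counts_tbl(2, 1, 1)), 0.625)  # 5 of 8 copies
  expect_equal(allele_frequency(counts_tbl(c(10, 1), c(0, 2), c(0, 1))),
               c(1, 0.5))
  expect_error(allele_frequency(counts_tbl(0, 0, 0)), ">= 1")
})

test_that("observed heterozygosity is the Aa fraction", {
  expect_equal(heterozygosity(counts_tbl(0, 12, 0)), 1)
  expect_equal(heterozygosity(counts_tbl(12, 0, 0)), 0)
  expect_equal(heterozygosity(counts_tbl(3, 2, 3)), 0.25)
})

test_that("inbreeding coefficient measures heterozygote deficit", {
  expect_equal(inbreeding_coefficient(counts_tbl(25, 50, 25)), 0)  # HWE
  expect_equal(inbreeding_coefficient(counts_tbl(50, 0, 50)), 1)
  expect_equal(inbreeding_coefficient(counts_tbl(3, 2, 3)), 0.5)
  expect_error(inbreeding_coefficient(counts_tbl(10, 0, 0)), "undefined")
})

test_that("statistics agree with direct recounting of a population grid", {
  set.seed(61)
  grid <- initialize_population(sim_params(size = 8, topology = "g4",
                                           p0 = 0.4))
  g <- as.integer(grid)
  cc <- genotype_counts(grid)
  expect_identical(cc$n_AA, sum(g == 2L))
  expect_identical(cc$n_Aa, sum(g == 1L))
  expect_equal(allele_frequency(cc), sum(g) / (2 * length(g)))
  expect_equal(heterozygosity(cc), mean(g == 1L))
})

test_that("inverse-Gaussian MLE has its closed form", {
  fit <- fit_inverse_gaussian(c(1, 2, 3))
  expect_equal(fit$mu, 2)
  expect_equal(fit$lambda, 9)  # 3 / (1 + 1/2 + 1/3 - 3/2)
  expect_error(fit_inverse_gaussian(rep(4, 10)), "degenerate")
  expect_error(fit_inverse_gaussian(c(1, -2, 3)), "positive")
  expect_error(fit_inverse_gaussian(2), "at least 2")
})

test_that("fitted mu equals the sample mean exactly, for any sample", {
  set.seed(62)
  for (i in 1:5) {
    x <- stats::rgamma(50, shape = 2, rate = 0.1) + 1
    expect_identical(fit_inverse_gaussian(x)$mu, mean(x))
  }
})

test_that("inverse-Gaussian parameters are recovered from large samples", {
  set.seed(63)
  x <- oracle_rinvgauss(50000, mu = 5, lambda = 20)
  fit <- fit_inverse_gaussian(x)
  se_mu <- sqrt(5^3 / 20 / 50000)
  se_lam <- 20 * sqrt(2 / 50000)
  expect_lt(abs(fit$mu - 5), 3 * se_mu)
  expect_lt(abs(fit$lambda - 20), 3 * se_lam)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_inverse_gaussian(c(1, 2, 3))
  td <- tidy(fit)
  expect_identical(td$term, c("mu", "lambda"))
  expect_equal(td$estimate, c(2, 9))
  gl <- glance(fit)
  expect_identical(gl$n, 3L)
  expect_true(is.finite(gl$logLik))
})

test_that("heterozygosity decay recovers its own closed form exactly", {
  curve <- tibble::tibble(generation = 0:200,
                          H = 0.5 * (1 - 1 / 100)^(0:200))
  fit <- fit_het_decay(curve)
  expect_equal(fit$N_e, 50, tolerance = 1e-6)
  expect_equal(fit$H0, 0.5, tolerance = 1e-6)
  expect_equal(fit$mean_rel_residual, 0, tolerance = 1e-8)
})

test_that("decay fitting rejects degenerate inputs and drops H = 0 points", {
  flat <- tibble::tibble(generation = 0:50, H = rep(0.5, 51))
  expect_error(fit_het_decay(flat), "no decay")
  few <- tibble::tibble(generation = 0:4, H = c(0.5, 0.4, 0, 0, 0))
  expect_error(fit_het_decay(few), "at least 3")
  some <- tibble::tibble(generation = 0:5,
                         H = c(0.5, 0.45, 0.4, 0.36, 0, 0))
  fit <- fit_het_decay(some)
  expect_identical(fit$n_dropped, 2L)
  expect_identical(fit$n_used, 4L)
})

test_that("panmictic simulations decay exponentially; constrained ones do not", {
  cv <- heterozygosity_curves(c("gnf", "g4"), size = 20, n_reps = 400,
                              horizon = 200, base_seed = 55)
  fit_gnf <- fit_het_decay(dplyr::filter(cv, topology == "gnf"),
                           window = c(1, 200))
  fit_g4 <- fit_het_decay(dplyr::filter(cv, topology == "g4"),
                          window = c(1, 200))
  # panmixia: single-exponential decay, small relative residuals, and the
  # implied effective size is of the population's order (here above N:
  # mate-number variance is below Wright-Fisher's)
  expect_lt(fit_gnf$mean_rel_residual, 0.05)
  expect_gt(fit_gnf$N_e, 400)
  expect_lt(fit_gnf$N_e, 800)
  # local mating: systematic curvature, visibly worse single-exponential fit
  expect_gt(fit_g4$mean_rel_residual, 2 * fit_gnf$mean_rel_residual)
})

test_that("mean fixation time excludes capped replicates with a count", {
  expect_equal(t_ave(tibble::tibble(t_h = c(10, 20, 30)))$t_ave, 20)
  expect_equal(t_ave(tibble::tibble(t_h = 5))$t_ave, 5)
  mixed <- tibble::tibble(t_h = c(10, NA, 20, NA),
                          capped = c(FALSE, TRUE, FALSE, TRUE))
  ta <- t_ave(mixed)
  expect_equal(ta$t_ave, 15)
  expect_identical(ta$excluded, 2L)
  expect_error(t_ave(tibble::tibble(t_h = NA_real_, capped = TRUE)),
               "all replicates")
})

test_that("the size slope is the through-origin proportionality constant", {
  fit <- fit_slope(sizes = c(100, 400), t_aves = c(473, 1892))
  expect_equal(fit$slope, 4.73)
  expect_error(fit_slope(sizes = 100, t_aves = 500), "at least 2")
  set.seed(64)
  sizes <- c(100, 400, 900)
  t_aves <- 8.44 * sizes * (1 + stats::rnorm(3, 0, 0.02))
  fit <- fit_slope(sizes = sizes, t_aves = t_aves)
  expect_lt(abs(fit$slope - 8.44) / 8.44, 0.03)
})

test_that("equivalent-size ratios invert the slopes", {
  expect_equal(size_ratio(4.73, 4.73), 1)
  expect_equal(round(size_ratio(8.44, 4.73), 2), 0.56)
  expect_equal(round(size_ratio(6.96, 4.73), 2), 0.68)
  expect_error(size_ratio(-1, 2), "positive")
})
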