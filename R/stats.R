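#' Allele frequency from genotype counts
#'
#' The frequency of allele A is its share of all 2N gene copies:
#' `f_A = (2 n_AA + n_Aa) / (2N)`.
#'
#' @param counts A data frame with columns `n_AA`, `n_Aa`, `n_aa` (e.g. from
#'   [genotype_counts()]); rows are vectorised.
#' @return Numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequency <- function(counts) {
  counts <- as_counts(counts)
  (2 * counts$n_AA + counts$n_Aa) / (2 * counts$N)
}

#' Observed heterozygosity
#'
#' The fraction of heterozygous individuals, `n_Aa / N`.
#'
#' @inheritParams allele_frequency
#' @return Numeric vector in \[0, 1\].
#' @export
heterozygosity <- function(counts) {
  counts <- as_counts(counts)
  counts$n_Aa / counts$N
}

#' Inbreeding coefficient
#'
#' The proportional deficit of observed relative to expected (Hardy-Weinberg)
#' heterozygosity: `F = 1 - H_obs / (2 f_A (1 - f_A))`. Undefined in a fixed
#' population (`f_A` 0 or 1), where expected heterozygosity vanishes.
#'
#' @inheritParams allele_frequency
#' @return Numeric vector; `F = 0` at Hardy-Weinberg proportions, `F = 1`
#'   with no heterozygotes at intermediate frequency.
#' @export
inbreeding_coefficient <- function(counts) {
  counts <- as_counts(counts)
  f <- allele_frequency(counts)
  if (any(f <= 0 | f >= 1)) {
    stop("inbreeding coefficient is undefined for a fixed population ",
         "(allele frequency 0 or 1)", call. = FALSE)
  }
  1 - heterozygosity(counts) / (2 * f * (1 - f))
}

as_counts <- function(counts) {
  if (inherits(counts, "population_grid")) counts <- genotype_counts(counts)
  if (!is.data.frame(counts) ||
      !all(c("n_AA", "n_Aa", "n_aa") %in% names(counts))) {
    stop("`counts` must be a data frame with columns n_AA, n_Aa, n_aa",
         call. = FALSE)
  }
  if (any(counts$n_AA < 0 | counts$n_Aa < 0 | counts$n_aa < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  counts$N <- counts$n_AA + counts$n_Aa + counts$n_aa
  if (any(counts$N < 1)) stop("population size must be >= 1", call. = FALSE)
  counts
}

#' Maximum-likelihood inverse-Gaussian fit
#'
#' Fits the two-parameter inverse-Gaussian (Wald) distribution -- the
#' first-passage-time law of Brownian motion with drift -- to a sample of
#' positive values such as fixation times. The MLE is closed form:
#' `mu = mean(x)` and `lambda = n / sum(1/x - 1/mu)`.
#'
#' @param x Numeric vector of positive values (at least 2, not all equal), or
#'   a `fixation_sample` from [run_replicates()] (capped replicates are
#'   excluded with a count).
#' @return An `ig_fit` object with fields `mu`, `lambda`, `n`, `loglik` and
#'   `excluded` (capped values dropped before fitting).
#' @export
fit_inverse_gaussian <- function(x) {
  excluded <- 0L
  if (inherits(x, "fixation_sample")) {
    excluded <- sum(x$capped)
    x <- x$t_h[!x$capped]
  }
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values to fit", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  mu <- mean(x)
  denom <- sum(1 / x - 1 / mu)
  if (denom <= .Machine$double.eps * length(x)) {
    stop("degenerate fit: sample has no within-sample dispersion",
         call. = FALSE)
  }
  lambda <- length(x) / denom
  structure(list(mu = mu, lambda = lambda, n = length(x),
                 loglik = sum(dinvgauss_log(x, mu, lambda)),
                 excluded = excluded),
            class = "ig_fit")
}

# log-density of the inverse-Gaussian distribution
dinvgauss_log <- function(x, mu, lambda) {
  0.5 * log(lambda / (2 * pi * x^3)) - lambda * (x - mu)^2 / (2 * mu^2 * x)
}

#' @export
print.ig_fit <- function(x, ...) {
  cat("<ig_fit> inverse-Gaussian MLE on n = ", x$n, " values\n",
      "  mu = ", format(x$mu, digits = 6), ", lambda = ",
      format(x$lambda, digits = 6), "\n", sep = "")
  if (x$excluded > 0) cat("  (", x$excluded, " capped replicates excluded)\n",
                          sep = "")
  invisible(x)
}

#' @rdname fit_inverse_gaussian
#' @param ... Unused.
#' @export
tidy.ig_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "lambda"),
                 estimate = c(x$mu, x$lambda))
}

#' @rdname fit_inverse_gaussian
#' @export
glance.ig_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, lambda = x$lambda, n = x$n,
                 logLik = x$loglik, excluded = x$excluded)
}

#' Fit exponential heterozygosity decay and effective population size
#'
#' In an ideal randomly mating population of effective size `N_e`, expected
#' heterozygosity declines geometrically:
#' `H_e(T) = H0 (1 - 1/(2 N_e))^T`. The fit is ordinary least squares of
#' `log H` on `T` within a generation window; `N_e` is recovered from the
#' slope `b` as `1 / (2 (1 - exp(b)))`.
#'
#' @param curve Data frame with columns `generation` and a heterozygosity
#'   column (`mean_H`, `H_obs` or `H` -- first match wins).
#' @param window Length-2 numeric range of generations to fit, default the
#'   whole curve.
#' @return A `het_decay_fit` with `N_e`, `H0`, the fitted slope, the number
#'   of points used and dropped (non-positive H), and the mean absolute
#'   relative residual on the natural scale.
#' @export
fit_het_decay <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve), "generation" %in% names(curve))
  hcol <- intersect(c("mean_H", "H_obs", "H"), names(curve))[1]
  if (is.na(hcol)) stop("no heterozygosity column found", call. = FALSE)
  df <- tibble::tibble(generation = curve$generation, H = curve[[hcol]])
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$generation >= window[1],
                        .data$generation <= window[2])
  }
  dropped <- sum(df$H <= 0)
  df <- dplyr::filter(df, .data$H > 0)
  if (nrow(df) < 3L) {
    stop("need at least 3 points with positive heterozygosity", call. = FALSE)
  }
  fit <- stats::lm(log(H) ~ generation, data = df)
  b <- unname(stats::coef(fit)[["generation"]])
  if (b >= 0) {
    stop("no decay: heterozygosity does not decrease over the window",
         call. = FALSE)
  }
  n_e <- 1 / (2 * (1 - exp(b)))
  h0 <- exp(unname(stats::coef(fit)[[1]]))
  pred <- h0 * exp(b * df$generation)
  structure(list(N_e = n_e, H0 = h0, slope = b,
                 n_used = nrow(df), n_dropped = dropped,
                 mean_rel_residual = mean(abs(df$H - pred) / df$H),
                 window = window %||% range(df$generation)),
            class = "het_decay_fit")
}

#' @export
print.het_decay_fit <- function(x, ...) {
  cat("<het_decay_fit> H(T) = H0 (1 - 1/(2 Ne))^T\n",
      "  N_e = ", format(x$N_e, digits = 6), ", H0 = ",
      format(x$H0, digits = 4), " (", x$n_used, " points",
      if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped"), ")\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_het_decay
#' @param x A `het_decay_fit`.
#' @param ... Unused.
#' @export
glance.het_decay_fit <- function(x, ...) {
  tibble::tibble(N_e = x$N_e, H0 = x$H0, slope = x$slope,
                 n_used = x$n_used, n_dropped = x$n_dropped,
                 mean_rel_residual = x$mean_rel_residual)
}

#' Mean fixation time
#'
#' Arithmetic mean of the fixation times of the uncapped replicates; capped
#' replicates (no fixation before the generation cap) are excluded and
#' counted.
#'
#' @param samples A `fixation_sample` from [run_replicates()], or a data
#'   frame with a `t_h` column and optional logical `capped` column.
#' @return A one-row tibble with `t_ave`, `se`, `n` and `excluded`.
#' @export
t_ave <- function(samples) {
  if (is.data.frame(samples)) {
    capped <- if ("capped" %in% names(samples)) samples$capped else is.na(samples$t_h)
    x <- samples$t_h[!capped]
  } else {
    x <- as.numeric(samples)
    capped <- is.na(x)
    x <- x[!capped]
  }
  if (length(x) < 1L) stop("all replicates were capped; T_ave undefined",
                           call. = FALSE)
  tibble::tibble(t_ave = mean(x),
                 se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
                 n = length(x), excluded = sum(capped))
}

#' Proportionality of mean fixation time to population size
#'
#' Mean fixation time grows with population size; this fits the
#' proportionality constant (generations per individual) by least squares
#' through the origin, `slope = sum(size * t_ave) / sum(size^2)`, and also
#' reports the ordinary with-intercept OLS slope as a sensitivity diagnostic.
#'
#' @param df Data frame with columns `size` and `t_ave` (one row per
#'   population size), e.g. the `cells` table of [sweep_sizes()] filtered to
#'   one topology. Alternatively pass `sizes` and `t_aves` vectors.
#' @param sizes,t_aves Optional numeric vectors used when `df` is missing.
#' @return A `slope_fit` with `slope` (through origin), `slope_ols` and
#'   `intercept_ols`, plus the data used.
#' @export
fit_slope <- function(df = NULL, sizes = NULL, t_aves = NULL) {
  if (!is.null(df)) {
    stopifnot(is.data.frame(df), all(c("size", "t_ave") %in% names(df)))
    sizes <- df$size; t_aves <- df$t_ave
  }
  keep <- is.finite(sizes) & is.finite(t_aves)
  sizes <- sizes[keep]; t_aves <- t_aves[keep]
  if (length(sizes) < 2L) {
    stop("need at least 2 population sizes to fit a slope", call. = FALSE)
  }
  if (any(t_aves <= 0)) stop("mean fixation times must be positive", call. = FALSE)
  slope <- sum(sizes * t_aves) / sum(sizes^2)
  ols <- stats::lm(t_aves ~ sizes)
  structure(list(slope = slope,
                 slope_ols = unname(stats::coef(ols)[["sizes"]]),
                 intercept_ols = unname(stats::coef(ols)[[1]]),
                 sizes = sizes, t_aves = t_aves, n = length(sizes)),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("<slope_fit> T_ave / size = ", format(x$slope, digits = 5),
      " generations per individual (through origin, ", x$n, " sizes)\n",
      "  with-intercept OLS slope ", format(x$slope_ols, digits = 5), "\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_slope
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_ols = x$slope_ols,
                 intercept_ols = x$intercept_ols, n_sizes = x$n)
}

#' Equivalent-population-size ratio
#'
#' The population size needed under a spatially constrained topology to match
#' the mean fixation time of a panmictic population is inversely proportional
#' to the T_ave/size slopes: `ratio = slope_panmictic / slope_constrained`.
#'
#' @param slope_constrained,slope_panmictic Positive slopes (generations per
#'   individual), e.g. from [fit_slope()].
#' @return The size fraction (a constrained population this fraction of the
#'   panmictic size has the same mean fixation time).
#' @export
size_ratio <- function(slope_constrained, slope_panmictic) {
  if (inherits(slope_constrained, "slope_fit")) slope_constrained <- slope_constrained$slope
  if (inherits(slope_panmictic, "slope_fit")) slope_panmictic <- slope_panmictic$slope
  if (any(slope_constrained <= 0) || any(slope_panmictic <= 0)) {
    stop("slopes must be positive", call. = FALSE)
  }
  slope_panmictic / slope_constrained
}
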