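#' Simulation parameters
#'
#' Bundles everything one drift run needs: lattice dimensions, mate-choice
#' topology, the initial per-copy probability of allele A, a seed, and a
#' generation cap.
#'
#' @param size Convenience for a square lattice: `size = 10` means a 10x10
#'   lattice (N = 100). Ignored when `rows`/`cols` are given.
#' @param rows,cols Lattice dimensions (both >= 2; `rows` even for `"g6"`).
#' @param topology One of `"g4"`, `"g6"`, `"g8"`, `"gnf"`.
#' @param p0 Initial probability that any single gene copy is allele A, in
#'   \[0, 1\]. Each of the 2N copies is drawn independently.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param max_generations Generation cap; runs that have not fixed by then are
#'   flagged as capped, never silently truncated. Defaults to `1000 * N`,
#'   far above typical fixation times (a few times N generations).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(size = NULL, rows = NULL, cols = NULL,
                       topology = c("g4", "g6", "g8", "gnf"),
                       p0 = 0.5, seed = NULL, max_generations = NULL) {
  topology <- match_topology(topology[[1L]])
  if (is.null(rows)) {
    if (is.null(size)) stop("supply `size` or `rows` and `cols`", call. = FALSE)
    rows <- size
    cols <- size
  }
  if (is.null(cols)) cols <- rows
  cfg <- check_lattice(rows, cols, topology)
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 0 || p0 > 1) {
    stop("`p0` must be a probability in [0, 1]", call. = FALSE)
  }
  n <- cfg$rows * cfg$cols
  if (is.null(max_generations)) max_generations <- 1000L * n
  if (max_generations < 1) stop("`max_generations` must be >= 1", call. = FALSE)
  structure(list(rows = cfg$rows, cols = cfg$cols, topology = cfg$topology,
                 p0 = p0, seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_generations = as.integer(max_generations), n = n),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$rows, "x", x$cols, " (N = ", x$n, "), topology ",
      x$topology, ", p0 = ", x$p0,
      if (!is.null(x$seed)) paste0(", seed = ", x$seed) else "",
      ", cap = ", x$max_generations, "\n", sep = "")
  invisible(x)
}

new_population_grid <- function(g, rows, cols, topology, generation = 0L) {
  m <- matrix(as.integer(g), nrow = rows, ncol = cols, byrow = TRUE)
  structure(m, class = c("population_grid", "matrix", "array"),
            topology = topology, generation = as.integer(generation))
}

#' Initialise a population grid
#'
#' Draws each of the 2N gene copies independently: allele A with probability
#' `p0`. Genotypes are stored as copies of allele A per site (0 = aa, 1 = Aa,
#' 2 = AA); heterozygotes are unordered states.
#'
#' @param params A [sim_params()] object. If it carries a seed, the RNG is
#'   seeded before drawing.
#' @return A `population_grid`: an integer matrix of allele-A copy numbers
#'   with attributes `topology` and `generation` (0).
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g <- stats::rbinom(params$n, 2L, params$p0)
  new_population_grid(g, params$rows, params$cols, params$topology)
}

#' Advance a population by one synchronous generation
#'
#' Every site acts once as a focal parent: it draws a uniform mate from its
#' candidate set, each parent contributes one of its two alleles with equal
#' probability, and the offspring occupies the focal site. All offspring are
#' produced from the parental generation before any replacement (synchronous
#' update), so population size is constant.
#'
#' @param grid A `population_grid`.
#' @param topology Optional override of the grid's topology attribute.
#' @return The next-generation `population_grid` (generation incremented).
#' @export
step_generation <- function(grid, topology = NULL) {
  stopifnot(inherits(grid, "population_grid"))
  topology <- match_topology(topology %||% attr(grid, "topology"))
  rows <- nrow(grid); cols <- ncol(grid)
  nbr <- nbr_for_cpp(rows, cols, topology)
  g <- as.integer(t(unclass(grid)))  # row-major site order
  out <- cpp_step(g, nbr$mat, nbr$panmictic)
  new_population_grid(out, rows, cols, topology,
                      generation = attr(grid, "generation") + 1L)
}

#' @export
print.population_grid <- function(x, ...) {
  cat("<population_grid> ", nrow(x), "x", ncol(x), ", topology ",
      attr(x, "topology"), ", generation ", attr(x, "generation"), "\n",
      sep = "")
  counts <- genotype_counts(x)
  cat("  n_AA = ", counts$n_AA, ", n_Aa = ", counts$n_Aa, ", n_aa = ",
      counts$n_aa, ", f_A = ", format(allele_frequency(counts), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Genotype counts of a population grid
#'
#' @param grid A `population_grid` (or an integer matrix of allele-A copies).
#' @return A one-row tibble with `n_AA`, `n_Aa`, `n_aa` and `N`.
#' @export
genotype_counts <- function(grid) {
  g <- as.integer(grid)
  tibble::tibble(n_AA = sum(g == 2L), n_Aa = sum(g == 1L),
                 n_aa = sum(g == 0L), N = length(g))
}

#' Run one replicate to allelic fixation
#'
#' Iterates [step_generation()] until the allele frequency reaches 0 or 1
#' (equivalently, all individuals are homozygous for the same allele) or the
#' generation cap is hit. The fixation generation `T_h` is the first
#' generation with `f_A` in \{0, 1\}; an initially fixed population has
#' `T_h = 0`. Identical parameters and seed give a bit-identical trajectory.
#'
#' @param params A [sim_params()] object.
#' @param record If `TRUE` (default), per-generation genotype counts are kept;
#'   turn off for large replicate batteries where only `T_h` matters.
#' @return A `drift_trajectory`: list with `counts` (tibble of `generation`,
#'   `n_AA`, `n_Aa`, `n_aa`, `f_A`, `H_obs`; `NULL` when `record = FALSE`),
#'   `t_h` (`NA` if capped), `fixed_allele` (`"A"`, `"a"` or `NA`), `capped`,
#'   `final` (final `population_grid`) and `params`.
#' @export
run_to_fixation <- function(params, record = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g0 <- stats::rbinom(params$n, 2L, params$p0)
  nbr <- nbr_for_cpp(params$rows, params$cols, params$topology)
  res <- cpp_run(g0, nbr$mat, nbr$panmictic, params$max_generations, record)
  capped <- res$t_h < 0L
  fixed_allele <- if (capped) NA_character_ else if (res$n_AA == params$n) "A" else "a"
  counts <- NULL
  if (record) {
    counts <- tibble::tibble(
      generation = seq_along(res$series_AA) - 1L,
      n_AA = res$series_AA, n_Aa = res$series_Aa, n_aa = res$series_aa) |>
      dplyr::mutate(
        f_A = (2 * .data$n_AA + .data$n_Aa) / (2 * params$n),
        H_obs = .data$n_Aa / params$n)
  }
  structure(list(
    counts = counts,
    t_h = if (capped) NA_integer_ else res$t_h,
    fixed_allele = fixed_allele,
    capped = capped,
    final = new_population_grid(res$g, params$rows, params$cols,
                                params$topology,
                                generation = if (capped) params$max_generations
                                             else res$t_h),
    params = params), class = "drift_trajectory")
}

#' @export
print.drift_trajectory <- function(x, ...) {
  cat("<drift_trajectory> ", x$params$rows, "x", x$params$cols, " ",
      x$params$topology, ", p0 = ", x$params$p0, "\n", sep = "")
  if (x$capped) {
    cat("  capped at ", x$params$max_generations,
        " generations without fixation\n", sep = "")
  } else {
    cat("  fixed allele ", x$fixed_allele, " at generation T_h = ", x$t_h,
        "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_to_fixation
#' @param x A `drift_trajectory`.
#' @param ... Unused.
#' @export
tidy.drift_trajectory <- function(x, ...) {
  if (is.null(x$counts)) {
    stop("trajectory was run with `record = FALSE`; no per-generation counts",
         call. = FALSE)
  }
  x$counts
}

#' @rdname run_to_fixation
#' @export
glance.drift_trajectory <- function(x, ...) {
  tibble::tibble(
    n = x$params$n, topology = x$params$topology, p0 = x$params$p0,
    t_h = x$t_h, fixed_allele = x$fixed_allele, capped = x$capped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
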