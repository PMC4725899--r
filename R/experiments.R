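#' Deterministic per-replicate seed
#'
#' Derives an integer seed in `[1, 2^31 - 2]` from a base seed, topology,
#' population size and replicate index by modular folding, so every replicate
#' of every sweep cell is reproducible on its own and independent of
#' scheduling order.
#'
#' @param base_seed Integer base seed.
#' @param topology Topology name (enters as its index among g4, g6, g8, gnf).
#' @param size Population size N.
#' @param rep Replicate index (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, topology, size, rep) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(base_seed) %% m
  for (tok in c(match(match_topology(topology), TOPOLOGIES),
                as.numeric(size), as.numeric(rep))) {
    h <- (h * 69069 + tok + 1) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Run a battery of replicates to fixation
#'
#' Runs `n_reps` independent replicates of the same parameter set, each from
#' its own [replicate_seed()] stream, and collects fixation times.
#'
#' @param params A [sim_params()] object (its own `seed` field is ignored in
#'   favour of per-replicate seeds).
#' @param n_reps Number of replicates.
#' @param base_seed Base seed for [replicate_seed()].
#' @return A `fixation_sample`: tibble with columns `rep`, `seed`, `t_h`
#'   (`NA` when capped), `fixed_allele`, `capped`, carrying the parameters as
#'   an attribute.
#' @export
run_replicates <- function(params, n_reps, base_seed = 1L) {
  stopifnot(inherits(params, "sim_params"), n_reps >= 1)
  nbr <- nbr_for_cpp(params$rows, params$cols, params$topology)
  res <- purrr::map(seq_len(n_reps), function(i) {
    s <- replicate_seed(base_seed, params$topology, params$n, i)
    set.seed(s)
    g0 <- stats::rbinom(params$n, 2L, params$p0)
    r <- cpp_run(g0, nbr$mat, nbr$panmictic, params$max_generations, FALSE)
    capped <- r$t_h < 0L
    tibble::tibble(
      rep = i, seed = s,
      t_h = if (capped) NA_integer_ else r$t_h,
      fixed_allele = if (capped) NA_character_ else if (r$n_AA == params$n) "A" else "a",
      capped = capped)
  })
  out <- dplyr::bind_rows(res)
  structure(out, params = params, base_seed = base_seed,
            class = c("fixation_sample", class(out)))
}

#' @rdname run_replicates
#' @param x A `fixation_sample`.
#' @param ... Unused.
#' @export
glance.fixation_sample <- function(x, ...) {
  p <- attr(x, "params")
  dplyr::bind_cols(
    tibble::tibble(topology = p$topology, size = p$n, p0 = p$p0,
                   n_reps = nrow(x),
                   fixed_A = sum(x$fixed_allele == "A", na.rm = TRUE)),
    t_ave(x))
}

#' Sweep population sizes and topologies
#'
#' Runs fixation-time batteries over a grid of (topology, lattice size)
#' cells, computes the mean fixation time per cell, fits the T_ave-versus-N
#' proportionality per topology, and reports equivalent-size ratios relative
#' to panmixia.
#'
#' @param topologies Character vector of topologies.
#' @param sizes Integer vector of lattice side lengths (at least 2 per
#'   topology); cell population size is `side^2`.
#' @param n_reps Replicates per cell.
#' @param base_seed Base seed (per-replicate seeds also fold in topology and
#'   size, so cells are independent of execution order).
#' @param p0 Initial allele-A probability.
#' @return A `sweep_result`: list with `cells` (tibble: `topology`, `side`,
#'   `size`, `n_reps`, `t_ave`, `se`, `capped`), `slopes` (tibble:
#'   `topology`, `slope`, `slope_ols`, `ratio_vs_gnf` when panmixia is in the
#'   sweep) and `fits` (named list of `slope_fit`s).
#' @export
sweep_sizes <- function(topologies = c("g4", "g6", "g8", "gnf"),
                        sizes = c(10, 20, 30), n_reps = 200,
                        base_seed = 1L, p0 = 0.5) {
  topologies <- vapply(topologies, match_topology, character(1),
                       USE.NAMES = FALSE)
  if (length(sizes) < 2L) {
    stop("need at least 2 lattice sizes per topology to fit a slope",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(topology = topologies, side = as.integer(sizes))
  cells <- purrr::pmap(grid, function(topology, side) {
    params <- sim_params(size = side, topology = topology, p0 = p0)
    fs <- run_replicates(params, n_reps, base_seed)
    ta <- t_ave(fs)
    tibble::tibble(topology = topology, side = side, size = side^2L,
                   n_reps = n_reps, t_ave = ta$t_ave, se = ta$se,
                   capped = ta$excluded)
  }) |> dplyr::bind_rows()
  fits <- cells |>
    dplyr::group_by(.data$topology) |>
    dplyr::group_map(~ fit_slope(.x)) |>
    stats::setNames(sort(unique(cells$topology)))
  # group_map orders groups alphabetically; rebuild in requested order
  fits <- fits[topologies]
  slopes <- tibble::tibble(
    topology = topologies,
    slope = unname(vapply(fits, function(f) f$slope, numeric(1))),
    slope_ols = unname(vapply(fits, function(f) f$slope_ols, numeric(1))))
  if ("gnf" %in% topologies) {
    slopes$ratio_vs_gnf <- size_ratio(slopes$slope,
                                      slopes$slope[slopes$topology == "gnf"])
  }
  structure(list(cells = cells, slopes = slopes, fits = fits,
                 n_reps = n_reps, base_seed = base_seed, p0 = p0),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", length(unique(x$cells$topology)), " topologies x ",
      length(unique(x$cells$size)), " sizes, ", x$n_reps,
      " replicates per cell\n", sep = "")
  print(x$slopes)
  invisible(x)
}

#' @rdname sweep_sizes
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @export
tidy.sweep_result <- function(x, ...) x$cells

#' @rdname sweep_sizes
#' @export
glance.sweep_result <- function(x, ...) x$slopes

#' Mean heterozygosity trajectories
#'
#' Tracks mean observed heterozygosity per generation across replicates for
#' each topology. A replicate that fixes before the horizon contributes
#' `H = 0` from its fixation generation onwards (fixation is absorbing).
#'
#' @param topologies Character vector of topologies.
#' @param size Lattice side length (population `size^2`).
#' @param n_reps Replicates per topology.
#' @param horizon Last generation tracked (inclusive; generation 0 is the
#'   initial state).
#' @param base_seed Base seed for [replicate_seed()].
#' @param p0 Initial allele-A probability.
#' @return Tibble with `topology`, `generation`, `mean_H`, `se` (across
#'   replicates) and `n_reps`.
#' @export
heterozygosity_curves <- function(topologies = c("g4", "g6", "g8", "gnf"),
                                  size = 20, n_reps = 200, horizon = 200,
                                  base_seed = 1L, p0 = 0.5) {
  topologies <- vapply(topologies, match_topology, character(1),
                       USE.NAMES = FALSE)
  stopifnot(horizon >= 0)
  n <- as.integer(size)^2L
  purrr::map(topologies, function(topo) {
    nbr <- nbr_for_cpp(size, size, topo)
    hmat <- matrix(0, nrow = n_reps, ncol = horizon + 1L)
    for (i in seq_len(n_reps)) {
      set.seed(replicate_seed(base_seed, topo, n, i))
      g0 <- stats::rbinom(n, 2L, p0)
      r <- cpp_run(g0, nbr$mat, nbr$panmictic, as.integer(horizon), TRUE)
      h <- (r$series_Aa / n)[seq_len(min(horizon + 1L, length(r$series_Aa)))]
      # pad with 0 after fixation: the run is absorbed, not truncated
      hmat[i, seq_along(h)] <- h
    }
    tibble::tibble(
      topology = topo, generation = 0:horizon,
      mean_H = colMeans(hmat),
      se = apply(hmat, 2, stats::sd) / sqrt(n_reps),
      n_reps = n_reps)
  }) |> dplyr::bind_rows()
}
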