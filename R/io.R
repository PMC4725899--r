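#' Write a trajectory to CSV with a JSON sidecar
#'
#' The CSV holds the per-generation counts (`generation, n_AA, n_Aa, n_aa,
#' f_A`); the sidecar (`<path>.json`) records the full parameter set, seed,
#' fixation outcome and package version, so the run is reconstructible from
#' its outputs alone.
#'
#' @param traj A `drift_trajectory` run with `record = TRUE`.
#' @param path Output CSV path.
#' @return Invisibly, the two file paths.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "drift_trajectory"))
  df <- tidy(traj)[, c("generation", "n_AA", "n_Aa", "n_aa", "f_A")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- paste0(path, ".json")
  p <- traj$params
  jsonlite::write_json(list(
    rows = p$rows, cols = p$cols, topology = p$topology, p0 = p$p0,
    seed = p$seed, max_generations = p$max_generations,
    t_h = traj$t_h, fixed_allele = traj$fixed_allele, capped = traj$capped,
    engine = as.character(utils::packageVersion("driftlattice"))),
    side, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(csv = path, json = side))
}

#' Read/write a grid snapshot
#'
#' Snapshots are CSV matrices of allele-A copy numbers per site (0, 1 or 2),
#' enabling external plotting of genotype maps.
#'
#' @param grid A `population_grid`.
#' @param path CSV path.
#' @param topology Topology to attach when reading.
#' @return `write_grid_snapshot`: the path, invisibly. `read_grid_snapshot`:
#'   a `population_grid`.
#' @export
write_grid_snapshot <- function(grid, path) {
  stopifnot(inherits(grid, "population_grid"))
  utils::write.table(unclass(grid), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_snapshot
#' @export
read_grid_snapshot <- function(path, topology = "g4") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!all(m %in% 0:2)) stop("snapshot values must be 0, 1 or 2", call. = FALSE)
  new_population_grid(as.integer(t(m)), nrow(m), ncol(m),
                      match_topology(topology))
}

#' Read fixation-time samples from a text file
#'
#' Accepts either one value per line, or a delimited file with a `t_h`
#' column.
#'
#' @param path Input file.
#' @return Numeric vector of fixation times.
#' @export
read_fixation_times <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty input file: ", path, call. = FALSE)
  if (grepl("t_h", first, fixed = TRUE)) {
    df <- utils::read.csv(path)
    x <- df[["t_h"]]
  } else {
    x <- scan(path, what = numeric(), quiet = TRUE, sep = if (grepl(",", first)) "," else "")
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop("non-positive or non-numeric fixation times at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  as.numeric(x)
}
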