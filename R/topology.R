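#' Mate-choice topologies
#'
#' Four mate-choice regimes are supported on a periodic `rows x cols` lattice:
#'
#' * `"g4"` — von Neumann neighbourhood: the 4 orthogonal nearest sites.
#' * `"g6"` — hexagonal neighbourhood: even-numbered rows are treated as
#'   shifted left by half a cell, giving every site 6 nearest sites. Requires
#'   an even number of rows so the shift wraps consistently across the
#'   periodic seam.
#' * `"g8"` — Moore neighbourhood: the 8 orthogonal and diagonal nearest
#'   sites.
#' * `"gnf"` — panmixia: every other individual in the population.
#'
#' @name topologies
#' @keywords internal
NULL

TOPOLOGIES <- c("g4", "g6", "g8", "gnf")

match_topology <- function(topology) {
  if (!is.character(topology) || length(topology) != 1L) {
    stop("`topology` must be one of ", paste(TOPOLOGIES, collapse = ", "),
         call. = FALSE)
  }
  match.arg(tolower(topology), TOPOLOGIES)
}

#' Validate lattice dimensions for a topology
#'
#' @param rows,cols Lattice dimensions; both must be at least 2 so every site
#'   has a distinct neighbour in each direction.
#' @param topology One of `"g4"`, `"g6"`, `"g8"`, `"gnf"`.
#' @return Invisibly, a list with `rows`, `cols` and the canonical topology
#'   name.
#' @export
check_lattice <- function(rows, cols, topology = "g4") {
  topology <- match_topology(topology)
  if (!is.numeric(rows) || !is.numeric(cols) ||
      length(rows) != 1L || length(cols) != 1L ||
      rows != as.integer(rows) || cols != as.integer(cols) ||
      rows < 2 || cols < 2) {
    stop("lattice dimensions must be integers >= 2", call. = FALSE)
  }
  if (topology == "g6" && as.integer(rows) %% 2L != 0L) {
    stop("the hexagonal topology (g6) requires an even number of rows ",
         "so the half-cell row shift wraps consistently", call. = FALSE)
  }
  invisible(list(rows = as.integer(rows), cols = as.integer(cols),
                 topology = topology))
}

# 1-based periodic wrap
wrap_index <- function(x, n) ((x - 1L) %% n) + 1L

# Row-major linear index of (row, col) after periodic wrap, 1-based.
site_index <- function(row, col, rows, cols) {
  (wrap_index(as.integer(row), rows) - 1L) * cols +
    wrap_index(as.integer(col), cols)
}

# Neighbour offsets in the fixed order W, E, N, S (+ NW, NE, SW, SE for g8).
# For g6 the vertical neighbours depend on row parity because even rows sit
# half a cell to the left.
neighbor_index_matrix <- function(rows, cols, topology) {
  cfg <- check_lattice(rows, cols, topology)
  rows <- cfg$rows; cols <- cfg$cols; topology <- cfg$topology
  if (topology == "gnf") return(NULL)
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  idx <- function(rr, cc) site_index(rr, cc, rows, cols)
  if (topology == "g4") {
    m <- cbind(idx(r, c - 1L), idx(r, c + 1L), idx(r - 1L, c), idx(r + 1L, c))
  } else if (topology == "g8") {
    m <- cbind(idx(r, c - 1L), idx(r, c + 1L), idx(r - 1L, c), idx(r + 1L, c),
               idx(r - 1L, c - 1L), idx(r - 1L, c + 1L),
               idx(r + 1L, c - 1L), idx(r + 1L, c + 1L))
  } else {
    odd <- r %% 2L == 1L
    up1 <- ifelse(odd, idx(r - 1L, c), idx(r - 1L, c - 1L))
    up2 <- ifelse(odd, idx(r - 1L, c + 1L), idx(r - 1L, c))
    dn1 <- ifelse(odd, idx(r + 1L, c), idx(r + 1L, c - 1L))
    dn2 <- ifelse(odd, idx(r + 1L, c + 1L), idx(r + 1L, c))
    m <- cbind(idx(r, c - 1L), idx(r, c + 1L), up1, up2, dn1, dn2)
  }
  storage.mode(m) <- "integer"
  m
}

# 0-based neighbour matrix + panmictic flag, in the form the C++ core takes
nbr_for_cpp <- function(rows, cols, topology) {
  nbr <- neighbor_index_matrix(rows, cols, topology)
  if (is.null(nbr)) {
    list(mat = matrix(integer(), nrow = rows * cols, ncol = 0),
         panmictic = TRUE)
  } else {
    list(mat = nbr - 1L, panmictic = FALSE)
  }
}

#' Candidate-mate sites of a lattice site
#'
#' Returns the ordered candidate-mate set of a focal site under one of the
#' four mate-choice topologies, with periodic wrap at the lattice edges. The
#' focal site is never a candidate (no selfing). On very small lattices a
#' geometric direction can wrap onto the same site as another; such duplicate
#' entries are kept so every direction retains equal selection probability.
#'
#' @param row,col 1-based coordinates of the focal site.
#' @param topology One of `"g4"`, `"g6"`, `"g8"`, `"gnf"`.
#' @param rows,cols Lattice dimensions.
#' @return A tibble with columns `row` and `col`, one row per candidate mate,
#'   in a fixed deterministic order: W, E, N, S (then NW, NE, SW, SE for
#'   `"g8"`); the two upper then two lower hex neighbours for `"g6"`;
#'   row-major order over all other sites for `"gnf"`.
#' @examples
#' neighbors(1, 5, "g4", 10, 10)
#' @export
neighbors <- function(row, col, topology, rows, cols) {
  cfg <- check_lattice(rows, cols, topology)
  if (length(row) != 1L || length(col) != 1L ||
      row < 1 || row > cfg$rows || col < 1 || col > cfg$cols ||
      row != as.integer(row) || col != as.integer(col)) {
    stop("site (", row, ", ", col, ") is out of bounds for a ",
         cfg$rows, "x", cfg$cols, " lattice", call. = FALSE)
  }
  if (cfg$topology == "gnf") {
    self <- site_index(row, col, cfg$rows, cfg$cols)
    lin <- setdiff(seq_len(cfg$rows * cfg$cols), self)
  } else {
    nbr <- neighbor_index_matrix(cfg$rows, cfg$cols, cfg$topology)
    lin <- nbr[site_index(row, col, cfg$rows, cfg$cols), ]
  }
  tibble::tibble(row = ((lin - 1L) %/% cfg$cols) + 1L,
                 col = ((lin - 1L) %% cfg$cols) + 1L)
}

#' Draw a uniform random mate for a site
#'
#' Draws one candidate uniformly from [neighbors()]. Uses R's global RNG, so
#' `set.seed()` makes draws reproducible.
#'
#' @inheritParams neighbors
#' @return A one-row tibble with columns `row` and `col`.
#' @export
random_mate <- function(row, col, topology, rows, cols) {
  nb <- neighbors(row, col, topology, rows, cols)
  nb[sample.int(nrow(nb), 1L), ]
}
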