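#' Label homozygous genotype clusters
#'
#' Spatially constrained drift produces growing patches of identical
#' homozygotes with heterozygotes along their boundaries. This labels the
#' connected components of the lattice-adjacency graph restricted to edges
#' between neighbouring sites of the same homozygous genotype, with periodic
#' wrap (a cluster may span the seam). Heterozygotes are never cluster
#' members and keep label 0. Adjacency uses the same topology as mating,
#' which must be spatial (`"gnf"` has no adjacency).
#'
#' @param grid A `population_grid`.
#' @param topology `"g4"`, `"g6"` or `"g8"`; defaults to the grid's own.
#' @return A `cluster_labeling`: list with `label` (integer matrix, 0 for
#'   heterozygotes, dense positive labels in row-major first-encounter
#'   order), `clusters` (tibble of `label`, `genotype`, `size`) and
#'   `n_het`.
#' @export
label_clusters <- function(grid, topology = NULL) {
  stopifnot(inherits(grid, "population_grid"))
  topology <- match_topology(topology %||% attr(grid, "topology"))
  if (topology == "gnf") {
    stop("cluster analysis needs a spatial topology (g4, g6 or g8); ",
         "panmixia has no lattice adjacency", call. = FALSE)
  }
  rows <- nrow(grid); cols <- ncol(grid)
  g <- as.integer(t(unclass(grid)))  # row-major
  nbr <- neighbor_index_matrix(rows, cols, topology)
  homo <- g != 1L
  # same-genotype homozygous edges, undirected, via igraph components
  from <- rep(seq_along(g), times = ncol(nbr))
  to <- as.vector(nbr)
  keep <- homo[from] & homo[to] & g[from] == g[to] & from < to
  gr <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, length(g) - igraph::vcount(gr)))
  comp <- igraph::components(gr)$membership
  # dense labels in row-major first-encounter order over homozygous sites
  lab <- integer(length(g))
  comp_label <- integer(max(comp))
  nxt <- 0L
  for (i in seq_along(g)) {
    if (!homo[i]) next
    ci <- comp[i]
    if (comp_label[ci] == 0L) { nxt <- nxt + 1L; comp_label[ci] <- nxt }
    lab[i] <- comp_label[ci]
  }
  sizes <- tabulate(lab[lab > 0L])
  geno <- character(length(sizes))
  geno[lab[lab > 0L]] <- ifelse(g[lab > 0L] == 2L, "AA", "aa")
  structure(list(
    label = matrix(lab, nrow = rows, ncol = cols, byrow = TRUE),
    clusters = tibble::tibble(label = seq_along(sizes), genotype = geno,
                              size = sizes),
    n_het = sum(!homo), topology = topology),
    class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat("<cluster_labeling> ", nrow(x$label), "x", ncol(x$label), " (",
      x$topology, "): ", nrow(x$clusters), " homozygous clusters, ",
      x$n_het, " heterozygotes\n", sep = "")
  if (nrow(x$clusters) > 0) {
    cat("  largest cluster: ", max(x$clusters$size), " sites\n", sep = "")
  }
  invisible(x)
}

#' @rdname label_clusters
#' @param x A `cluster_labeling`.
#' @param ... Unused.
#' @export
tidy.cluster_labeling <- function(x, ...) x$clusters

#' Fraction of heterozygotes on cluster boundaries
#'
#' Heterozygotes act as the interface between opposite homozygous clusters:
#' only matings at these boundaries can change the population allele
#' frequency. Two statistics are returned: `frac_between` -- the fraction of
#' heterozygous sites with at least one AA neighbour and at least one aa
#' neighbour (strictly between opposite clusters) -- and `frac_adjacent` --
#' the fraction adjacent to any homozygote at all.
#'
#' @inheritParams label_clusters
#' @return One-row tibble with `frac_between`, `frac_adjacent`, `n_het` and
#'   `no_heterozygotes` (flag; both fractions are 0 when there are none).
#' @export
boundary_heterozygote_fraction <- function(grid, topology = NULL) {
  stopifnot(inherits(grid, "population_grid"))
  topology <- match_topology(topology %||% attr(grid, "topology"))
  if (topology == "gnf") {
    stop("boundary analysis needs a spatial topology (g4, g6 or g8)",
         call. = FALSE)
  }
  g <- as.integer(t(unclass(grid)))
  nbr <- neighbor_index_matrix(nrow(grid), ncol(grid), topology)
  het <- which(g == 1L)
  if (length(het) == 0L) {
    return(tibble::tibble(frac_between = 0, frac_adjacent = 0, n_het = 0L,
                          no_heterozygotes = TRUE))
  }
  nb_g <- matrix(g[nbr[het, , drop = FALSE]], nrow = length(het))
  has_AA <- rowSums(nb_g == 2L) > 0
  has_aa <- rowSums(nb_g == 0L) > 0
  tibble::tibble(
    frac_between = mean(has_AA & has_aa),
    frac_adjacent = mean(has_AA | has_aa),
    n_het = length(het), no_heterozygotes = FALSE)
}

#' Cluster-size histogram
#'
#' Counts homozygous clusters by size, split by genotype.
#'
#' @param labeling A `cluster_labeling` from [label_clusters()].
#' @return Tibble with `genotype`, `size` and `n_clusters`.
#' @export
cluster_size_distribution <- function(labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  labeling$clusters |>
    dplyr::count(.data$genotype, .data$size, name = "n_clusters") |>
    dplyr::arrange(.data$genotype, .data$size)
}
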