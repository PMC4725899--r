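# Independent oracles, deliberately written without reusing package internals.

# plain offset enumeration with modular wrap
oracle_neighbors <- function(row, col, topology, rows, cols) {
  w <- function(r, c) c(((r - 1) %% rows) + 1, ((c - 1) %% cols) + 1)
  offs <- switch(topology,
    g4 = list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0)),
    g8 = list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0),
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)),
    g6 = if (row %% 2 == 1) {
      list(c(0, -1), c(0, 1), c(-1, 0), c(-1, 1), c(1, 0), c(1, 1))
    } else {
      list(c(0, -1), c(0, 1), c(-1, -1), c(-1, 0), c(1, -1), c(1, 0))
    },
    stop("spatial topologies only"))
  do.call(rbind, lapply(offs, function(o) w(row + o[1], col + o[2])))
}

# breadth-first flood fill over same-genotype homozygous components
oracle_flood_fill <- function(mat, topology) {
  rows <- nrow(mat); cols <- ncol(mat)
  lab <- matrix(0L, rows, cols)
  nxt <- 0L
  for (r0 in seq_len(rows)) for (c0 in seq_len(cols)) {
    if (mat[r0, c0] == 1L || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- oracle_neighbors(cur[1], cur[2], topology, rows, cols)
      for (i in seq_len(nrow(nb))) {
        r <- nb[i, 1]; c <- nb[i, 2]
        if (lab[r, c] == 0L && mat[r, c] == mat[cur[1], cur[2]] &&
            mat[r, c] != 1L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# sorted multisets of cluster sizes per homozygous genotype
label_sizes <- function(lab, mat) {
  keep <- lab != 0L
  if (!any(keep)) return(list(AA = integer(0), aa = integer(0)))
  sz <- stats::aggregate(list(n = rep(1L, sum(keep))),
                         by = list(lab = lab[keep], g = mat[keep]), FUN = sum)
  list(AA = sort(sz$n[sz$g == 2L]), aa = sort(sz$n[sz$g == 0L]))
}

# --- exact 2x2 panmictic genotype-configuration chain (3^4 = 81 states) ----

gamete_dist <- function(g) switch(g + 1L, c(1, 0), c(0.5, 0.5), c(0, 1))

cross_dist <- function(ga, gb) {
  a <- gamete_dist(ga); b <- gamete_dist(gb)
  c(a[1] * b[1], a[1] * b[2] + a[2] * b[1], a[2] * b[2])
}

state_configs <- function() as.matrix(expand.grid(rep(list(0:2), 4)))

# per-site offspring distributions (4 x 3) given a parental configuration,
# mate uniform over the 3 other sites
site_offspring_dists <- function(g) {
  t(vapply(1:4, function(i) {
    rowMeans(vapply(setdiff(1:4, i), function(j) cross_dist(g[i], g[j]),
                    numeric(3)))
  }, numeric(3)))
}

oracle_2x2_transition <- function() {
  states <- state_configs()
  n <- nrow(states)
  P <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- site_offspring_dists(states[s, ])
    for (s2 in seq_len(n)) {
      P[s, s2] <- prod(d[cbind(1:4, states[s2, ] + 1L)])
    }
  }
  P
}

# expected absorption time from the binomial-initiation distribution at p0
oracle_2x2_mean_absorption <- function(p0 = 0.5) {
  states <- state_configs()
  P <- oracle_2x2_transition()
  absorbing <- apply(states, 1, function(g) all(g == 0L) || all(g == 2L))
  Q <- P[!absorbing, !absorbing]
  t_abs <- numeric(nrow(states))
  t_abs[!absorbing] <- solve(diag(nrow(Q)) - Q, rep(1, nrow(Q)))
  site_p <- stats::dbinom(0:2, 2, p0)
  p_state <- apply(states, 1, function(g) prod(site_p[g + 1L]))
  sum(p_state * t_abs)
}

# exact one-step distribution of (n_AA, n_Aa, n_aa) from one configuration
oracle_2x2_onestep_counts <- function(g) {
  states <- state_configs()
  d <- site_offspring_dists(g)
  probs <- apply(states, 1, function(s2) prod(d[cbind(1:4, s2 + 1L)]))
  key <- apply(states, 1, function(s2) {
    paste(sum(s2 == 2L), sum(s2 == 1L), sum(s2 == 0L), sep = "/")
  })
  tapply(probs, key, sum)
}

# inverse-Gaussian sampler via the Michael-Schucany-Haas transform
oracle_rinvgauss <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# grid builder from a row-major genotype vector
make_grid <- function(g, rows, cols, topology = "g4") {
  p <- sim_params(rows = rows, cols = cols, topology = topology, p0 = 0.5)
  grid <- initialize_population(p)
  grid[] <- matrix(as.integer(g), nrow = rows, ncol = cols, byrow = TRUE)
  grid
}
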