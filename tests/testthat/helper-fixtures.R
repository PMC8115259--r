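# Shared fixtures and independent oracles. Everything is generated in code;
# oracles are deliberately naive (loops, exhaustive enumeration) and stay
# independent of the implementation paths they check.

tiny_table <- function(m = NULL, relative = FALSE) {
  if (is.null(m)) {
    m <- matrix(c(1, 0, 2, 3), 2, 2,
                dimnames = list(c("ASV_1", "ASV_2"), c("S1", "S2")))
  }
  abundance_table(m, relative = relative)
}

random_table <- function(n_asv = 12, n_sample = 8, seed = 1,
                         sparsity = 0.3) {
  set.seed(seed)
  m <- matrix(rpois(n_asv * n_sample, 15), n_asv, n_sample)
  m[runif(n_asv * n_sample) < sparsity] <- 0
  dimnames(m) <- list(sprintf("ASV_%03d", seq_len(n_asv)),
                      sprintf("S%03d", seq_len(n_sample)))
  abundance_table(m)
}

# exhaustive MIC: enumerate every pair of axis partitions with
# nx * ny <= B and maximize normalized mutual information directly
mic_brute_force <- function(x, y, B) {
  n <- length(x)
  ox <- order(x); oy <- order(y)
  xgaps <- which(diff(x[ox]) > 0)
  ygaps <- which(diff(y[oy]) > 0)
  assign_bins <- function(ord, cuts) {
    bounds <- c(cuts, n)
    ids <- rep(seq_along(bounds), times = diff(c(0, bounds)))
    b <- integer(n)
    b[ord] <- ids
    b
  }
  best <- 0
  for (nx in 2:floor(B / 2)) {
    for (ny in 2:floor(B / nx)) {
      if (length(xgaps) < nx - 1 || length(ygaps) < ny - 1) next
      xc <- utils::combn(xgaps, nx - 1)
      yc <- utils::combn(ygaps, ny - 1)
      for (i in seq_len(ncol(xc))) {
        bx <- assign_bins(ox, xc[, i])
        for (j in seq_len(ncol(yc))) {
          by <- assign_bins(oy, yc[, j])
          p <- tabulate((bx - 1L) * ny + by, nbins = nx * ny) / n
          px <- tapply(p, rep(seq_len(nx), each = ny), sum)
          py <- tapply(p, rep(seq_len(ny), times = nx), sum)
          ep <- as.vector(outer(py, px))
          nz <- p > 0
          mi <- sum(p[nz] * log2(p[nz] / ep[nz]))
          v <- mi / log2(min(nx, ny))
          if (v > best) best <- v
        }
      }
    }
  }
  best
}

# naive per-ASV presence counting (oracle for prevalence/taxonomic_core)
prevalence_naive <- function(table) {
  m <- table$counts
  out <- numeric(nrow(m))
  names(out) <- rownames(m)
  for (i in seq_len(nrow(m))) {
    k <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] > 0) k <- k + 1
    out[i] <- k / ncol(m)
  }
  out
}

# triple-nested-loop metagenome prediction (oracle for predict_metagenome)
predict_naive <- function(table, gc, normalize_16s = TRUE) {
  m <- table$counts
  kos <- colnames(gc$ko)
  out <- matrix(0, length(kos), ncol(m),
                dimnames = list(kos, colnames(m)))
  for (k in seq_along(kos)) {
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (a in rownames(m)) {
        v <- m[a, j]
        if (normalize_16s) v <- v / gc$copies_16s[[a]]
        acc <- acc + v * gc$ko[a, kos[k]]
      }
      out[k, j] <- acc
    }
  }
  out
}

# mean silhouette width over Euclidean distances of a coordinate matrix
silhouette_mean <- function(coords, groups) {
  d <- as.matrix(stats::dist(coords))
  groups <- as.character(groups)
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
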