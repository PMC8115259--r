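# Beta-diversity and the hypothesis tests comparing taxonomic and
# functional core rhizobiomes. Normalization is total-sum scaling
# (proportions); samples are never rarefied. Permutation p-values use the
# (1 + #{stat_perm >= stat_obs}) / (1 + n_permutations) estimator.

make_dm <- function(mat, metric) {
  d <- stats::as.dist(mat)
  attr(d, "metric") <- metric
  d
}

#' Convert counts to relative abundances (total-sum scaling)
#'
#' @param table an [abundance_table()]; all-zero samples are an error.
#' @return the table with columns summing to 1 and the relative flag set;
#'   already-relative input is returned unchanged.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$relative) return(table)
  cs <- colSums(table$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(colnames(table$counts)[cs == 0], collapse = ", "))
  abundance_table(sweep(table$counts, 2, cs, "/"),
                  metadata = table$metadata, relative = TRUE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`.
#'
#' @param table an [abundance_table()] (counts or relative) with >= 2
#'   samples; two all-zero samples make the pair undefined and are an
#'   error.
#' @return a `dist` object with `attr(, "metric") = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (sum(colSums(m) == 0) >= 2)
    stop("two or more all-zero samples: Bray-Curtis undefined for the pair")
  n <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      num <- sum(abs(m[, j] - m[, k]))
      den <- sum(m[, j] + m[, k])
      D[j, k] <- D[k, j] <- num / den
    }
  }
  make_dm(D, "bray_curtis")
}

#' Unweighted UniFrac distance between samples
#'
#' `d(j, k)` = (branch length covered by exactly one of the two samples'
#' presence sets) / (branch length covered by their union); presence is
#' count > 0.
#'
#' @param table an [abundance_table()]; every ASV must be a tree tip.
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return a `dist` object with `attr(, "metric") = "unweighted_unifrac"`.
#' @export
unweighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "abundance_table"), inherits(tree, "phylo"))
  missing <- setdiff(asv_ids(table), tree$tip.label)
  if (length(missing))
    stop("ASV(s) missing from tree: ", paste(missing, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_vert <- n_tip + tr$Nnode
  edge <- tr$edge
  len <- tr$edge.length
  # descendant-tip membership per vertex, accumulated in postorder
  vert <- matrix(FALSE, n_vert, n_tip)
  vert[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  edge_tips <- matrix(FALSE, nrow(edge), n_tip)
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2]
    edge_tips[e, ] <- vert[child, ]
    vert[edge[e, 1], ] <- vert[edge[e, 1], ] | vert[child, ]
  }
  pres <- matrix(FALSE, n_tip, ncol(table$counts),
                 dimnames = list(tr$tip.label, colnames(table$counts)))
  pres[asv_ids(table), ] <- table$counts > 0
  covered <- (edge_tips %*% pres) > 0     # edges x samples
  n <- ncol(pres)
  D <- matrix(0, n, n, dimnames = list(colnames(pres), colnames(pres)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      un <- sum(len[covered[, j] | covered[, k]])
      uq <- sum(len[xor(covered[, j], covered[, k])])
      D[j, k] <- D[k, j] <- if (un > 0) uq / un else 0
    }
  }
  make_dm(D, "unweighted_unifrac")
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers `-D^2 / 2` and eigendecomposes; coordinates are built
#' from positive eigenvalues only, and negative eigenvalues are dropped
#' with a log message.
#'
#' @param dm a `dist` or symmetric distance matrix over >= 3 samples.
#' @return class `pcoa_result` with `coordinates` (samples x axes),
#'   `eigenvalues` (non-increasing, positive), and `proportion_explained`.
#' @export
pcoa <- function(dm) {
  D <- as.matrix(dm)
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples")
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-10
  pos <- e$values > tol
  n_neg <- sum(e$values < -tol)
  if (n_neg) message(n_neg, " negative eigenvalue(s) dropped in PCoA")
  vals <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals), nrow = sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 proportion_explained = vals / sum(vals)),
            class = "pcoa_result")
}

check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("`groups` must have one label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  groups
}

dist_pairs <- function(n) {
  ii <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)
  list(ii = ii, jj = jj)
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n (n - 1) / 2` distance pairs; midranks for ties. The p-value is
#' `(1 + #{R_perm >= R_obs}) / (1 + n_permutations)` over seeded label
#' permutations.
#'
#' @param dm a `dist` or symmetric distance matrix.
#' @param groups group labels, >= 2 groups each of size >= 2.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return class `anosim_result`: `R`, `p`, `n_permutations`, `seed`.
#' @export
anosim <- function(dm, groups, n_permutations = 999, seed = 1) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  groups <- check_groups(groups, n)
  rk <- rank(as.vector(d))   # midrank convention
  pr <- dist_pairs(n)
  M <- length(rk)
  stat <- function(g) {
    within <- g[pr$ii] == g[pr$jj]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  set.seed(seed)
  R_perm <- vapply(seq_len(n_permutations),
                   function(b) stat(groups[sample.int(n)]), numeric(1))
  p <- (1 + sum(R_perm >= R_obs)) / (n_permutations + 1)
  structure(list(R = R_obs, p = p, n_permutations = n_permutations,
                 seed = seed), class = "anosim_result")
}

#' Permutational multivariate ANOVA (PERMANOVA / Adonis)
#'
#' One-way partitioning of the squared-distance variance:
#' `SS_total = sum d^2 / n` over all pairs, `SS_within` from within-group
#' pairs scaled by group size, `R^2 = SS_between / SS_total`,
#' `F = (SS_between / (a - 1)) / (SS_within / (n - a))`; permutation
#' p-value on F as in [anosim()].
#'
#' @inheritParams anosim
#' @return class `permanova_result`: `R2`, `F`, `p`, `n_permutations`,
#'   `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  groups <- check_groups(groups, n)
  d2 <- as.vector(d)^2
  pr <- dist_pairs(n)
  a <- nlevels(groups)
  SS_T <- sum(d2) / n
  ss_w <- function(g) {
    within <- g[pr$ii] == g[pr$jj]
    sizes <- tabulate(g)
    sum(vapply(seq_len(a), function(lv) {
      sel <- within & (unclass(g)[pr$ii] == lv)
      sum(d2[sel]) / sizes[lv]
    }, numeric(1)))
  }
  f_stat <- function(g) {
    SS_W <- ss_w(g)
    SS_B <- SS_T - SS_W
    (SS_B / (a - 1)) / (SS_W / (n - a))
  }
  SS_W <- ss_w(groups)
  R2 <- (SS_T - SS_W) / SS_T
  F_obs <- f_stat(groups)
  set.seed(seed)
  F_perm <- vapply(seq_len(n_permutations),
                   function(b) f_stat(groups[sample.int(n)]), numeric(1))
  p <- (1 + sum(F_perm >= F_obs)) / (n_permutations + 1)
  structure(list(R2 = R2, F = F_obs, p = p,
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' @param table an [abundance_table()].
#' @param taxonomy a [taxonomy_table()] covering every ASV in `table`.
#' @param rank one of the names in [taxonomy_ranks()] (typically
#'   `"phylum"` or `"genus"`); the `"unassigned"` bucket is preserved.
#' @return a [function_table()] whose level is the rank; per-sample totals
#'   are conserved.
#' @export
aggregate_rank <- function(table, taxonomy, rank = "phylum") {
  stopifnot(inherits(table, "abundance_table"),
            inherits(taxonomy, "taxonomy_table"))
  rank <- match.arg(rank, taxonomy_ranks())
  missing <- setdiff(asv_ids(table), taxonomy$asv_id)
  if (length(missing))
    stop("ASV(s) missing from taxonomy: ", paste(missing, collapse = ", "))
  labels <- taxonomy[asv_ids(table), rank]
  agg <- rowsum(table$counts, group = labels)
  function_table(agg, level = rank)
}

#' Welch's t-test with Benjamini-Hochberg correction across features
#'
#' One Welch t-test per feature (Welch-Satterthwaite df), BH step-up
#' adjustment over all tested features. Features with fewer than 2
#' observations in a group, or zero variance in both groups with unequal
#' means, are skipped with a log message.
#'
#' @param features_a,features_b feature x sample matrices or
#'   [function_table()] objects for the two groups; features are matched by
#'   name on the union (absent = 0).
#' @param alpha significance level on the adjusted q-values (default 0.05).
#' @return data.frame: `feature`, `mean_pct_a`, `mean_pct_b` (group means
#'   in percent, assuming proportion-scale input), `welch_t`, `df`,
#'   `p_raw`, `q_bh`, `significant`.
#' @export
welch_bh <- function(features_a, features_b, alpha = 0.05) {
  get_mat <- function(x) {
    if (inherits(x, "function_table")) x$abundances
    else if (inherits(x, "abundance_table")) x$counts
    else x
  }
  A <- get_mat(features_a)
  B <- get_mat(features_b)
  feats <- union(rownames(A), rownames(B))
  full <- function(m) {
    out <- matrix(0, length(feats), ncol(m),
                  dimnames = list(feats, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  A <- full(A); B <- full(B)
  nx <- ncol(A); ny <- ncol(B)
  if (nx < 2 || ny < 2) stop("each group needs >= 2 samples")
  res <- lapply(feats, function(f) {
    x <- A[f, ]; y <- B[f, ]
    vx <- stats::var(x); vy <- stats::var(y)
    mx <- mean(x); my <- mean(y)
    if (vx == 0 && vy == 0) {
      if (mx == my)
        return(data.frame(feature = f, mean_pct_a = 100 * mx,
                          mean_pct_b = 100 * my, welch_t = 0,
                          df = nx + ny - 2, p_raw = 1))
      message("feature '", f, "' skipped: zero variance in both groups")
      return(NULL)
    }
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    data.frame(feature = f, mean_pct_a = 100 * mx, mean_pct_b = 100 * my,
               welch_t = t, df = df,
               p_raw = 2 * stats::pt(-abs(t), df))
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(feature = character(0), mean_pct_a = numeric(0),
                      mean_pct_b = numeric(0), welch_t = numeric(0),
                      df = numeric(0), p_raw = numeric(0),
                      q_bh = numeric(0), significant = logical(0)))
  res$q_bh <- stats::p.adjust(res$p_raw, method = "BH")
  res$significant <- res$q_bh < alpha
  rownames(res) <- NULL
  res
}
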