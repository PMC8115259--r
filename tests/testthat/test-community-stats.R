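test_that("relative_abundance normalizes columns and flags errors", {
  tab <- tiny_table(matrix(c(2, 2, 0, 5), 2, 2,
                           dimnames = list(c("a", "b"), c("S1", "S2"))))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel$counts[, "S1"]), c(0.5, 0.5))
  expect_equal(unname(rel$counts[, "S2"]), c(0, 1))
  expect_true(rel$relative)
  expect_identical(relative_abundance(rel), rel)
  zero <- tiny_table(matrix(c(1, 1, 0, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("S1", "S2"))))
  expect_error(relative_abundance(zero), "S2")
})

test_that("Bray-Curtis matches the formula and vegan", {
  m <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  d <- as.matrix(bray_curtis(abundance_table(m)))
  expect_equal(d["x", "y"], 1)      # disjoint supports
  expect_equal(d["x", "z"], 0)      # identical columns
  tab <- random_table(n_asv = 20, n_sample = 9, seed = 3)
  d1 <- bray_curtis(relative_abundance(tab))
  d2 <- vegan::vegdist(t(relative_abundance(tab)$counts), method = "bray")
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
  zz <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
               dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(bray_curtis(abundance_table(zz)), "all-zero")
})

test_that("unweighted UniFrac: hand oracle, bounds, and phyloseq agreement", {
  # ((A:1,B:1):1,C:1); samples {A} vs {A,B}: unique = B's branch (1),
  # union = A + B + stem (3) -> 1/3
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  m <- matrix(c(1, 0, 0, 1, 1, 0, 1, 0, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  d <- as.matrix(unweighted_unifrac(abundance_table(m), tree))
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(d["s1", "s3"], 0)            # identical presence sets
  # presence sets on opposite sides of the root share no branches
  m2 <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(as.vector(unweighted_unifrac(abundance_table(m2), tree)), 1)

  tab <- random_table(n_asv = 15, n_sample = 7, seed = 10, sparsity = 0.5)
  tr <- generate_tree(rownames(tab$counts), seed = 2)
  d1 <- unweighted_unifrac(tab, tr)
  expect_true(all(as.vector(d1) >= 0 & as.vector(d1) <= 1))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(tab$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tr))
  d2 <- phyloseq::UniFrac(ps, weighted = FALSE)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)

  bad <- random_table(n_asv = 16, n_sample = 4, seed = 1)
  expect_error(unweighted_unifrac(bad, tr), "missing from tree")
})

test_that("PCoA: closed-form equilateral case, Euclidean exactness, ape", {
  # three equidistant points at distance d: two equal eigenvalues d^2/2
  D <- matrix(0.6, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D) <- 0
  res <- pcoa(D)
  expect_equal(res$eigenvalues, rep(0.6^2 / 2, 2), tolerance = 1e-12)
  expect_equal(res$proportion_explained, c(0.5, 0.5), tolerance = 1e-12)

  set.seed(12)
  pts <- matrix(rnorm(7 * 3), 7, 3,
                dimnames = list(paste0("p", 1:7), NULL))
  D2 <- as.matrix(dist(pts))
  res2 <- pcoa(D2)
  expect_equal(as.matrix(dist(res2$coordinates)), D2, tolerance = 1e-9,
               ignore_attr = TRUE)

  # duplicated point adds a zero eigenvalue direction (dropped axis)
  D3 <- as.matrix(dist(pts[c(1, 1:6), ]))
  expect_lt(length(pcoa(D3)$eigenvalues), 6)

  tab <- random_table(seed = 5)
  dm <- bray_curtis(relative_abundance(tab))
  mine <- suppressMessages(pcoa(dm))
  theirs <- ape::pcoa(dm)
  k <- length(mine$eigenvalues)
  expect_equal(mine$eigenvalues, theirs$values$Eigenvalues[1:k],
               tolerance = 1e-9)
  expect_error(pcoa(matrix(0, 2, 2)), "at least 3")
})

test_that("ANOSIM: separated groups give R = 1, ties give R = 0, vegan agrees", {
  # block structure: within < between everywhere
  D <- matrix(1, 10, 10)
  D[1:5, 1:5] <- 0.1
  D[6:10, 6:10] <- 0.1
  diag(D) <- 0
  g <- factor(rep(c("A", "B"), each = 5))
  res <- anosim(D, g, n_permutations = 199, seed = 1)
  expect_equal(res$R, 1)
  expect_lte(res$p, 0.05)
  expect_gte(res$p, 1 / 200)

  # all distances equal: every rank ties -> R = 0
  Deq <- matrix(1, 10, 10); diag(Deq) <- 0
  expect_equal(anosim(Deq, g, 49, seed = 1)$R, 0)

  tab <- random_table(n_asv = 20, n_sample = 10, seed = 14)
  dm <- bray_curtis(relative_abundance(tab))
  g2 <- factor(rep(c("A", "B"), each = 5))
  expect_equal(anosim(dm, g2, 99, seed = 3)$R,
               unname(vegan::anosim(dm, g2, permutations = 0)$statistic),
               tolerance = 1e-12)
  expect_error(anosim(dm, factor(c("A", rep("B", 9))), 99, 1), "size 1")
  expect_error(anosim(dm, factor(rep("A", 10)), 99, 1), "2 groups")
})

test_that("PERMANOVA matches vegan::adonis2 and its R2 identity", {
  tab <- random_table(n_asv = 25, n_sample = 12, seed = 15)
  dm <- bray_curtis(relative_abundance(tab))
  g <- factor(rep(c("A", "B", "C"), each = 4))
  mine <- permanova(dm, g, n_permutations = 99, seed = 5)
  ref <- vegan::adonis2(stats::as.dist(dm) ~ g, permutations = 99)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-12)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-12)
  expect_gte(mine$p, 1 / 100)

  # zero within-group distances, positive between -> R2 = 1
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  g2 <- factor(rep(c("A", "B"), each = 3))
  expect_equal(permanova(D, g2, 49, seed = 1)$R2, 1)
})

test_that("rank aggregation conserves totals and keeps the unassigned bucket", {
  tab <- random_table(n_asv = 10, n_sample = 5, seed = 16)
  tax <- taxonomy_table(data.frame(
    asv_id = rownames(tab$counts),
    phylum = c(rep("P1", 4), rep("P2", 4), NA, NA),
    genus = "G1"))
  agg <- aggregate_rank(tab, tax, "phylum")
  expect_setequal(rownames(agg$abundances), c("P1", "P2", "unassigned"))
  expect_equal(colSums(agg$abundances), colSums(tab$counts))
  expect_equal(agg$abundances["P1", ],
               colSums(tab$counts[1:4, ]))
  tax_partial <- taxonomy_table(data.frame(
    asv_id = rownames(tab$counts)[1:5], phylum = "P1"))
  expect_error(aggregate_rank(tab, tax_partial, "phylum"), "missing")
})

test_that("welch_bh: identical groups, strong shifts, BH behavior", {
  set.seed(17)
  A <- matrix(rnorm(3 * 10, mean = 5), 3, 10,
              dimnames = list(c("f1", "f2", "f3"), paste0("a", 1:10)))
  res_same <- welch_bh(A, A)
  expect_true(all(res_same$welch_t == 0))
  expect_true(all(res_same$p_raw == 1))
  expect_false(any(res_same$significant))

  # one feature shifted by 10 SDs
  B <- A
  B["f2", ] <- B["f2", ] + 10 * sd(A["f2", ])
  res <- welch_bh(A, B)
  expect_lt(res$q_bh[res$feature == "f2"], 0.001)
  expect_true(res$significant[res$feature == "f2"])

  # BH is invariant to feature order and monotone in raw p
  resr <- welch_bh(A[3:1, ], B[3:1, ])
  expect_equal(res$q_bh[order(res$feature)],
               resr$q_bh[order(resr$feature)])
  o <- order(res$p_raw)
  expect_true(all(diff(res$q_bh[o]) >= -1e-15))
})
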