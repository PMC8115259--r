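test_that("mic_params validates its fields", {
  expect_error(mic_params(alpha_exponent = 0), "alpha_exponent")
  expect_error(mic_params(alpha_exponent = 1.2), "alpha_exponent")
  expect_error(mic_params(fdr_alpha = 0), "fdr_alpha")
  expect_error(mic_params(clumps_factor = 0), "clumps_factor")
})

test_that("habitat correction divides by habitat means", {
  m <- matrix(c(2, 4, 6,
                0, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "zero"), paste0("S", 1:3)))
  tab <- abundance_table(m)
  hc <- habitat_correct(tab, setNames(rep("H1", 3), paste0("S", 1:3)))
  # a is the only non-zero ASV, so relative abundance is 1 everywhere;
  # use a two-ASV example to see the division
  m2 <- rbind(a = c(2, 4, 6), b = c(2, 4, 6))
  colnames(m2) <- paste0("S", 1:3)
  hc2 <- habitat_correct(abundance_table(m2),
                         setNames(rep("H1", 3), paste0("S", 1:3)))
  expect_equal(unname(hc2$counts["a", ]), c(1, 1, 1))  # equal shares
  m3 <- rbind(a = c(1, 2, 3), b = c(1, 1, 1))
  colnames(m3) <- paste0("S", 1:3)
  hc3 <- habitat_correct(abundance_table(m3),
                         setNames(rep("H1", 3), paste0("S", 1:3)))
  rel <- m3["a", ] / colSums(m3)
  expect_equal(unname(hc3$counts["a", ]), unname(rel / mean(rel)))
  # zeros are preserved and habitat means of corrected rows equal 1
  expect_true(all(hc$counts["zero", ] == 0))
  expect_equal(mean(hc3$counts["a", ]), 1)
  expect_error(
    habitat_correct(abundance_table(m3),
                    setNames(c("H1", "H1", "H2"), paste0("S", 1:3))),
    "fewer than 3")
})

test_that("habitat correction removes a planted habitat confounder", {
  # two independent ASVs both doubled in habitat B: raw correlation is
  # spurious, corrected correlation vanishes on average
  set.seed(20)
  raw_r <- corr_r <- numeric(40)
  for (i in seq_len(40)) {
    n <- 100
    hab <- rep(c("H1", "H2"), each = n / 2)
    base_a <- rlnorm(n, 0, 0.3)
    base_b <- rlnorm(n, 0, 0.3)
    shift <- ifelse(hab == "H2", 3, 1)
    m <- rbind(a = base_a * shift, b = base_b * shift,
               filler = rep(1000, n))
    colnames(m) <- sprintf("S%03d", 1:n)
    tab <- abundance_table(m)
    labels <- setNames(hab, colnames(m))
    rel <- relative_abundance(tab)
    raw_r[i] <- cor(rel$counts["a", ], rel$counts["b", ])
    hc <- habitat_correct(tab, labels)
    corr_r[i] <- cor(hc$counts["a", ], hc$counts["b", ])
  }
  expect_gt(mean(raw_r), 0.5)
  expect_lt(abs(mean(corr_r)), 0.05)
})

test_that("mic basics: identity, symmetry, monotone invariance, degenerate", {
  set.seed(21)
  x <- runif(100)
  expect_gte(mic(x, x)$mic, 0.99)
  y <- runif(100)
  m1 <- mic(x, y, method = "approx")
  m2 <- mic(y, x, method = "approx")
  expect_equal(m1$mic, m2$mic, tolerance = 1e-12)
  # strictly monotone transforms leave the rank-based grids unchanged
  expect_equal(mic(exp(x), y, method = "approx")$mic, m1$mic,
               tolerance = 1e-12)
  expect_equal(mic(x, -1 / (y + 1), method = "approx")$mic, m1$mic,
               tolerance = 1e-12)
  expect_true(mic(rep(1, 50), y[1:50])$degenerate)
  expect_error(mic(x[1:5], y[1:5]), "n >= 10")
  expect_error(mic(x, y[1:50]), "equal length")
})

test_that("exact DP equals the brute-force oracle on small n", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(10:25, 1)
    x <- runif(n)
    y <- if (i %% 2) runif(n) else x + rnorm(n, 0, 0.4)
    B <- max(4, n^0.6)
    expect_equal(mic(x, y, method = "exact")$mic, mic_brute_force(x, y, B),
                 tolerance = 1e-9)
  }
})

test_that("nonlinearity classification separates sine from identity", {
  x <- seq(0, 1, length.out = 200)
  lin <- mic(x, x, method = "approx")
  expect_lt(lin$nonlinearity, 0.05)
  s <- sin(6 * pi * x)
  nl <- mic(x, s, method = "approx")
  expect_lt(nl$pearson_r^2, 0.1)   # r = -1/(6 pi sd_x sd_s), near zero
  expect_gt(nl$mic, 0.6)
  expect_gt(nl$nonlinearity, 0.5)

  edges <- data.frame(mic = c(1, 0.9), pearson_r = c(1, 0.1),
                      nonlinearity = c(0, 0.89),
                      significant = c(TRUE, TRUE),
                      degenerate = FALSE)
  cl <- classify_nonlinear(edges)
  expect_equal(cl$nonlinear, c(FALSE, TRUE))
  expect_equal(attr(cl, "frac_nonlinear"), 0.5)
  empty <- classify_nonlinear(edges[0, ])
  expect_equal(attr(empty, "frac_nonlinear"), 0)
})

test_that("edge_scan scores all pairs, supports bipartite mode, seeds", {
  hub <- simulate_hub_table(n_samples = 40, n_satellites = 2, n_decoys = 1,
                            seed = 30)
  params <- mic_params(n_permutations = 50, seed = 7)
  edges <- edge_scan(hub$table, hub$core_labels, params)
  expect_equal(nrow(edges), choose(4, 2))   # 4 labeled nodes -> 6 pairs
  edges2 <- edge_scan(hub$table, hub$core_labels, params)
  expect_identical(edges, edges2)           # seeded determinism
  bip <- edge_scan(hub$table, hub$core_labels, params, pairs = "bipartite")
  # hub is the only functional node: bipartite keeps hub-* pairs only
  expect_true(all(bip$from == "ASV_hub" | bip$to == "ASV_hub"))
  expect_equal(nrow(bip), 3)
})

test_that("a planted dependent pair is called; independent decoys are not", {
  called <- 0; decoy_fp <- 0
  for (s in 1:20) {
    set.seed(s + 400)
    n <- 60
    x <- rnorm(n)
    m <- rbind(pair_a = x, pair_b = x + rnorm(n, 0, 0.3),
               d1 = rnorm(n), d2 = rnorm(n), d3 = rnorm(n), d4 = rnorm(n))
    m <- exp(m / 2)
    colnames(m) <- sprintf("S%03d", 1:n)
    tab <- abundance_table(m)
    labels <- setNames(rep("taxonomic", 6), rownames(m))
    # with a single true pair among 15, the rank-1 BH threshold is
    # 0.05/15, so the permutation count must push 1/(N+1) below it
    edges <- edge_scan(tab, labels, mic_params(n_permutations = 400,
                                               seed = s))
    planted <- edges$from == "pair_a" & edges$to == "pair_b"
    if (edges$significant[planted]) called <- called + 1
    decoy_fp <- decoy_fp + sum(edges$significant[!planted])
  }
  expect_gte(called, 19)
  expect_lte(decoy_fp / 20, 0.5)
})

test_that("build_network labels nodes and drops non-significant edges", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                      mic = 0.5, pearson_r = 0.1, nonlinearity = 0.4,
                      p_raw = c(0.001, 0.001, 0.9),
                      q_bh = c(0.01, 0.01, 0.9),
                      significant = c(TRUE, TRUE, FALSE),
                      degenerate = FALSE)
  labels <- c(a = "taxonomic", b = "functional", c = "both",
              d = "taxonomic")
  net <- build_network(edges, labels)
  expect_equal(nrow(net$nodes), 3)          # d only touches a dropped edge
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$nodes$core_label[net$nodes$id == "c"], "both")
  empty <- build_network(edges[edges$p_raw > 0.5, ], labels)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("hub detection: star center unique, cycle fully tied", {
  mk_edges <- function(from, to) {
    data.frame(from = from, to = to, mic = 0.8, pearson_r = 0.5,
               nonlinearity = 0.55, p_raw = 0.001, q_bh = 0.01,
               significant = TRUE, degenerate = FALSE)
  }
  leaves <- paste0("L", 1:5)
  star <- build_network(mk_edges("C", leaves),
                        setNames(rep("taxonomic", 6), c("C", leaves)))
  hs <- hub_taxa(star)
  expect_equal(hs$id[hs$is_hub], "C")
  expect_equal(hs$degree[hs$id == "C"], 5)

  ring <- paste0("N", 1:6)
  cyc <- build_network(mk_edges(ring, ring[c(2:6, 1)]),
                       setNames(rep("functional", 6), ring))
  hc <- hub_taxa(cyc)
  expect_true(all(hc$is_hub))               # full symmetry: all tied

  expect_error(hub_taxa(build_network(mk_edges("C", leaves)[0, ],
                                      c(C = "taxonomic"))),
               "empty")
})
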