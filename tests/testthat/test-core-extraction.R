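test_that("prevalence counts presence per ASV", {
  m <- matrix(0, 3, 10, dimnames = list(c("a", "b", "c"), paste0("S", 1:10)))
  m["a", 1:8] <- 5
  m["c", ] <- 1
  tab <- abundance_table(m)
  prev <- prevalence(tab)
  expect_equal(unname(prev["a"]), 0.8)
  expect_equal(unname(prev["b"]), 0)
  expect_equal(unname(prev["c"]), 1)
  expect_equal(prev, prevalence_naive(tab))
})

test_that("taxonomic core applies the cut-off at the boundary", {
  m <- matrix(0, 3, 10, dimnames = list(c("in8", "in7", "all"),
                                        paste0("S", 1:10)))
  m["in8", 1:8] <- 1
  m["in7", 1:7] <- 1
  m["all", ] <- 1
  tab <- abundance_table(m)
  core <- taxonomic_core(tab, 0.75)
  expect_setequal(core$member_ids, c("in8", "all"))   # 0.8 >= 0.75, 0.7 < 0.75
  expect_equal(unname(core$prevalence["in8"]), 0.8)
  strict <- taxonomic_core(tab, 1.0)
  expect_setequal(strict$member_ids, "all")
  expect_error(taxonomic_core(tab, 0), "cutoff")
  expect_error(taxonomic_core(tab, 1.5), "cutoff")
})

test_that("taxonomic core agrees with the naive loop on random tables", {
  for (seed in 1:5) {
    tab <- random_table(n_asv = 25, n_sample = 13, seed = seed,
                        sparsity = 0.5)
    prev <- prevalence_naive(tab)
    for (ct in c(0.5, 0.75, 0.9)) {
      expect_setequal(taxonomic_core(tab, ct)$member_ids,
                      names(prev)[prev >= ct])
    }
  }
})

test_that("cut-off monotonicity: higher cut-offs never add members", {
  tab <- random_table(n_asv = 30, n_sample = 16, seed = 9, sparsity = 0.4)
  cuts <- seq(0.5, 1, by = 0.1)
  cores <- lapply(cuts, function(ct) taxonomic_core(tab, ct)$member_ids)
  for (i in seq_along(cuts)[-1])
    expect_true(all(cores[[i]] %in% cores[[i - 1]]))
})

test_that("core_kos finds prevalent KOs and rejects pathway tables", {
  ab <- matrix(c(rep(1, 9), 0,
                 rep(0, 10),
                 rep(2, 10)), 3, 10, byrow = TRUE,
               dimnames = list(c("K1", "K2", "K3"), paste0("S", 1:10)))
  kt <- function_table(ab, level = "KO")
  expect_setequal(core_kos(kt, 0.75), c("K1", "K3"))
  expect_setequal(core_kos(kt, 0.1), c("K1", "K3"))   # K2 never core
  pt <- function_table(ab, level = "pathway")
  expect_error(core_kos(pt), "KO-level")
})

test_that("functional core: prevalence route, redundancy route, provenance", {
  m <- matrix(0, 4, 10,
              dimnames = list(c("prev80", "noko", "redund", "single"),
                              paste0("S", 1:10)))
  m["prev80", 1:8] <- 3
  m["noko", ] <- 5
  m["redund", 1:3] <- 2
  m["single", 1:3] <- 2
  tab <- abundance_table(m)
  ko <- matrix(0L, 4, 4, dimnames = list(rownames(m),
                                         c("K1", "K2", "K3", "K4")))
  ko["prev80", "K1"] <- 2L
  ko["redund", c("K1", "K2", "K3")] <- 1L
  ko["single", "K2"] <- 1L
  gc <- genome_content_table(ko, setNames(rep(1L, 4), rownames(m)))

  fun <- functional_core(tab, gc, c("K1", "K2", "K3"), 0.75)
  # prev80: carries K1 and prevalent; redund: 3 core KOs (redundancy rule);
  # noko: no core KO despite 100% prevalence; single: 1 core KO, 30% prev
  expect_setequal(fun$member_ids, c("prev80", "redund"))
  expect_setequal(fun$provenance[["prev80"]], "K1")
  expect_setequal(fun$provenance[["redund"]], c("K1", "K2", "K3"))
  expect_equal(sum(fun$member_ids == "redund"), 1)  # counted once

  # disabling the redundancy inclusion leaves the pure conjunction
  fun2 <- functional_core(tab, gc, c("K1", "K2", "K3"), 0.75,
                          redundancy_min_kos = NULL)
  expect_setequal(fun2$member_ids, "prev80")

  expect_warning(empty <- functional_core(tab, gc, character(0), 0.75),
                 "empty core KO")
  expect_length(empty$member_ids, 0)
  expect_error(functional_core(tab, gc, "K9", 0.75), "K9")
})

test_that("filter_to_core restricts rows and drops empty samples", {
  m <- matrix(c(1, 0, 2, 5,
                0, 0, 1, 1,
                3, 1, 0, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("S", 1:4)))
  tab <- abundance_table(m)
  prev <- prevalence(tab)
  core <- core_set("taxonomic", c("a", "b"), 0.5, prev)
  expect_message(rh <- filter_to_core(tab, core), "1 sample")
  expect_equal(rownames(rh$counts), c("a", "b"))
  expect_equal(colnames(rh$counts), c("S1", "S3", "S4"))  # S2 all-zero
  expect_equal(rh$counts["a", "S4"], 5)

  all_core <- core_set("taxonomic", c("a", "b", "c"), 0.1, prev)
  expect_identical(filter_to_core(tab, all_core)$counts, tab$counts)

  bad <- core_set("taxonomic", "zz", 0.5, c(zz = 1))
  expect_error(filter_to_core(tab, bad), "zz")
})

test_that("shared_core computes intersection percentages", {
  prev <- c(a = 1, b = 1, c = 1)
  mk <- function(ids) core_set("taxonomic", ids, 0.5, prev)
  sh <- shared_core(mk(c("a", "b")), mk(c("b", "c")))
  expect_equal(sh$shared_ids, "b")
  expect_equal(sh$pct_shared, 100 / 3, tolerance = 1e-12)
  expect_equal(shared_core(mk("a"), mk("b"))$pct_shared, 0)
  expect_equal(shared_core(mk(c("a", "b")), mk(c("a", "b")))$pct_shared, 100)
})

test_that("Good's coverage follows 1 - singletons/observed", {
  col <- c(rep(1, 5), rep(10, 95))
  expect_equal(goods_coverage(col), 0.95)
  expect_equal(goods_coverage(c(5, 7, 2)), 1.0)
  expect_equal(goods_coverage(c(1, 1, 1, 0)), 0.0)
  expect_error(goods_coverage(c(0, 0)), "all-zero")
})

test_that("core_summary reports membership and abundance percentages", {
  m <- matrix(1, 100, 4,
              dimnames = list(sprintf("a%03d", 1:100), paste0("S", 1:4)))
  m[1:3, ] <- 33          # 3 core ASVs carry 99 of 196 reads per sample
  tab <- abundance_table(m)
  prev <- prevalence(tab)
  core <- core_set("taxonomic", rownames(m)[1:3], 0.75, prev)
  cs <- core_summary(tab, core, core)
  expect_equal(cs$pct_of_all_asvs, 3)
  expect_equal(cs$pct_of_total_relative_abundance, 100 * 99 / 196)
  expect_equal(cs$pct_shared, 100)
})

test_that("functional minus taxonomic core is non-empty with planted redundancy", {
  sim <- generate_scenario(scenario_config(n_samples = 80, seed = 13))
  tax <- taxonomic_core(sim$table, 0.75)
  kt <- predict_metagenome(sim$table, sim$genome_content)
  fun <- functional_core(sim$table, sim$genome_content,
                         core_kos(kt, 0.75), 0.75)
  expect_gt(length(setdiff(fun$member_ids, tax$member_ids)), 0)
})
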