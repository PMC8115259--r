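test_that("scenario config rejects invalid fields by name", {
  expect_error(scenario_config(n_samples = 0), "n_samples")
  expect_error(scenario_config(core_prevalence = 1.2), "core_prevalence")
  expect_error(scenario_config(background_prevalence = 0.95),
               "background_prevalence")
  expect_error(scenario_config(n_asvs = 10, planted_tax_core_size = 8,
                               planted_redundant_asvs = 5),
               "planted")
  expect_error(scenario_config(overdispersion = -1), "overdispersion")
  expect_error(scenario_config(seed = 1.5), "seed")
})

test_that("fixed seed gives bit-identical scenarios", {
  cfg <- scenario_config(n_samples = 15, n_asvs = 30, n_kos = 20, seed = 11,
                         planted_tax_core_size = 5,
                         planted_redundant_asvs = 3)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$genome_content$ko, b$genome_content$ko)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$truth, b$truth)
})

test_that("noise-free scenario is exactly recoverable", {
  cfg <- scenario_config(core_prevalence = 1, background_prevalence = 0,
                         overdispersion = 1e9, seed = 2)
  sim <- generate_scenario(cfg)
  prev <- prevalence(sim$table)
  expect_true(all(prev[sim$truth$tax_core_ids] == 1))
  expect_true(all(prev[setdiff(names(prev), sim$truth$tax_core_ids)] == 0))
})

test_that("generated structure matches the stated world", {
  cfg <- scenario_config(n_samples = 40, seed = 8)
  sim <- generate_scenario(cfg)
  # multinomial totals are exact
  expect_true(all(colSums(sim$table$counts) == cfg$sequencing_depth_mean))
  # redundancy group: functional-only members carry >= 2 core KOs
  fun_only <- setdiff(sim$truth$functional_core_ids,
                      sim$truth$tax_core_ids)
  expect_gt(length(fun_only), 0)
  cn <- sim$genome_content$ko[fun_only, sim$truth$core_ko_ids,
                              drop = FALSE]
  expect_true(all(rowSums(cn > 0) >= 2))
  # ground truth consistent with the genome content
  cn_all <- sim$genome_content$ko[sim$truth$functional_core_ids,
                                  sim$truth$core_ko_ids, drop = FALSE]
  expect_true(all(rowSums(cn_all >= 1) >= 1))
  # habitat labels cover all samples
  expect_setequal(names(sim$truth$habitat_labels),
                  colnames(sim$table$counts))
})

test_that("planted core presence rate is near its target", {
  cfg <- scenario_config(n_samples = 200, core_prevalence = 0.9, seed = 21)
  sim <- generate_scenario(cfg)
  prev <- prevalence(sim$table)
  core_prev <- mean(prev[sim$truth$tax_core_ids])
  # multinomial/Dirichlet thinning may shave a few points off the target
  expect_gt(core_prev, 0.8)
  expect_lt(mean(prev[setdiff(names(prev), sim$truth$tax_core_ids)]), 0.5)
})

test_that("generate_tree yields rooted bifurcating trees, deterministically", {
  ids <- sprintf("ASV_%02d", 1:7)
  tr <- generate_tree(ids, seed = 4)
  expect_setequal(tr$tip.label, ids)
  expect_equal(tr$Nnode, length(ids) - 1)  # bifurcating, rooted
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(generate_tree(ids, seed = 4)),
                   ape::write.tree(tr))
  cherry <- generate_tree(c("a", "b"), seed = 1)
  expect_equal(length(cherry$tip.label), 2)
  expect_error(generate_tree("one"), "at least 2")
  expect_error(generate_tree(c("a", "a")), "duplicated")
})
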