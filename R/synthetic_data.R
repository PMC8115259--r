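#' Configuration for a synthetic rhizobiome scenario
#'
#' The generator plants known structure so every downstream stage has ground
#' truth: a high-prevalence taxonomic core, a functionally redundant ASV
#' group (carrying core KOs but occupying fewer samples than the prevalence
#' cut-off), habitat-driven abundance shifts, and a random phylogeny.
#'
#' Occupancy is controlled directly: each ASV is present in a sample with
#' probability `core_prevalence` (planted core) or `background_prevalence`
#' (everything else); present ASVs receive lognormal base weights, a
#' per-habitat multiplicative shift is applied to a random ASV subset, and
#' counts are drawn as a multinomial over Dirichlet-perturbed proportions
#' (concentration = `overdispersion`).
#'
#' @param n_samples,n_asvs,n_kos,n_pathways,n_habitats positive counts.
#' @param planted_tax_core_size number of planted taxonomic-core ASVs.
#' @param planted_redundant_asvs number of ASVs that carry >= 2 core KOs but
#'   sit below the taxonomic prevalence cut-off (the functional-redundancy
#'   group).
#' @param core_prevalence target per-sample presence probability of planted
#'   core ASVs (default 0.9).
#' @param background_prevalence presence probability of all other ASVs
#'   (default 0.3); must be strictly below `core_prevalence`.
#' @param sequencing_depth_mean reads per sample (multinomial total).
#' @param overdispersion Dirichlet concentration; larger = less
#'   compositional noise (default 200).
#' @param habitat_effect log-scale abundance shift applied per habitat to a
#'   random 30% of ASVs (default 1).
#' @param seed integer master seed.
#' @return class `synthetic_scenario` config list.
#' @export
scenario_config <- function(n_samples = 60, n_asvs = 150, n_kos = 120,
                            n_pathways = 20, n_habitats = 2,
                            planted_tax_core_size = 15,
                            planted_redundant_asvs = 10,
                            core_prevalence = 0.9,
                            background_prevalence = 0.3,
                            sequencing_depth_mean = 10000,
                            overdispersion = 200,
                            habitat_effect = 1,
                            seed = 1) {
  cfg <- list(n_samples = n_samples, n_asvs = n_asvs, n_kos = n_kos,
              n_pathways = n_pathways, n_habitats = n_habitats,
              planted_tax_core_size = planted_tax_core_size,
              planted_redundant_asvs = planted_redundant_asvs,
              core_prevalence = core_prevalence,
              background_prevalence = background_prevalence,
              sequencing_depth_mean = sequencing_depth_mean,
              overdispersion = overdispersion,
              habitat_effect = habitat_effect, seed = seed)
  counts <- c("n_samples", "n_asvs", "n_kos", "n_pathways", "n_habitats",
              "sequencing_depth_mean")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("invalid `", f, "`: must be a positive count")
  }
  for (f in c("planted_tax_core_size", "planted_redundant_asvs")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop("invalid `", f, "`: must be a non-negative count")
  }
  if (planted_tax_core_size + planted_redundant_asvs > n_asvs)
    stop("invalid `planted_tax_core_size`/`planted_redundant_asvs`: ",
         "planted groups exceed `n_asvs`")
  if (!is.numeric(core_prevalence) || core_prevalence <= 0 ||
      core_prevalence > 1)
    stop("invalid `core_prevalence`: must be in (0, 1]")
  if (!is.numeric(background_prevalence) || background_prevalence < 0 ||
      background_prevalence >= core_prevalence)
    stop("invalid `background_prevalence`: ",
         "must satisfy 0 <= background_prevalence < core_prevalence")
  if (!is.numeric(overdispersion) || overdispersion <= 0)
    stop("invalid `overdispersion`: must be a positive real")
  if (!is.numeric(habitat_effect) || habitat_effect < 0)
    stop("invalid `habitat_effect`: must be non-negative")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("invalid `seed`: must be an integer")
  structure(cfg, class = "synthetic_scenario")
}

#' Generate a synthetic rhizobiome dataset with planted ground truth
#'
#' @param config a [scenario_config()].
#' @return list with elements `table` ([abundance_table()]), `taxonomy`
#'   ([taxonomy_table()]), `genome_content` ([genome_content_table()]),
#'   `ko_map` ([ko_pathway_map()]), `tree` (`ape::phylo`), and `truth`
#'   (class `ground_truth`: `tax_core_ids`, `core_ko_ids`,
#'   `functional_core_ids`, `habitat_labels`).
#' @details Fixed seed implies bit-identical output. Core KOs are assigned
#'   only to planted (core + redundant) ASVs, and every non-core KO has at
#'   most two background carriers, so that the planted sets are exactly
#'   recoverable in the noise-free regime.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "synthetic_scenario"))
  c_ <- config
  set.seed(c_$seed)
  asvs <- sprintf("ASV_%04d", seq_len(c_$n_asvs))
  samples <- sprintf("S_%03d", seq_len(c_$n_samples))
  kos <- sprintf("K%05d", seq_len(c_$n_kos))
  pathways <- sprintf("path_%03d", seq_len(c_$n_pathways))

  n_core <- c_$planted_tax_core_size
  n_red <- c_$planted_redundant_asvs
  core_ids <- asvs[seq_len(n_core)]
  red_ids <- asvs[n_core + seq_len(n_red)]

  # habitat structure
  habitats <- sprintf("H%d", seq_len(c_$n_habitats))
  habitat_labels <- stats::setNames(
    habitats[(seq_len(c_$n_samples) - 1L) %% c_$n_habitats + 1L], samples)
  n_affected <- round(0.3 * c_$n_asvs)
  affected <- sample(asvs, n_affected)
  # per (ASV, habitat) log-scale shift; first habitat is the reference
  shift <- matrix(0, c_$n_asvs, c_$n_habitats,
                  dimnames = list(asvs, habitats))
  if (c_$n_habitats > 1 && n_affected > 0) {
    sgn <- matrix(sample(c(-1, 1), n_affected * (c_$n_habitats - 1),
                         replace = TRUE),
                  n_affected, c_$n_habitats - 1)
    shift[affected, -1] <- sgn * c_$habitat_effect
  }

  # core taxa are typically among the more abundant members; the higher
  # base weights also keep multinomial/Dirichlet thinning from pushing
  # realized presence below the planted presence probability
  base_weight <- stats::setNames(stats::rlnorm(c_$n_asvs, 0, 1), asvs)
  base_weight[core_ids] <- stats::rlnorm(n_core, 1, 0.7)
  prevalence_target <- stats::setNames(
    rep(c_$background_prevalence, c_$n_asvs), asvs)
  prevalence_target[core_ids] <- c_$core_prevalence

  counts <- matrix(0, c_$n_asvs, c_$n_samples,
                   dimnames = list(asvs, samples))
  for (j in seq_len(c_$n_samples)) {
    present <- stats::runif(c_$n_asvs) < prevalence_target
    if (!any(present)) next
    w <- base_weight * exp(shift[, habitat_labels[j]]) * present
    pr <- w / sum(w)
    alpha <- c_$overdispersion * pr[present]
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    pr[present] <- g / sum(g)
    pr[!present] <- 0
    counts[, j] <- stats::rmultinom(1, c_$sequencing_depth_mean, pr)[, 1]
  }

  metadata <- data.frame(study = "synthetic",
                         habitat = unname(habitat_labels),
                         group = "rhizosphere",
                         row.names = samples)
  table <- abundance_table(counts, metadata = metadata)

  # taxonomy: a handful of synthetic lineages
  n_phyla <- max(2, min(8, ceiling(c_$n_asvs / 20)))
  phyla <- sprintf("Phylum_%02d", seq_len(n_phyla))
  phy <- sample(phyla, c_$n_asvs, replace = TRUE)
  gen <- sprintf("Genus_%03d", sample.int(max(3, c_$n_asvs %/% 5),
                                          c_$n_asvs, replace = TRUE))
  unas <- stats::runif(c_$n_asvs) < 0.1
  gen[unas] <- "unassigned"
  taxonomy <- taxonomy_table(data.frame(
    asv_id = asvs, kingdom = "Bacteria", phylum = phy,
    class = paste0(phy, "_c"), order = paste0(phy, "_o"),
    family = paste0(phy, "_f"), genus = gen,
    stringsAsFactors = FALSE))

  # genome content: core KOs only on planted ASVs; every non-core KO has at
  # most 2 background carriers so it cannot reach core-KO prevalence
  n_core_ko <- max(5, round(0.25 * c_$n_kos))
  n_core_ko <- min(n_core_ko, c_$n_kos)
  core_ko_ids <- kos[seq_len(n_core_ko)]
  other_kos <- setdiff(kos, core_ko_ids)
  ko_cn <- matrix(0L, c_$n_asvs, c_$n_kos, dimnames = list(asvs, kos))
  for (a in core_ids) {
    k <- sample(core_ko_ids, max(1, stats::rbinom(1, n_core_ko, 0.3)))
    ko_cn[a, k] <- sample(1:3, length(k), replace = TRUE)
  }
  for (a in red_ids) {
    k <- sample(core_ko_ids, min(n_core_ko, sample(2:4, 1)))
    ko_cn[a, k] <- sample(1:3, length(k), replace = TRUE)
  }
  background <- setdiff(asvs, c(core_ids, red_ids))
  if (length(background) && length(other_kos)) {
    for (k in other_kos) {
      carriers <- sample(background, min(length(background),
                                         sample(1:2, 1)))
      ko_cn[carriers, k] <- sample(1:3, length(carriers), replace = TRUE)
    }
  }
  copies_16s <- stats::setNames(sample(1:7, c_$n_asvs, replace = TRUE), asvs)
  genome_content <- genome_content_table(ko_cn, copies_16s)

  ko_map <- ko_pathway_map(stats::setNames(lapply(kos, function(k) {
    n <- sample(0:2, 1, prob = c(0.2, 0.5, 0.3))
    if (n == 0) character(0) else sample(pathways, n)
  }), kos))

  tree <- generate_tree(asvs, seed = c_$seed + 1L)

  truth <- structure(list(
    tax_core_ids = core_ids,
    core_ko_ids = core_ko_ids,
    functional_core_ids = c(core_ids[rowSums(ko_cn[core_ids, core_ko_ids,
                                                   drop = FALSE] > 0) > 0],
                            red_ids),
    habitat_labels = habitat_labels), class = "ground_truth")

  list(table = table, taxonomy = taxonomy, genome_content = genome_content,
       ko_map = ko_map, tree = tree, truth = truth)
}

#' Random bifurcating tree over a set of ASV ids
#'
#' @param asv_ids at least two unique tip labels.
#' @param seed integer seed; fixed seed gives an identical newick string.
#' @return rooted bifurcating `ape::phylo` with exponential branch lengths.
#' @export
generate_tree <- function(asv_ids, seed = 1) {
  asv_ids <- as.character(asv_ids)
  if (length(asv_ids) < 2) stop("need at least 2 ASV ids for a tree")
  if (anyDuplicated(asv_ids))
    stop("duplicated ASV id(s): ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
  set.seed(seed)
  tree <- ape::rtree(length(asv_ids), rooted = TRUE,
                     tip.label = asv_ids, br = stats::rexp)
  tree
}

#' Simulate a hub-structured relative-abundance table
#'
#' A validation scenario for the co-occurrence network stage: one hub ASV is
#' associated with all `n_satellites` satellite ASVs, while the satellites
#' split into two factor-driven cliques. On the latent (log) scale the hub
#' is the mean of two independent factors and each satellite follows one of
#' them plus noise, so hub-satellite associations are strong, within-clique
#' associations exist, and cross-clique satellite pairs are independent --
#' making the hub the unique node with top degree, closeness and
#' betweenness. `n_decoys` ASVs vary independently, and a large constant
#' filler taxon absorbs most of the compositional closure so the planted
#' dependence survives the transformation to relative abundances. The hub
#' is labeled functional-core-only; satellites and decoys are taxonomic.
#'
#' @param n_samples number of samples (default 60).
#' @param n_satellites ASVs correlated with the hub (default 10).
#' @param n_decoys independent ASVs (default 4).
#' @param noise_sd latent-scale noise added to satellites (default 0.15;
#'   the latent factors have unit variance, giving hub-satellite
#'   correlations near 0.7 and within-clique correlations near 1).
#' @param seed integer seed.
#' @return list with `table` (relative [abundance_table()], one habitat),
#'   `core_labels` (named character: taxonomic/functional/both), and
#'   `hub_id`.
#' @export
simulate_hub_table <- function(n_samples = 60, n_satellites = 10,
                               n_decoys = 4, noise_sd = 0.15, seed = 1) {
  set.seed(seed)
  ids <- c("ASV_hub",
           sprintf("ASV_sat%02d", seq_len(n_satellites)),
           sprintf("ASV_dec%02d", seq_len(n_decoys)),
           "ASV_filler")
  f1 <- stats::rnorm(n_samples)
  f2 <- stats::rnorm(n_samples)
  # orthogonalize in-sample so cross-clique independence holds exactly in
  # every realization (a chance factor correlation would couple all
  # cross-clique pairs at once)
  f1 <- as.vector(scale(f1))
  f2 <- as.vector(scale(stats::residuals(stats::lm(f2 ~ f1))))
  fac <- rep(c(1, 2), length.out = n_satellites)
  lat <- rbind((f1 + f2) / sqrt(2),
               t(vapply(seq_len(n_satellites), function(i) {
                 (if (fac[i] == 1) f1 else f2) +
                   stats::rnorm(n_samples, 0, noise_sd)
               }, numeric(n_samples))),
               t(vapply(seq_len(n_decoys),
                        function(i) stats::rnorm(n_samples),
                        numeric(n_samples))),
               log(500) + stats::rnorm(n_samples, 0, 0.01))
  m <- exp(lat)
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(ids, sprintf("S_%03d", seq_len(n_samples)))
  metadata <- data.frame(study = rep("synthetic", n_samples),
                         habitat = rep("H1", n_samples),
                         group = rep("rhizosphere", n_samples),
                         row.names = colnames(m))
  # the filler is deliberately unlabeled: it is not a core member
  labels <- stats::setNames(
    c("functional", rep("taxonomic", n_satellites + n_decoys)),
    ids[-length(ids)])
  list(table = abundance_table(m, metadata = metadata, relative = TRUE),
       core_labels = labels, hub_id = "ASV_hub")
}
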