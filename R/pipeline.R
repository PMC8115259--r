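# Per-study pipeline: both core-identification routes, the comparison
# statistics, and the habitat-corrected MIC network, driven by one config.
# All randomness flows from one master seed via fixed per-stage offsets, so
# identical configs give byte-identical outputs.

#' Pipeline run configuration
#'
#' @param table,taxonomy,genome_content,ko_map,tree,metadata input paths
#'   (TSV tables, newick tree, sample-metadata TSV; `metadata` may be
#'   `NULL` if the table was written with embedded defaults).
#' @param out_dir output directory (created if missing).
#' @param cutoff prevalence cut-off (default 0.75).
#' @param cutoff_sweep cut-offs for [cutoff_sensitivity()]
#'   (default 0.70 to 0.90 by 0.05).
#' @param permutations label permutations for ANOSIM/PERMANOVA
#'   (default 999).
#' @param mic_permutations permutations per pair for MIC edge p-values
#'   (default 200).
#' @param fdr_alpha FDR level for edge calling (default 0.05).
#' @param seed master integer seed.
#' @return class `run_config`.
#' @export
run_config <- function(table, taxonomy, genome_content, ko_map, tree,
                       metadata = NULL, out_dir = "dualcore_out",
                       cutoff = 0.75,
                       cutoff_sweep = seq(0.70, 0.90, by = 0.05),
                       permutations = 999, mic_permutations = 200,
                       fdr_alpha = 0.05, seed = 1) {
  cfg <- list(table = table, taxonomy = taxonomy,
              genome_content = genome_content, ko_map = ko_map,
              tree = tree, metadata = metadata, out_dir = out_dir,
              cutoff = cutoff, cutoff_sweep = cutoff_sweep,
              permutations = permutations,
              mic_permutations = mic_permutations,
              fdr_alpha = fdr_alpha, seed = seed)
  for (f in c("table", "taxonomy", "genome_content", "ko_map", "tree")) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("config error: input path `", f, "` does not exist: ", cfg[[f]])
  }
  if (!is.null(metadata) && !file.exists(metadata))
    stop("config error: input path `metadata` does not exist: ", metadata)
  if (any(cfg$cutoff <= 0 | cfg$cutoff > 1) ||
      any(cfg$cutoff_sweep <= 0 | cfg$cutoff_sweep > 1))
    stop("config error: cutoffs must lie in (0, 1]")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("config error: seed must be a single integer")
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat JSON object whose keys are the [run_config()] arguments; relative
#' input paths are resolved against the config file's directory.
#'
#' @param path JSON config file.
#' @return class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (f in c("table", "taxonomy", "genome_content", "ko_map", "tree",
              "metadata"))
    raw[[f]] <- resolve(raw[[f]])
  if (!is.null(raw$out_dir) && !grepl("^/", raw$out_dir))
    raw$out_dir <- file.path(base, raw$out_dir)
  do.call(run_config, raw)
}

#' Write a synthetic scenario to a directory in standard formats
#'
#' Emits `table.tsv`, `metadata.tsv`, `taxonomy.tsv`,
#' `genome_content.tsv`, `ko_map.tsv`, `tree.nwk`, and `truth.json`.
#'
#' @param sim result of [generate_scenario()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             genome_content = file.path(dir, "genome_content.tsv"),
             ko_map = file.path(dir, "ko_map.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_abundance(sim$table, paths["table"])
  write_sample_metadata(sim$table$metadata, paths["metadata"])
  write_taxonomy(sim$taxonomy, paths["taxonomy"])
  write_genome_content(sim$genome_content, paths["genome_content"])
  write_ko_map(sim$ko_map, paths["ko_map"])
  write_tree(sim$tree, paths["tree"])
  jsonlite::write_json(
    list(tax_core_ids = sim$truth$tax_core_ids,
         core_ko_ids = sim$truth$core_ko_ids,
         functional_core_ids = sim$truth$functional_core_ids,
         habitat_labels = as.list(sim$truth$habitat_labels)),
    paths["truth"], auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}

load_inputs <- function(config) {
  list(table = read_abundance(config$table, metadata = config$metadata),
       taxonomy = read_taxonomy(config$taxonomy),
       genome_content = read_genome_content(config$genome_content),
       ko_map = read_ko_map(config$ko_map),
       tree = read_tree(config$tree))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Pool two core rhizobiomes for between-core comparison
#'
#' Builds one table over the union of ASVs whose columns are the samples of
#' both core rhizobiomes (suffixed `_tax` / `_fun`), plus the core-type
#' group factor — the input expected by [bray_curtis()] / [anosim()] /
#' [permanova()] when comparing the two cores.
#'
#' @param tax_rhizo,fun_rhizo [abundance_table()]s filtered to the
#'   taxonomic and functional core (see [filter_to_core()]).
#' @return list with `table` (an [abundance_table()]) and `groups`
#'   (factor: taxonomic/functional).
#' @export
pool_rhizobiomes <- function(tax_rhizo, fun_rhizo) {
  ids <- union(asv_ids(tax_rhizo), asv_ids(fun_rhizo))
  expand <- function(rhizo, suffix) {
    m <- matrix(0, length(ids), ncol(rhizo$counts),
                dimnames = list(ids, paste0(sample_ids(rhizo), suffix)))
    m[asv_ids(rhizo), ] <- rhizo$counts
    m
  }
  m <- cbind(expand(tax_rhizo, "_tax"), expand(fun_rhizo, "_fun"))
  groups <- factor(c(rep("taxonomic", ncol(tax_rhizo$counts)),
                     rep("functional", ncol(fun_rhizo$counts))))
  list(table = abundance_table(m), groups = groups)
}

compare_tables <- function(dm, groups, permutations, seed) {
  an <- anosim(dm, groups, n_permutations = permutations, seed = seed)
  pe <- permanova(dm, groups, n_permutations = permutations, seed = seed)
  list(anosim = an, permanova = pe,
       pcoa = if (attr(dm, "Size") >= 3) pcoa(dm) else NULL)
}

#' Run the full per-study analysis
#'
#' Executes, in order: KO metagenome prediction, taxonomic-core
#' identification and filtering, core-KO and functional-core
#' identification and filtering, per-core function tables, beta-diversity
#' comparisons (Bray-Curtis at ASV/KO/pathway level, unweighted UniFrac at
#' ASV level, PCoA, ANOSIM, PERMANOVA), Welch + BH differential abundance
#' at phylum/genus/pathway/KO level, then habitat correction, the MIC edge
#' scan, network construction and hub detection. Every artifact is written
#' to `config$out_dir`; a manifest records the package version, seed and
#' config hash. Any stage failure aborts with the stage name; artifacts
#' from earlier stages are preserved.
#'
#' @param config a [run_config()].
#' @return class `report_bundle`: the in-memory results plus output paths.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  inputs <- stage("load_inputs", load_inputs(config))
  tab <- inputs$table

  ko_table <- stage("predict_metagenome",
                    predict_metagenome(tab, inputs$genome_content))
  write_function_table(ko_table, file.path(out, "ko_metagenome.tsv"))
  pathway_table <- stage("ko_to_pathway",
                         ko_to_pathway(ko_table, inputs$ko_map))
  write_function_table(pathway_table,
                       file.path(out, "pathway_abundance.tsv"))

  tax_core <- stage("taxonomic_core", taxonomic_core(tab, config$cutoff))
  write_core_set(tax_core, file.path(out, "taxonomic_core.tsv"))
  note("taxonomic core: %d members", length(tax_core$member_ids))

  kos <- stage("core_kos", core_kos(ko_table, config$cutoff))
  writeLines(kos, file.path(out, "core_kos.txt"))
  fun_core <- stage("functional_core",
                    suppressWarnings(functional_core(
                      tab, inputs$genome_content, kos, config$cutoff)))
  write_core_set(fun_core, file.path(out, "functional_core.tsv"))
  note("functional core: %d members", length(fun_core$member_ids))

  have_cores <- length(tax_core$member_ids) > 0 &&
    length(fun_core$member_ids) > 0
  tax_rhizo <- fun_rhizo <- NULL
  stats_out <- list()
  diff_out <- list()
  if (have_cores) {
    tax_rhizo <- stage("filter_taxonomic",
                       filter_to_core(tab, tax_core))
    fun_rhizo <- stage("filter_functional",
                       filter_to_core(tab, fun_core))
    write_abundance(tax_rhizo, file.path(out, "taxonomic_rhizobiome.tsv"))
    write_abundance(fun_rhizo, file.path(out, "functional_rhizobiome.tsv"))

    for (kind in c("taxonomic", "functional")) {
      rh <- if (kind == "taxonomic") tax_rhizo else fun_rhizo
      kt <- stage(paste0("predict_", kind),
                  predict_metagenome(rh, inputs$genome_content))
      write_function_table(kt, file.path(out, sprintf(
        "ko_metagenome_%s_core.tsv", kind)))
      write_function_table(ko_to_pathway(kt, inputs$ko_map),
                           file.path(out, sprintf(
                             "pathway_abundance_%s_core.tsv", kind)))
    }

    pooled <- stage("pool_rhizobiomes",
                    pool_rhizobiomes(tax_rhizo, fun_rhizo))
    if (all(table(pooled$groups) >= 2)) {
      rel <- relative_abundance(pooled$table)
      dm_bc <- stage("bray_curtis_asv", bray_curtis(rel))
      stats_out$asv_bray <- stage("compare_asv_bray", compare_tables(
        dm_bc, pooled$groups, config$permutations, config$seed + 11L))
      dm_uf <- stage("unifrac_asv",
                     unweighted_unifrac(pooled$table, inputs$tree))
      stats_out$asv_unifrac <- stage("compare_asv_unifrac", compare_tables(
        dm_uf, pooled$groups, config$permutations, config$seed + 12L))
      utils::write.table(as.matrix(dm_bc),
                         file.path(out, "bray_curtis_asv.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(as.matrix(dm_uf),
                         file.path(out, "unifrac_asv.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      if (!is.null(stats_out$asv_bray$pcoa))
        utils::write.table(stats_out$asv_bray$pcoa$coordinates,
                           file.path(out, "pcoa_bray_asv.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)

      for (lvl in c("KO", "pathway")) {
        pt_tax <- predict_metagenome(tax_rhizo, inputs$genome_content)
        pt_fun <- predict_metagenome(fun_rhizo, inputs$genome_content)
        if (lvl == "pathway") {
          pt_tax <- ko_to_pathway(pt_tax, inputs$ko_map)
          pt_fun <- ko_to_pathway(pt_fun, inputs$ko_map)
        }
        pooled_f <- pool_rhizobiomes(
          abundance_table(pt_tax$abundances,
                          metadata = tax_rhizo$metadata),
          abundance_table(pt_fun$abundances,
                          metadata = fun_rhizo$metadata))
        keep <- colSums(pooled_f$table$counts) > 0
        if (sum(keep) >= 4 && nlevels(droplevels(
          pooled_f$groups[keep])) == 2) {
          sub <- abundance_table(
            pooled_f$table$counts[, keep, drop = FALSE])
          dm <- bray_curtis(relative_abundance(sub))
          stats_out[[paste0(tolower(lvl), "_bray")]] <-
            stage(paste0("compare_", lvl), compare_tables(
              dm, droplevels(pooled_f$groups[keep]),
              config$permutations, config$seed + 13L))
        }
      }
    } else {
      warning("too few samples per core for beta-diversity comparisons")
    }

    diff_out <- stage("welch_bh", {
      res <- list()
      rel_tax <- relative_abundance(tax_rhizo)
      rel_fun <- relative_abundance(fun_rhizo)
      for (rk in c("phylum", "genus")) {
        res[[rk]] <- welch_bh(
          aggregate_rank(rel_tax, inputs$taxonomy, rk),
          aggregate_rank(rel_fun, inputs$taxonomy, rk))
      }
      to_prop <- function(ft) {
        m <- ft$abundances
        cs <- colSums(m)
        m[, cs > 0] <- sweep(m[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
        m
      }
      kt_tax <- predict_metagenome(tax_rhizo, inputs$genome_content)
      kt_fun <- predict_metagenome(fun_rhizo, inputs$genome_content)
      res$KO <- welch_bh(to_prop(kt_tax), to_prop(kt_fun))
      res$pathway <- welch_bh(to_prop(ko_to_pathway(kt_tax, inputs$ko_map)),
                              to_prop(ko_to_pathway(kt_fun, inputs$ko_map)))
      res
    })
    for (lvl in names(diff_out))
      utils::write.table(diff_out[[lvl]],
                         file.path(out, sprintf("welch_bh_%s.tsv", lvl)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("empty core set(s): comparison stages skipped")
  }

  network <- NULL
  hubs <- NULL
  edges <- NULL
  if (have_cores) {
    labels <- core_labels(tax_core, fun_core)
    sizes <- table(tab$metadata$habitat)
    corrected <- if (all(sizes >= 3)) {
      stage("habitat_correct", habitat_correct(tab))
    } else {
      warning("habitat(s) with < 3 samples: habitat correction skipped")
      relative_abundance(tab)
    }
    params <- mic_params(n_permutations = config$mic_permutations,
                         fdr_alpha = config$fdr_alpha,
                         seed = config$seed + 14L)
    edges <- stage("edge_scan", edge_scan(corrected, labels, params))
    edges <- classify_nonlinear(edges)
    network <- stage("build_network", build_network(edges, labels))
    write_network(network, file.path(out, "network_edges.tsv"),
                  format = "edge_tsv")
    if (nrow(network$nodes)) {
      hubs <- stage("hub_taxa", hub_taxa(network))
      network$nodes$degree <-
        hubs$degree[match(network$nodes$id, hubs$id)]
      network$nodes$closeness <-
        hubs$closeness[match(network$nodes$id, hubs$id)]
      network$nodes$betweenness <-
        hubs$betweenness[match(network$nodes$id, hubs$id)]
      network$nodes$is_hub <-
        hubs$is_hub[match(network$nodes$id, hubs$id)]
      write_network(network, file.path(out, "network.graphml"))
      utils::write.table(hubs, file.path(out, "hub_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("network: %d nodes, %d edges, %d hub(s)", nrow(network$nodes),
           nrow(network$edges), sum(hubs$is_hub))
    } else {
      warning("no significant edges: network is empty")
    }
  }

  manifest <- list(package = "dualcore",
                   version = as.character(utils::packageVersion("dualcore")),
                   seed = config$seed,
                   cutoff = config$cutoff,
                   config_hash = unname(tools::md5sum(config$table)),
                   log = log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(out_dir = out, tax_core = tax_core, fun_core = fun_core,
                 tax_rhizobiome = tax_rhizo, fun_rhizobiome = fun_rhizo,
                 ko_table = ko_table, pathway_table = pathway_table,
                 stats = stats_out, differential = diff_out,
                 edges = edges, network = network, hubs = hubs,
                 log = log),
            class = "report_bundle")
}

#' Cut-off sensitivity sweep
#'
#' Repeats the core-identification stages for each cut-off in
#' `config$cutoff_sweep` and reports core sizes together with the
#' between-core ANOSIM R and PERMANOVA R^2 (ASV-level Bray-Curtis).
#' Core sizes are checked to be monotone non-increasing in the cut-off.
#'
#' @param config a [run_config()].
#' @return data.frame: `cutoff`, `n_tax_core`, `n_fun_core`, `anosim_R`,
#'   `permanova_R2`.
#' @export
cutoff_sensitivity <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- stage("load_inputs", load_inputs(config))
  tab <- inputs$table
  ko_table <- stage("predict_metagenome",
                    predict_metagenome(tab, inputs$genome_content))
  sweep_vals <- sort(config$cutoff_sweep)
  rows <- lapply(sweep_vals, function(ct) {
    tax <- taxonomic_core(tab, ct)
    kos <- core_kos(ko_table, ct)
    fun <- suppressWarnings(functional_core(tab, inputs$genome_content,
                                            kos, ct))
    R <- R2 <- NA_real_
    if (length(tax$member_ids) && length(fun$member_ids)) {
      pooled <- pool_rhizobiomes(filter_to_core(tab, tax),
                                 filter_to_core(tab, fun))
      if (all(table(pooled$groups) >= 2)) {
        dm <- bray_curtis(relative_abundance(pooled$table))
        R <- anosim(dm, pooled$groups,
                    n_permutations = config$permutations,
                    seed = config$seed + 11L)$R
        R2 <- permanova(dm, pooled$groups,
                        n_permutations = config$permutations,
                        seed = config$seed + 11L)$R2
      }
    }
    data.frame(cutoff = ct, n_tax_core = length(tax$member_ids),
               n_fun_core = length(fun$member_ids),
               anosim_R = R, permanova_R2 = R2)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(diff(out$n_tax_core) <= 0), all(diff(out$n_fun_core) <= 0))
  out
}
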