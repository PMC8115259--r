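# Core-rhizobiome extraction: the prevalence-based taxonomic core and the
# KO-mediated functional core, plus filtering, overlap and summary
# statistics. Presence means raw count > 0 (the QIIME2 core-features
# default); an optional minimum-abundance floor is exposed.

#' Per-ASV prevalence (fraction of samples with presence)
#'
#' @param table an [abundance_table()].
#' @param floor minimum abundance counted as presence; presence is
#'   `counts > floor` (default 0).
#' @return named numeric vector in `[0, 1]`, one entry per ASV.
#' @export
prevalence <- function(table, floor = 0) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$counts) < 1) stop("table has no samples")
  rowMeans(table$counts > floor)
}

#' Taxonomic core: ASVs present in at least `cutoff` of samples
#'
#' @param table an [abundance_table()].
#' @param cutoff prevalence cut-off in (0, 1]; default 0.75.
#' @param floor presence floor passed to [prevalence()].
#' @return a [core_set()] of kind `"taxonomic"`.
#' @export
taxonomic_core <- function(table, cutoff = 0.75, floor = 0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff > 1)
    stop("`cutoff` must lie in (0, 1]")
  prev <- prevalence(table, floor = floor)
  members <- names(prev)[prev >= cutoff]
  core_set("taxonomic", members, cutoff, prevalence = prev)
}

#' Core KOs: KOs present in at least `cutoff` of samples
#'
#' @param ko_table a KO-level [function_table()] (rows KOs, columns
#'   samples), e.g. from [predict_metagenome()].
#' @param cutoff prevalence cut-off in (0, 1]; default 0.75.
#' @return character vector of core KO ids.
#' @export
core_kos <- function(ko_table, cutoff = 0.75) {
  stopifnot(inherits(ko_table, "function_table"))
  if (ko_table$level != "KO")
    stop("core_kos requires a KO-level table, got level '",
         ko_table$level, "'")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must lie in (0, 1]")
  prev <- rowMeans(ko_table$abundances > 0)
  names(prev)[prev >= cutoff]
}

#' Functional core: ASVs qualified through core KOs
#'
#' An ASV is a functional-core member if it carries at least one core KO
#' (copy number >= 1) and is present in at least `cutoff` of the samples,
#' or if it carries at least `redundancy_min_kos` core KOs regardless of
#' its own prevalence (the functional-redundancy inclusion: taxa carrying
#' several core functions are retained even when individually sparse).
#' Multi-KO ASVs are counted once; their provenance lists every qualifying
#' core KO.
#'
#' @param table an [abundance_table()].
#' @param genome_content a [genome_content_table()].
#' @param core_ko_ids character vector of core KO ids (subset of the
#'   genome-content KO ids); an empty vector yields an empty core with a
#'   warning.
#' @param cutoff prevalence cut-off in (0, 1]; default 0.75.
#' @param conditioning `"all_samples"` (default): prevalence is computed
#'   over all samples; `"ko_detected"`: over the samples in which at least
#'   one of the ASV's core KOs is detected in `ko_table`.
#' @param ko_table KO-level [function_table()], required when
#'   `conditioning = "ko_detected"`.
#' @param redundancy_min_kos minimum number of carried core KOs that
#'   qualifies an ASV irrespective of prevalence (default 2); `NULL`
#'   disables the redundancy inclusion.
#' @param floor presence floor passed to [prevalence()].
#' @return a [core_set()] of kind `"functional"`.
#' @export
functional_core <- function(table, genome_content, core_ko_ids,
                            cutoff = 0.75,
                            conditioning = c("all_samples", "ko_detected"),
                            ko_table = NULL, redundancy_min_kos = 2,
                            floor = 0) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(genome_content, "genome_content_table"))
  conditioning <- match.arg(conditioning)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stop("`cutoff` must lie in (0, 1]")
  core_ko_ids <- as.character(core_ko_ids)
  missing_ko <- setdiff(core_ko_ids, colnames(genome_content$ko))
  if (length(missing_ko))
    stop("core KO id(s) absent from genome content: ",
         paste(missing_ko, collapse = ", "))
  prev_all <- prevalence(table, floor = floor)
  if (!length(core_ko_ids)) {
    warning("empty core KO set: functional core is empty")
    return(core_set("functional", character(0), cutoff,
                    prevalence = prev_all, provenance = list()))
  }
  shared <- intersect(asv_ids(table), rownames(genome_content$ko))
  cn <- genome_content$ko[shared, core_ko_ids, drop = FALSE]
  carries <- lapply(seq_along(shared),
                    function(i) core_ko_ids[cn[i, ] >= 1])
  names(carries) <- shared
  n_carried <- lengths(carries)

  prev <- prev_all[shared]
  if (conditioning == "ko_detected") {
    if (is.null(ko_table) || !inherits(ko_table, "function_table") ||
        ko_table$level != "KO")
      stop("conditioning = 'ko_detected' requires a KO-level `ko_table`")
    ko_abund <- ko_table$abundances
    prev <- vapply(shared, function(a) {
      k <- intersect(carries[[a]], rownames(ko_abund))
      if (!length(k)) return(0)
      in_samples <- colSums(ko_abund[k, , drop = FALSE] > 0) > 0
      sel <- colnames(ko_abund)[in_samples]
      sel <- intersect(sel, sample_ids(table))
      if (!length(sel)) return(0)
      mean(table$counts[a, sel] > floor)
    }, numeric(1))
  }

  qualifies <- (n_carried >= 1 & prev >= cutoff)
  if (!is.null(redundancy_min_kos))
    qualifies <- qualifies | (n_carried >= redundancy_min_kos)
  members <- shared[qualifies]
  core_set("functional", members, cutoff, prevalence = prev_all,
           provenance = carries[members])
}

#' Restrict a table to a core set (a core rhizobiome)
#'
#' Rows are restricted to the core members; samples whose core-restricted
#' column is all zero are dropped (the filter-samples analogue) with a
#' logged count.
#'
#' @param table an [abundance_table()].
#' @param core a [core_set()] whose members all occur in `table`.
#' @return an [abundance_table()] restricted to the core members.
#' @export
filter_to_core <- function(table, core) {
  stopifnot(inherits(table, "abundance_table"), inherits(core, "core_set"))
  missing <- setdiff(core$member_ids, asv_ids(table))
  if (length(missing))
    stop("core member(s) absent from table: ",
         paste(missing, collapse = ", "))
  m <- table$counts[core$member_ids, , drop = FALSE]
  keep <- colSums(m) > 0
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped (all-zero on core rows)")
  abundance_table(m[, keep, drop = FALSE],
                  metadata = table$metadata[keep, , drop = FALSE],
                  relative = FALSE)
}

#' Overlap between two core sets
#'
#' @param tax,fun two [core_set()] objects over the same source table.
#' @return list with `shared_ids` (intersection) and `pct_shared`
#'   (`100 * |intersection| / |union|`; 0 when both sets are empty).
#' @export
shared_core <- function(tax, fun) {
  stopifnot(inherits(tax, "core_set"), inherits(fun, "core_set"))
  shared <- intersect(tax$member_ids, fun$member_ids)
  un <- union(tax$member_ids, fun$member_ids)
  list(shared_ids = shared,
       pct_shared = if (length(un)) 100 * length(shared) / length(un) else 0)
}

#' Good's coverage of a sample
#'
#' Computed as `1 - S/N` with `S` the number of ASVs observed exactly once
#' (singletons) and `N` the number of ASVs observed at all (count > 0).
#'
#' @param sample_column numeric vector of counts for one sample with at
#'   least one positive entry.
#' @return coverage fraction in `[0, 1]`.
#' @export
goods_coverage <- function(sample_column) {
  if (!any(sample_column > 0)) stop("all-zero sample column")
  n_obs <- sum(sample_column > 0)
  n_single <- sum(sample_column == 1)
  1 - n_single / n_obs
}

#' Summary statistics for a core set
#'
#' @param table the source [abundance_table()].
#' @param core the [core_set()] to summarize.
#' @param other_core optional second [core_set()] for overlap statistics.
#' @return list `pct_of_all_asvs`, `pct_of_total_relative_abundance` (mean
#'   over samples of the core's share of reads, in percent),
#'   `n_shared_with_other_core`, `pct_shared`.
#' @export
core_summary <- function(table, core, other_core = NULL) {
  stopifnot(inherits(table, "abundance_table"), inherits(core, "core_set"))
  totals <- colSums(table$counts)
  ok <- totals > 0
  core_sum <- colSums(table$counts[core$member_ids, , drop = FALSE])
  pct_ra <- if (any(ok)) mean(100 * core_sum[ok] / totals[ok]) else 0
  out <- list(pct_of_all_asvs = 100 * length(core$member_ids) /
                nrow(table$counts),
              pct_of_total_relative_abundance = pct_ra,
              n_shared_with_other_core = NA_integer_,
              pct_shared = NA_real_)
  if (!is.null(other_core)) {
    sh <- shared_core(core, other_core)
    out$n_shared_with_other_core <- length(sh$shared_ids)
    out$pct_shared <- sh$pct_shared
  }
  out
}
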