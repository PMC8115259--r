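# PICRUSt-style metagenome prediction from a user-supplied genome-content
# reference: KO abundance = sum over ASVs of (16S-corrected) abundance times
# KO copy number; pathway abundance = plain sum over member KOs (no MinPath
# style pruning -- a documented divergence from PICRUSt2).

#' Predict the KO metagenome of a community
#'
#' KO `k` abundance in sample `j` is
#' `sum_a (count[a, j] / copies16S[a]) * copy[a, k]` (division by the 16S
#' copy number is skipped when `normalize_16s = FALSE`).
#'
#' @param table an [abundance_table()]; every ASV must occur in `gc`.
#' @param gc a [genome_content_table()].
#' @param normalize_16s divide abundances by per-ASV 16S copy number before
#'   multiplying by KO copy numbers (default `TRUE`, the PICRUSt2
#'   convention).
#' @return a KO-level [function_table()]; KOs carried by no present ASV get
#'   an all-zero row.
#' @export
predict_metagenome <- function(table, gc, normalize_16s = TRUE) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(gc, "genome_content_table"))
  missing <- setdiff(asv_ids(table), rownames(gc$ko))
  if (length(missing))
    stop("ASV(s) missing from genome content: ",
         paste(missing, collapse = ", "))
  m <- table$counts
  if (normalize_16s) m <- m / gc$copies_16s[rownames(m)]
  cn <- gc$ko[rownames(m), , drop = FALSE]
  ko <- t(cn) %*% m
  function_table(ko, level = "KO")
}

#' Aggregate a KO table to pathway level
#'
#' Pathway abundance is the sum of its member KOs' abundances; a KO mapped
#' to several pathways contributes fully to each, and KOs with an empty map
#' contribute nowhere.
#'
#' @param ko_table a KO-level [function_table()].
#' @param map a [ko_pathway_map()].
#' @return a pathway-level [function_table()] (possibly with zero rows when
#'   the map is empty).
#' @export
ko_to_pathway <- function(ko_table, map) {
  stopifnot(inherits(ko_table, "function_table"),
            inherits(map, "ko_pathway_map"))
  if (ko_table$level != "KO")
    stop("ko_to_pathway requires a KO-level table")
  kos <- intersect(rownames(ko_table$abundances), names(map))
  pairs <- data.frame(
    ko = rep(kos, lengths(map[kos])),
    pathway = unlist(map[kos], use.names = FALSE),
    stringsAsFactors = FALSE)
  pathways <- sort(unique(pairs$pathway))
  out <- matrix(0, length(pathways), ncol(ko_table$abundances),
                dimnames = list(pathways, colnames(ko_table$abundances)))
  for (p in pathways) {
    members <- pairs$ko[pairs$pathway == p]
    out[p, ] <- colSums(ko_table$abundances[members, , drop = FALSE])
  }
  function_table(out, level = "pathway")
}
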