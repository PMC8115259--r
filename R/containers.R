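#' ASV-by-sample abundance table
#'
#' The universal input container: a non-negative numeric matrix with ASVs as
#' rows and samples as columns, plus per-sample metadata (study, habitat,
#' group). Tables are either raw read counts or relative abundances; the
#' `relative` flag records which, and relative tables must have unit column
#' sums.
#'
#' @param counts numeric matrix, ASVs x samples, with unique row and column
#'   names and no negative entries.
#' @param metadata `data.frame` with one row per sample (rownames = sample
#'   ids). Missing columns among `study`, `habitat`, `group` are filled with
#'   `"unspecified"`.
#' @param relative logical; `TRUE` if entries are relative abundances
#'   (columns must then sum to 1 within 1e-9 and no column may be all zero).
#' @return an object of class `abundance_table` with elements `counts`,
#'   `metadata`, `relative`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("ASV_1", "ASV_2"), c("S1", "S2")))
#' abundance_table(m)
#' @export
abundance_table <- function(counts, metadata = NULL, relative = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have ASV rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicated ASV id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative entry at row '%s', column '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]))
  if (is.null(metadata)) {
    metadata <- data.frame(row.names = colnames(counts))
  }
  if (!all(colnames(counts) %in% rownames(metadata)))
    stop("metadata must cover all samples")
  metadata <- metadata[colnames(counts), , drop = FALSE]
  for (col in c("study", "habitat", "group")) {
    if (is.null(metadata[[col]])) metadata[[col]] <- "unspecified"
    metadata[[col]] <- as.character(metadata[[col]])
  }
  if (isTRUE(relative)) {
    cs <- colSums(counts)
    if (any(cs == 0))
      stop("relative table may not contain all-zero samples: ",
           paste(colnames(counts)[cs == 0], collapse = ", "))
    if (any(abs(cs - 1) > 1e-9))
      stop("relative table columns must sum to 1 (max deviation ",
           format(max(abs(cs - 1))), ")")
  }
  structure(list(counts = counts, metadata = metadata,
                 relative = isTRUE(relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d ASVs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$relative) "relative" else "counts"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

asv_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

#' Taxonomy assignments for ASVs
#'
#' @param df data.frame with column `asv_id` plus the six ranks
#'   `kingdom, phylum, class, order, family, genus`. `NA` or empty strings
#'   are replaced by the `"unassigned"` sentinel.
#' @return class `taxonomy_table`: a data.frame keyed by `asv_id`.
#' @export
taxonomy_table <- function(df) {
  ranks <- taxonomy_ranks()
  if (!"asv_id" %in% names(df)) stop("taxonomy needs an `asv_id` column")
  dup <- df$asv_id[duplicated(df$asv_id)]
  if (length(dup))
    stop("duplicated ASV id(s) in taxonomy: ",
         paste(unique(dup), collapse = ", "))
  for (r in ranks) {
    if (is.null(df[[r]])) df[[r]] <- "unassigned"
    v <- as.character(df[[r]])
    v[is.na(v) | v == ""] <- "unassigned"
    df[[r]] <- v
  }
  out <- df[, c("asv_id", ranks)]
  rownames(out) <- out$asv_id
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Ordered taxonomic ranks used throughout the package
#' @return character vector of the six ranks, kingdom to genus.
#' @export
taxonomy_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

#' Per-ASV genome content (KO copy numbers and 16S copies)
#'
#' Stand-in for the PICRUSt2 reference: how many copies of each KEGG
#' ortholog (KO) each ASV's inferred genome carries, plus its 16S rRNA gene
#' copy number used to de-bias read counts.
#'
#' @param ko_copy_number integer matrix, ASVs x KOs, non-negative.
#' @param copies_16s named integer vector (>= 1), one entry per ASV.
#' @return class `genome_content_table`.
#' @export
genome_content_table <- function(ko_copy_number, copies_16s) {
  if (is.null(rownames(ko_copy_number)) || is.null(colnames(ko_copy_number)))
    stop("ko_copy_number needs ASV rownames and KO colnames")
  neg <- which(ko_copy_number < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative copy number at row '%s', column '%s'",
                 rownames(ko_copy_number)[neg[1, 1]],
                 colnames(ko_copy_number)[neg[1, 2]]))
  if (!all(rownames(ko_copy_number) %in% names(copies_16s)))
    stop("copies_16s must cover all ASVs")
  copies_16s <- copies_16s[rownames(ko_copy_number)]
  if (any(copies_16s < 1))
    stop("16S copy numbers must be >= 1; offending ASV(s): ",
         paste(names(copies_16s)[copies_16s < 1], collapse = ", "))
  structure(list(ko = ko_copy_number, copies_16s = copies_16s),
            class = "genome_content_table")
}

#' @export
print.genome_content_table <- function(x, ...) {
  cat(sprintf("genome_content_table: %d ASVs x %d KOs\n",
              nrow(x$ko), ncol(x$ko)))
  invisible(x)
}

#' KO-to-pathway membership map
#'
#' @param map named list: KO id -> character vector of pathway ids (possibly
#'   empty: a KO may map to no pathway).
#' @return class `ko_pathway_map`.
#' @export
ko_pathway_map <- function(map) {
  if (is.null(names(map)) || any(names(map) == ""))
    stop("map must be a named list keyed by KO id")
  dup <- names(map)[duplicated(names(map))]
  if (length(dup))
    stop("duplicated KO id(s): ", paste(unique(dup), collapse = ", "))
  map <- lapply(map, function(p) {
    p <- as.character(p)
    p <- p[!is.na(p) & p != ""]
    unique(p)
  })
  structure(map, class = "ko_pathway_map")
}

#' KO- or pathway-level predicted function table
#'
#' @param abundances non-negative numeric matrix, features x samples.
#' @param level `"KO"`, `"pathway"`, or a taxonomic rank name for
#'   rank-aggregated tables.
#' @return class `function_table`.
#' @export
function_table <- function(abundances, level = c("KO", "pathway",
                                                 taxonomy_ranks())) {
  level <- match.arg(level)
  if ((nrow(abundances) > 0 && is.null(rownames(abundances))) ||
      (ncol(abundances) > 0 && is.null(colnames(abundances))))
    stop("abundances need feature rownames and sample colnames")
  dup <- rownames(abundances)[duplicated(rownames(abundances))]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  if (any(abundances < 0)) stop("negative abundance entries")
  structure(list(level = level, abundances = abundances),
            class = "function_table")
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf("function_table (%s): %d features x %d samples\n",
              x$level, nrow(x$abundances), ncol(x$abundances)))
  invisible(x)
}

#' A named set of core ASVs
#'
#' @param kind `"taxonomic"` or `"functional"`.
#' @param member_ids character vector of ASV ids.
#' @param cutoff prevalence cut-off in (0, 1] that produced the set.
#' @param prevalence named numeric vector of per-member prevalence.
#' @param provenance for functional cores, a named list mapping each member
#'   to the core KO ids that qualified it.
#' @return class `core_set`.
#' @export
core_set <- function(kind = c("taxonomic", "functional"), member_ids,
                     cutoff, prevalence, provenance = NULL) {
  kind <- match.arg(kind)
  member_ids <- as.character(member_ids)
  if (anyDuplicated(member_ids)) stop("duplicated member ids")
  if (!all(member_ids %in% names(prevalence)))
    stop("prevalence must cover all members")
  prevalence <- prevalence[member_ids]
  if (kind == "functional") {
    if (is.null(provenance) && length(member_ids))
      stop("functional core requires provenance")
    if (length(member_ids) &&
        (!all(member_ids %in% names(provenance)) ||
         any(lengths(provenance[member_ids]) == 0)))
      stop("every functional core member needs non-empty provenance")
    provenance <- provenance[member_ids]
  }
  structure(list(kind = kind, member_ids = member_ids, cutoff = cutoff,
                 prevalence = prevalence, provenance = provenance),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set (%s): %d members at cutoff %.2f\n",
              x$kind, length(x$member_ids), x$cutoff))
  invisible(x)
}
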