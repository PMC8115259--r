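# On-disk formats. TSV dialect: first header cell "#OTU ID", tab-separated,
# UTF-8, no quoting (QIIME-classic). Numbers are written with "%.17g" so
# doubles round-trip bit-exactly. BIOM is the 1.0 JSON dialect (dense),
# delegated to the biomformat package. Trees are newick via ape.

fmt_num <- function(v) sprintf("%.17g", v)

write_tsv_matrix <- function(m, path, first_cell = "#OTU ID") {
  header <- paste(c(first_cell, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  ncol <- length(header) - 1L
  ids <- vapply(parts[-1], `[[`, character(1), 1L)
  vals <- lapply(parts[-1], function(p) {
    if (length(p) != ncol + 1L)
      stop("ragged row for id '", p[[1]], "' in ", path)
    suppressWarnings(as.numeric(p[-1]))
  })
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(0), 0, ncol)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric entry at row '%s', column '%s' in %s",
                 ids[bad[1]], header[-1][bad[2]], path))
  }
  dimnames(m) <- list(ids, header[-1])
  m
}

#' Write an abundance table to disk
#'
#' @param table an [abundance_table()].
#' @param path output file.
#' @param dialect `"tsv"` (QIIME-classic, `#OTU ID` header) or `"biom-json"`
#'   (BIOM 1.0 dense JSON).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "abundance_table"))
  if (dialect == "tsv") {
    write_tsv_matrix(table$counts, path)
  } else {
    b <- biomformat::make_biom(table$counts)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read an abundance table
#'
#' Rejects malformed input: duplicated ids and negative entries are hard
#' errors naming the offender.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @param metadata optional path to a sample-metadata TSV
#'   (see [write_sample_metadata()]).
#' @param relative logical flag recorded on the returned table.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, dialect = c("tsv", "biom-json"),
                           metadata = NULL, relative = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") {
    m <- read_tsv_matrix(path)
  } else {
    b <- biomformat::read_biom(path)
    m <- methods::as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "double"
  }
  md <- if (!is.null(metadata)) read_sample_metadata(metadata) else NULL
  abundance_table(m, metadata = md, relative = relative)
}

#' Write per-sample metadata (sample_id, study, habitat, group) as TSV
#' @param metadata data.frame with rownames = sample ids.
#' @param path output file.
#' @export
write_sample_metadata <- function(metadata, path) {
  cols <- intersect(c("study", "habitat", "group"), names(metadata))
  header <- paste(c("sample_id", cols), collapse = "\t")
  body <- vapply(seq_len(nrow(metadata)), function(i) {
    paste(c(rownames(metadata)[i],
            vapply(cols, function(cl) as.character(metadata[[cl]][i]),
                   character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read per-sample metadata written by [write_sample_metadata()]
#' @param path input file.
#' @return data.frame with rownames = sample ids.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs `sample_id` column")
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  df
}

#' Write a taxonomy table as TSV
#' @param taxonomy a [taxonomy_table()].
#' @param path output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  header <- paste(c("asv_id", taxonomy_ranks()), collapse = "\t")
  body <- apply(as.matrix(taxonomy[, c("asv_id", taxonomy_ranks())]), 1,
                paste, collapse = "\t")
  writeLines(c(header, unname(body)), path, useBytes = TRUE)
  invisible(path)
}

#' Read a taxonomy TSV written by [write_taxonomy()]
#' @param path input file.
#' @return a [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  taxonomy_table(df)
}

#' Write a genome-content table as TSV
#'
#' One row per ASV: KO copy-number columns plus a final `n_16S` column.
#' @param gc a [genome_content_table()].
#' @param path output file.
#' @export
write_genome_content <- function(gc, path) {
  m <- cbind(gc$ko, n_16S = gc$copies_16s[rownames(gc$ko)])
  write_tsv_matrix(m, path, first_cell = "#ASV ID")
  invisible(path)
}

#' Read a genome-content TSV written by [write_genome_content()]
#' @param path input file.
#' @return a [genome_content_table()].
#' @export
read_genome_content <- function(path) {
  m <- read_tsv_matrix(path)
  if (!"n_16S" %in% colnames(m)) stop("missing `n_16S` column in ", path)
  ko <- m[, setdiff(colnames(m), "n_16S"), drop = FALSE]
  genome_content_table(ko, stats::setNames(m[, "n_16S"], rownames(m)))
}

#' Write a KO-to-pathway map as two-column TSV
#'
#' One row per (KO, pathway) pair; a KO with no pathway gets a single row
#' with an empty pathway field so the empty set round-trips.
#' @param map a [ko_pathway_map()].
#' @param path output file.
#' @export
write_ko_map <- function(map, path) {
  rows <- unlist(lapply(names(map), function(k) {
    p <- map[[k]]
    if (!length(p)) p <- ""
    paste(k, p, sep = "\t")
  }))
  writeLines(c("ko_id\tpathway_id", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a KO-to-pathway TSV written by [write_ko_map()]
#' @param path input file.
#' @return a [ko_pathway_map()].
#' @export
read_ko_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  sp <- split(df$pathway_id, df$ko_id)
  sp <- sp[unique(df$ko_id)]  # keep file order
  ko_pathway_map(lapply(sp, function(p) p[p != ""]))
}

#' Write a phylogenetic tree as newick
#'
#' Branch lengths are mandatory on write.
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must carry branch lengths on write")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' Missing branch lengths are tolerated with a warning and set to 0.
#' @param path input file.
#' @return an `ape::phylo` object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; treating them as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a co-occurrence network
#'
#' GraphML carries node attributes (core_label, degree, closeness,
#' betweenness, is_hub) and edge attributes (mic, pearson_r, nonlinearity,
#' p_raw, q_value); `edge_tsv` writes the edge table with full double
#' precision.
#'
#' @param network a `mic_network` (see [build_network()]).
#' @param path output file.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "mic_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    e <- network$edges
    header <- "from\tto\tmic\tpearson_r\tnonlinearity\tp_raw\tq_bh"
    body <- vapply(seq_len(nrow(e)), function(i) {
      paste(c(e$from[i], e$to[i],
              fmt_num(c(e$mic[i], e$pearson_r[i], e$nonlinearity[i],
                        e$p_raw[i], e$q_bh[i]))), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read an edge table written by `write_network(format = "edge_tsv")`
#' @param path input file.
#' @return data.frame of edges.
#' @export
read_network_edges <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(from = "character", to = "character"))
}

#' Write a core set as TSV (id, prevalence, provenance)
#' @param core a [core_set()].
#' @param path output file.
#' @export
write_core_set <- function(core, path) {
  prov <- if (core$kind == "functional")
    vapply(core$member_ids,
           function(m) paste(core$provenance[[m]], collapse = ";"),
           character(1))
  else rep("", length(core$member_ids))
  header <- sprintf("#kind=%s cutoff=%s", core$kind, fmt_num(core$cutoff))
  body <- paste(core$member_ids, fmt_num(core$prevalence), prov, sep = "\t")
  writeLines(c(header, "asv_id\tprevalence\tprovenance", body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a core-set TSV written by [write_core_set()]
#' @param path input file.
#' @return a [core_set()].
#' @export
read_core_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- regmatches(lines[1],
                     regexec("#kind=(\\w+) cutoff=([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(meta) != 3) stop("malformed core-set header in ", path)
  kind <- meta[2]
  cutoff <- as.numeric(meta[3])
  if (length(lines) <= 2) {
    return(core_set(kind, character(0), cutoff,
                    prevalence = stats::setNames(numeric(0), character(0)),
                    provenance = if (kind == "functional") list() else NULL))
  }
  parts <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  prev <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]),
                                 numeric(1)), ids)
  prov <- NULL
  if (kind == "functional") {
    prov <- stats::setNames(lapply(parts, function(p) {
      if (length(p) < 3 || p[3] == "") character(0)
      else strsplit(p[3], ";", fixed = TRUE)[[1]]
    }), ids)
  }
  core_set(kind, ids, cutoff, prevalence = prev, provenance = prov)
}

#' Write a KO/pathway function table as TSV
#' @param ft a [function_table()].
#' @param path output file.
#' @export
write_function_table <- function(ft, path) {
  write_tsv_matrix(ft$abundances, path,
                   first_cell = sprintf("#%s ID", ft$level))
  invisible(path)
}

#' Read a function table written by [write_function_table()]
#' @param path input file.
#' @param level the table level (`"KO"` or `"pathway"`).
#' @return a [function_table()].
#' @export
read_function_table <- function(path, level = "KO") {
  function_table(read_tsv_matrix(path), level = level)
}
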