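# Habitat-corrected MIC co-occurrence network over the union of the
# taxonomic and functional cores: MIC edge scores with permutation p-values
# and BH-FDR edge calling, non-linearity classification (MIC - r^2), and
# centrality-based hub detection.

#' MIC and edge-scan parameters
#'
#' @param alpha_exponent grid-size exponent in (0, 1]: grids are bounded by
#'   `B(n) = max(4, n^alpha_exponent)` cells (default 0.6, the MINE
#'   reference value).
#' @param clumps_factor superclump refinement factor (default 15, MINE
#'   reference value).
#' @param n_permutations permutations per pair for edge p-values
#'   (default 200).
#' @param fdr_alpha BH false-discovery-rate level in (0, 1) (default 0.05).
#' @param seed integer seed used by [edge_scan()].
#' @return class `mic_params`.
#' @export
mic_params <- function(alpha_exponent = 0.6, clumps_factor = 15,
                       n_permutations = 200, fdr_alpha = 0.05, seed = 1) {
  if (!is.numeric(alpha_exponent) || alpha_exponent <= 0 ||
      alpha_exponent > 1)
    stop("`alpha_exponent` must lie in (0, 1]")
  if (!is.numeric(clumps_factor) || clumps_factor < 1)
    stop("`clumps_factor` must be a positive integer")
  if (!is.numeric(fdr_alpha) || fdr_alpha <= 0 || fdr_alpha >= 1)
    stop("`fdr_alpha` must lie in (0, 1)")
  structure(list(alpha_exponent = alpha_exponent,
                 clumps_factor = as.integer(clumps_factor),
                 n_permutations = as.integer(n_permutations),
                 fdr_alpha = fdr_alpha, seed = seed),
            class = "mic_params")
}

mic_grid_bound <- function(n, params) max(4, n^params$alpha_exponent)

#' Habitat-filtering correction of an abundance table
#'
#' Within each habitat group, each ASV's relative abundance is divided by
#' its habitat mean (ASVs with zero habitat mean stay 0), so a shared
#' habitat-driven shift no longer induces spurious co-occurrence.
#'
#' @param table an [abundance_table()]; counts are converted to relative
#'   abundances first.
#' @param habitat_labels named character vector (sample -> habitat);
#'   defaults to the table's `metadata$habitat`. Every habitat needs >= 3
#'   samples.
#' @return an [abundance_table()] of corrected values (no longer
#'   compositional; the relative flag is off and a `habitat_corrected`
#'   attribute is set).
#' @export
habitat_correct <- function(table, habitat_labels = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(habitat_labels))
    habitat_labels <- stats::setNames(table$metadata$habitat,
                                      rownames(table$metadata))
  samples <- sample_ids(table)
  if (!all(samples %in% names(habitat_labels)))
    stop("unlabeled sample(s): ",
         paste(setdiff(samples, names(habitat_labels)), collapse = ", "))
  habitat_labels <- habitat_labels[samples]
  sizes <- table(habitat_labels)
  if (any(sizes < 3))
    stop("habitat(s) with fewer than 3 samples (correction unstable): ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  rel <- relative_abundance(table)
  m <- rel$counts
  for (h in unique(habitat_labels)) {
    sel <- which(habitat_labels == h)
    mu <- rowMeans(m[, sel, drop = FALSE])
    nz <- mu > 0
    m[nz, sel] <- m[nz, sel, drop = FALSE] / mu[nz]
  }
  out <- abundance_table(m, metadata = table$metadata, relative = FALSE)
  attr(out, "habitat_corrected") <- TRUE
  out
}

#' Maximal information coefficient of a pair of vectors
#'
#' MIC is the maximum over axis grids with at most `B(n)` cells of the
#' grid mutual information normalized by `log2(min(nx, ny))`. For
#' `n <= 30` (or `method = "exact"`) every row partition is enumerated and
#' the column partition solved exactly by dynamic programming; otherwise
#' the MINE approximation (row equipartition plus clump-restricted column
#' DP, both orientations) is used.
#'
#' @param x,y numeric vectors of equal length `n >= 10` with finite values.
#' @param params a [mic_params()].
#' @param method `"auto"` (default), `"approx"`, or `"exact"`.
#' @return list `mic`, `pearson_r`, `nonlinearity` (`mic - r^2`), and
#'   `degenerate` (`TRUE` for constant input, in which case `mic` is `NA`
#'   and the pair should be excluded from testing).
#' @export
mic <- function(x, y, params = mic_params(),
                method = c("auto", "approx", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 10) stop("MIC needs n >= 10")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(mic = NA_real_, pearson_r = NA_real_,
                nonlinearity = NA_real_, degenerate = TRUE))
  B <- mic_grid_bound(n, params)
  if (method == "auto") method <- if (n <= 30) "exact" else "approx"
  m <- if (method == "exact") mic_exact_cpp(x, y, B)
       else mic_approx_cpp(x, y, B, params$clumps_factor)
  r <- stats::cor(x, y)
  list(mic = m, pearson_r = r, nonlinearity = m - r^2, degenerate = FALSE)
}

#' Score all core-ASV pairs and call significant MIC edges
#'
#' Every unordered pair over the labeled core ASVs is scored with the
#' approximate MIC; per-pair permutation p-values (shuffling one vector)
#' are adjusted by Benjamini-Hochberg across all pairs, and edges with
#' `q < fdr_alpha` are flagged significant. Pairs with a constant vector
#' are degenerate and excluded from testing.
#'
#' @param table an [abundance_table()], normally habitat-corrected
#'   (see [habitat_correct()]).
#' @param core_labels named character vector over ASVs with values
#'   `"taxonomic"`, `"functional"`, or `"both"`; only named ASVs present
#'   in the table are scored.
#' @param params a [mic_params()] (permutation count, FDR level, seed).
#' @param pairs `"all"` (default): every pair; `"bipartite"`: only pairs
#'   joining a taxonomic-labeled to a functional-labeled ASV (an ASV
#'   labeled `"both"` joins either side).
#' @return data.frame of edge statistics: `from`, `to`, `mic`,
#'   `pearson_r`, `nonlinearity`, `p_raw`, `q_bh`, `significant`,
#'   `degenerate`.
#' @export
edge_scan <- function(table, core_labels, params = mic_params(),
                      pairs = c("all", "bipartite")) {
  stopifnot(inherits(table, "abundance_table"))
  pairs <- match.arg(pairs)
  nodes <- intersect(names(core_labels), asv_ids(table))
  if (length(nodes) < 2) stop("need at least 2 labeled ASVs in the table")
  m <- table$counts[nodes, , drop = FALSE]
  n <- ncol(m)
  if (n < 10) stop("MIC edge scan needs at least 10 samples")
  B <- mic_grid_bound(n, params)
  combs <- utils::combn(nodes, 2)
  if (pairs == "bipartite") {
    la <- core_labels[combs[1, ]]
    lb <- core_labels[combs[2, ]]
    keep <- (la %in% c("taxonomic", "both") &
             lb %in% c("functional", "both")) |
            (la %in% c("functional", "both") &
             lb %in% c("taxonomic", "both"))
    keep <- keep & !(la == lb & la != "both")
    combs <- combs[, keep, drop = FALSE]
  }
  set.seed(params$seed)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    x <- m[a, ]; y <- m[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(from = a, to = b, mic = NA_real_,
                        pearson_r = NA_real_, nonlinearity = NA_real_,
                        p_raw = NA_real_, degenerate = TRUE))
    }
    obs <- mic_approx_cpp(x, y, B, params$clumps_factor)
    perm <- mic_perm_cpp(x, y, B, params$clumps_factor,
                         params$n_permutations)
    p <- (1 + sum(perm >= obs)) / (params$n_permutations + 1)
    r <- stats::cor(x, y)
    data.frame(from = a, to = b, mic = obs, pearson_r = r,
               nonlinearity = obs - r^2, p_raw = p, degenerate = FALSE)
  })
  edges <- do.call(rbind, rows)
  edges$q_bh <- NA_real_
  tested <- !edges$degenerate
  edges$q_bh[tested] <- stats::p.adjust(edges$p_raw[tested], method = "BH")
  edges$significant <- !is.na(edges$q_bh) & edges$q_bh < params$fdr_alpha
  edges
}

#' Flag non-linear associations
#'
#' An edge is non-linear when `mic - pearson_r^2 > threshold`.
#'
#' @param edges edge data.frame from [edge_scan()].
#' @param threshold non-linearity margin (default 0).
#' @return `edges` with a `nonlinear` column; the fraction of non-linear
#'   edges among significant ones is attached as attribute
#'   `frac_nonlinear` (0 when there are no significant edges).
#' @export
classify_nonlinear <- function(edges, threshold = 0) {
  edges$nonlinear <- !is.na(edges$nonlinearity) &
    edges$nonlinearity > threshold
  sig <- edges$significant & !edges$degenerate
  attr(edges, "frac_nonlinear") <-
    if (any(sig)) mean(edges$nonlinear[sig]) else 0
  edges
}

#' Build the co-occurrence network from significant edges
#'
#' Nodes are the endpoints of significant edges (isolated core ASVs are
#' excluded), labeled taxonomic/functional/both per core membership.
#'
#' @param edges edge data.frame from [edge_scan()] (only rows with
#'   `significant == TRUE` are used).
#' @param core_labels named character vector as in [edge_scan()].
#' @return class `mic_network`: `nodes` (data.frame `id`, `core_label`),
#'   `edges` (significant edges).
#' @export
build_network <- function(edges, core_labels) {
  sig <- edges[!is.na(edges$significant) & edges$significant, , drop = FALSE]
  ids <- sort(unique(c(sig$from, sig$to)))
  nodes <- data.frame(id = ids,
                      core_label = unname(core_labels[ids]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = sig), class = "mic_network")
}

#' @export
print.mic_network <- function(x, ...) {
  cat(sprintf("mic_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "mic", "pearson_r", "nonlinearity",
                      "p_raw", "q_bh"), drop = FALSE],
    directed = FALSE, vertices = network$nodes)
  names(igraph::edge_attr(g))[names(igraph::edge_attr(g)) == "q_bh"] <-
    "q_value"
  g
}

#' Hub taxa of a co-occurrence network
#'
#' Centralities are computed on the undirected, unweighted graph (shortest
#' paths in edge counts): degree; closeness = 1 / (sum of shortest-path
#' distances to all reachable nodes); betweenness = fraction of shortest
#' paths the node lies on. Hubs are the nodes simultaneously among the top
#' `k = max(1, floor((1 - quantile) * n))` of all three centralities
#' (rank-based; ties at the k-th value are included, so a fully symmetric
#' graph flags every node).
#'
#' @param network a non-empty `mic_network` from [build_network()].
#' @param quantile hub quantile (default 0.90: top decile by rank).
#' @return data.frame: `id`, `core_label`, `degree`, `closeness`,
#'   `betweenness`, `is_hub`. On a disconnected graph closeness is
#'   computed within components (logged).
#' @export
hub_taxa <- function(network, quantile = 0.90) {
  stopifnot(inherits(network, "mic_network"))
  if (!nrow(network$nodes)) stop("empty network")
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  dmat <- igraph::distances(g)
  if (any(!is.finite(dmat)))
    message("disconnected network: closeness computed per component")
  clo <- apply(dmat, 1, function(dr) {
    dr <- dr[is.finite(dr)]
    s <- sum(dr)
    if (s > 0) 1 / s else 0
  })
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  k <- max(1, floor((1 - quantile) * length(deg)))
  topk <- function(v) v >= sort(v, decreasing = TRUE)[k]
  is_hub <- topk(deg) & topk(clo) & topk(btw)
  out <- data.frame(id = igraph::V(g)$name,
                    core_label = igraph::V(g)$core_label,
                    degree = unname(deg), closeness = unname(clo),
                    betweenness = unname(btw),
                    is_hub = unname(is_hub),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Label core membership of ASVs for the network stage
#'
#' @param tax,fun taxonomic and functional [core_set()] objects.
#' @return named character vector over the union of members with values
#'   `"taxonomic"`, `"functional"`, or `"both"`.
#' @export
core_labels <- function(tax, fun) {
  ids <- union(tax$member_ids, fun$member_ids)
  lab <- ifelse(ids %in% tax$member_ids & ids %in% fun$member_ids, "both",
                ifelse(ids %in% tax$member_ids, "taxonomic", "functional"))
  stats::setNames(lab, ids)
}
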