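## Expression anti-correlation validation of predicted targets, TF
## co-expression layer, tripartite miRNA-TF-mRNA network assembly, and
## hypergeometric pathway enrichment.

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance
#' @return correlation coefficient in [-1, 1]
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform t = r * sqrt((n-2) / (1-r^2)) against the t
#' distribution with n-2 degrees of freedom. |r| = 1 returns p = 0 by
#' convention.
#'
#' @param r correlation coefficient
#' @param n number of paired samples (>= 3)
#' @return two-sided p-value
#' @export
pearson_p <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Validate predicted targets by expression anti-correlation
#'
#' A predicted miRNA-target pair is validated when the Pearson correlation
#' between the miRNA's normalized abundance and the gene's expression
#' across the shared samples satisfies r <= r_max (strictly negative
#' threshold) and the two-sided p-value satisfies p <= p_max. Pairs whose
#' correlation is undefined (zero variance) are skipped and reported in
#' the `skipped` attribute.
#'
#' @param hits TargetHit data.frame (best hits; see [predict_targets()])
#' @param mirna_abund miRNA x sample abundance matrix (normalized)
#' @param expr gene x sample expression matrix
#' @param r_max correlation threshold (default -0.8)
#' @param p_max p-value threshold
#' @return CorrelationEdge data.frame (mirna_id, gene_id, r, p_value, n,
#'   expectation, validated) restricted to hits present in both matrices;
#'   rows with `validated = TRUE` pass both thresholds
#' @export
anticorrelation_filter <- function(hits, mirna_abund, expr, r_max = -0.8,
                                   p_max = 0.05) {
  common <- intersect(colnames(mirna_abund), colnames(expr))
  if (length(common) < 3) stop("sample mismatch between matrices")
  if (!identical(colnames(mirna_abund), colnames(expr))) {
    mirna_abund <- mirna_abund[, common, drop = FALSE]
    expr <- expr[, common, drop = FALSE]
  }
  hits <- hits[hits$best %||% rep(TRUE, nrow(hits)), , drop = FALSE]
  hits <- hits[hits$mirna_id %in% rownames(mirna_abund) &
                 hits$transcript_id %in% rownames(expr), , drop = FALSE]
  skipped <- character(0)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    x <- mirna_abund[hits$mirna_id[i], ]
    y <- expr[hits$transcript_id[i], ]
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      skipped <<- c(skipped, paste0(hits$mirna_id[i], "~",
                                    hits$transcript_id[i]))
      return(NULL)
    }
    r <- pearson_r(x, y)
    p <- pearson_p(r, length(x))
    data.frame(mirna_id = hits$mirna_id[i],
               gene_id = hits$transcript_id[i], r = r, p_value = p,
               n = length(x), expectation = hits$expectation[i],
               validated = r <= r_max & p <= p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(0), gene_id = character(0),
                      r = numeric(0), p_value = numeric(0), n = integer(0),
                      expectation = numeric(0), validated = logical(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' TF co-expression layer
#'
#' For every annotated TF gene, finds other genes whose expression has
#' |r| >= r_min and p <= p_max with the TF across samples. Self-edges are
#' excluded; the correlation sign is retained on the edge.
#'
#' @param tf_ids character vector of TF gene IDs (must be rows of `expr`)
#' @param expr gene x sample expression matrix
#' @param r_min absolute-correlation threshold
#' @param p_max p-value threshold
#' @return CorrelationEdge data.frame (tf_id, gene_id, r, p_value, n)
#' @export
tf_layer <- function(tf_ids, expr, r_min = 0.8, p_max = 0.05) {
  missing_tf <- setdiff(tf_ids, rownames(expr))
  if (length(missing_tf)) {
    stop("unknown TF id(s): ", paste(missing_tf, collapse = ", "))
  }
  n <- ncol(expr)
  rows <- list()
  for (tf in tf_ids) {
    x <- expr[tf, ]
    if (stats::var(x) == 0) next
    others <- setdiff(rownames(expr), tf)
    vy <- apply(expr[others, , drop = FALSE], 1, stats::var)
    others <- others[vy > 0]
    if (length(others) == 0) next
    r <- as.numeric(stats::cor(x, t(expr[others, , drop = FALSE])))
    p <- vapply(r, pearson_p, numeric(1), n = n)
    keep <- abs(r) >= r_min & p <= p_max
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tf_id = tf, gene_id = others[keep], r = r[keep],
        p_value = p[keep], n = n, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf_id = character(0), gene_id = character(0),
               r = numeric(0), p_value = numeric(0), n = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite miRNA-TF-mRNA network
#'
#' Nodes are typed miRNA / TF / gene; miRNA->TF and miRNA->gene edges
#' require both a target prediction and a passing anti-correlation edge
#' (only validated pairs should be passed in); TF->gene edges come from
#' the co-expression layer.
#'
#' @param validated validated pairs from [anticorrelation_filter()]
#'   (rows with `validated = TRUE` are used)
#' @param tf_edges TF co-expression edges from [tf_layer()]
#' @param tf_ids character vector of TF gene IDs (for node typing)
#' @return a `TripartiteNetwork`: list with `nodes` (id, type), `edges`
#'   (source, target, interaction, r, p_value) and `graph` (igraph object)
#' @export
build_network <- function(validated, tf_edges, tf_ids) {
  v <- validated[validated$validated, , drop = FALSE]
  e1 <- if (nrow(v)) data.frame(
    source = v$mirna_id, target = v$gene_id,
    interaction = ifelse(v$gene_id %in% tf_ids, "mirna-tf", "mirna-gene"),
    r = v$r, p_value = v$p_value, stringsAsFactors = FALSE) else NULL
  e2 <- if (nrow(tf_edges)) data.frame(
    source = tf_edges$tf_id, target = tf_edges$gene_id,
    interaction = "tf-coexpression", r = tf_edges$r,
    p_value = tf_edges$p_value, stringsAsFactors = FALSE) else NULL
  edges <- rbind(e1, e2)
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        interaction = character(0), r = numeric(0),
                        p_value = numeric(0), stringsAsFactors = FALSE)
  }
  ids <- unique(c(edges$source, edges$target))
  type <- ifelse(ids %in% unique(v$mirna_id), "miRNA",
                 ifelse(ids %in% tf_ids, "TF", "gene"))
  nodes <- data.frame(id = ids, type = type, stringsAsFactors = FALSE)
  stopifnot(all(edges$source %in% nodes$id),
            all(edges$target %in% nodes$id))
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else
      data.frame(source = character(0), target = character(0)),
    directed = TRUE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 n_components = if (nrow(nodes))
                   igraph::count_components(g) else 0L,
                 degree = if (nrow(nodes))
                   igraph::degree(g) else integer(0)),
            class = "TripartiteNetwork")
}

#' Export a tripartite network to SIF, GraphML and a node table
#'
#' @param net TripartiteNetwork from [build_network()]
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>.graphml`, `<prefix>_nodes.tsv`
#' @return invisible named vector of written paths
#' @export
export_network <- function(net, prefix) {
  sif <- paste0(prefix, ".sif")
  writeLines(sprintf("%s\t%s\t%s", net$edges$source,
                     net$edges$interaction, net$edges$target), sif)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(net$graph, gml, format = "graphml")
  nodes <- paste0(prefix, "_nodes.tsv")
  write_tsv(net$nodes, nodes)
  invisible(c(sif = sif, graphml = gml, nodes = nodes))
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway with at least one network gene, computes the
#' upper-tail hypergeometric probability P(X >= k) of drawing k pathway
#' members in n network genes from a background of N genes of which K are
#' in the pathway, with Benjamini-Hochberg correction across pathways.
#'
#' @param network_genes character vector (must be a subset of
#'   `background_genes`)
#' @param background_genes character vector of all considered genes
#' @param pathway_map data.frame (gene_id, pathway_id)
#' @return EnrichmentResult data.frame (pathway_id, k, K, n, N, p_value,
#'   q_value), ordered by p
#' @export
enrich_pathways <- function(network_genes, background_genes, pathway_map) {
  if (length(background_genes) == 0) stop("empty background")
  network_genes <- unique(network_genes)
  background_genes <- unique(background_genes)
  if (!all(network_genes %in% background_genes)) {
    stop("network genes must be a subset of the background")
  }
  pathway_map <- pathway_map[pathway_map$gene_id %in% background_genes, ,
                             drop = FALSE]
  N <- length(background_genes)
  n <- length(network_genes)
  rows <- lapply(split(pathway_map$gene_id, pathway_map$pathway_id),
                 function(genes) {
    K <- length(unique(genes))
    k <- length(intersect(network_genes, genes))
    data.frame(k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(pathway_id = names(rows),
                          stringsAsFactors = FALSE), out)
  out <- out[out$k > 0, , drop = FALSE]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
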