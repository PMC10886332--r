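# canonical unordered edge keys
.edge_keys <- function(edges) {
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  paste(a, b, sep = "\r")
}

.canonical_edges <- function(edges) {
  if (nrow(edges) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0)))
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- data.frame(gene_a = a, gene_b = b,
                    r = if ("r" %in% names(edges)) edges$r else NA_real_)
  out <- out[!duplicated(paste(a, b, sep = "\r")) & a != b, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treatment-contrast filters on co-expression edge sets
#'
#' Applies the five presence/absence contrasts between per-treatment edge
#' sets (NP control; PP, CP treatments). Edges are compared as unordered
#' pairs; weights are ignored for identity and the retained weight is the
#' one from the first-named treatment set.
#'
#' * `PP-NP`: edges of PP absent from NP;
#' * `PP-exclusive`: edges only in PP;
#' * `CP-NP`: edges of CP absent from NP;
#' * `CP-exclusive`: edges only in CP;
#' * `PP+CP-NP`: edges in both PP and CP but not NP.
#'
#' @param np,pp,cp edge data frames with `gene_a`, `gene_b` (and
#'   optionally `r`).
#' @return Named list of five edge data frames.
#' @export
contrast_filters <- function(np, pp, cp) {
  np <- .canonical_edges(np); pp <- .canonical_edges(pp)
  cp <- .canonical_edges(cp)
  nodes <- function(e) unique(c(e$gene_a, e$gene_b))
  if (nrow(np) && nrow(pp) && nrow(cp) &&
      (!length(intersect(nodes(np), nodes(pp))) ||
       !length(intersect(nodes(np), nodes(cp)))))
    warning("edge sets share no nodes; contrasts may be vacuous")
  knp <- .edge_keys(np); kpp <- .edge_keys(pp); kcp <- .edge_keys(cp)
  list(
    "PP-NP" = pp[!(kpp %in% knp), , drop = FALSE],
    "PP-exclusive" = pp[!(kpp %in% knp) & !(kpp %in% kcp), , drop = FALSE],
    "CP-NP" = cp[!(kcp %in% knp), , drop = FALSE],
    "CP-exclusive" = cp[!(kcp %in% knp) & !(kcp %in% kpp), , drop = FALSE],
    "PP+CP-NP" = pp[(kpp %in% kcp) & !(kpp %in% knp), , drop = FALSE])
}

#' Per-lncRNA connection counts
#'
#' Degree of each lncRNA within a (filtered) edge set, sorted descending.
#' lncRNAs absent from the node universe are kept with degree 0 and
#' flagged, so regulators without surviving connections remain visible.
#'
#' @param edges edge data frame.
#' @param lnc_ids lncRNA ids to tabulate.
#' @return Data frame `lncrna_id`, `connections`, `in_network`.
#' @export
connection_counts <- function(edges, lnc_ids) {
  edges <- .canonical_edges(edges)
  nodes <- c(edges$gene_a, edges$gene_b)
  deg <- vapply(lnc_ids, function(id) sum(nodes == id), integer(1))
  out <- data.frame(lncrna_id = lnc_ids, connections = deg,
                    in_network = lnc_ids %in% nodes)
  out <- out[order(-out$connections, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network
#'
#' Writes an edge set as SIF (`a co_expr b`), GraphML (with an `r` weight
#' attribute) or TSV. Node and edge ordering is lexicographic, so repeated
#' exports are byte-identical.
#'
#' @param edges edge data frame.
#' @param path output file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  edges <- .canonical_edges(edges)
  if (format == "tsv") {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(if (nrow(edges)) paste(edges$gene_a, "co_expr", edges$gene_b)
               else character(0), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = sort(unique(c(edges$gene_a, edges$gene_b))))
    igraph::E(g)$r <- edges$r
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Export mRNA partner gene lists
#'
#' Unique mRNA partners of the selected lncRNAs within an edge set, one id
#' per line, sorted — the input for external functional-enrichment tools.
#'
#' @param edges edge data frame.
#' @param lnc_ids lncRNA ids whose partners are collected.
#' @param path optional output file; when `NULL` the list is only
#'   returned.
#' @return Character vector of partner ids (invisibly when written).
#' @export
export_gene_lists <- function(edges, lnc_ids, path = NULL) {
  edges <- .canonical_edges(edges)
  sel <- edges$gene_a %in% lnc_ids | edges$gene_b %in% lnc_ids
  partners <- c(edges$gene_a[sel], edges$gene_b[sel])
  partners <- sort(unique(setdiff(partners, lnc_ids)))
  if (!length(partners)) warning("no lncRNA connections in this edge set")
  if (!is.null(path)) {
    writeLines(partners, path)
    return(invisible(partners))
  }
  partners
}
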