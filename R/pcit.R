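#' Gene-gene correlation matrix
#'
#' Pearson correlations between gene expression profiles. Genes with zero
#' variance are dropped with a warning naming them.
#'
#' @param expr genes x samples expression matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
correlation_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  diag(r) <- 1
  (r + t(r)) / 2
}

#' First-order partial correlation
#'
#' \deqn{r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' Denominators below `1e-12` are degenerate; the direct correlation is
#' returned for them (the PCIT guard: no elimination credit).
#'
#' @param r_xy,r_xz,r_yz correlations in \[-1, 1\] (vectorised).
#' @return The partial correlation of x and y given z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  out <- ifelse(den < 1e-12, r_xy, (r_xy - r_xz * r_yz) / sqrt(pmax(den, 1e-300)))
  as.numeric(out)
}

#' Significant co-expression edges (PCIT)
#'
#' Partial-correlation-and-information-theory edge selection: for every
#' gene trio the three first-order partial correlations define a local
#' tolerance (the mean of the partial/direct ratios, zero-correlation
#' terms contributing 0), and an edge is eliminated when a third gene
#' explains it within that tolerance, i.e. when
#' `|r_xy| < |eps * r_xz|` and `|r_xy| < |eps * r_yz|` for some z.
#' Surviving edges keep their direct correlation as weight.
#'
#' @param r symmetric correlation matrix with unit diagonal and gene-id
#'   dimnames.
#' @param condition optional condition label stored on each edge.
#' @param min_abs_r optional absolute-correlation floor applied after
#'   elimination (default 0: none).
#' @return Data frame `gene_a`, `gene_b`, `r` (and `condition` when
#'   given); pairs in canonical lexicographic order, no self-edges.
#' @export
significant_edges <- function(r, condition = NULL, min_abs_r = 0) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8 ||
      max(abs(diag(r) - 1)) > 1e-8)
    stop("r must be a symmetric correlation matrix with unit diagonal")
  if (is.null(rownames(r))) rownames(r) <- colnames(r) <- sprintf("g%d", seq_len(nrow(r)))
  keep <- .pcit_keep_cpp(r)
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  ga <- rownames(r)[idx[, 1]]
  gb <- colnames(r)[idx[, 2]]
  w <- r[idx]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  out <- data.frame(gene_a = ga, gene_b = gb, r = w)
  out <- out[abs(out$r) >= min_abs_r, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  if (!is.null(condition)) out$condition <- condition
  rownames(out) <- NULL
  out
}

#' PCIT network per condition from counts
#'
#' Convenience wrapper: log2(CPM+1) expression for the samples of one
#' treatment, correlation matrix over the requested genes, PCIT edge
#' selection.
#'
#' @param counts genes x samples count matrix.
#' @param meta metadata with `sample_id`, `treatment`.
#' @param genes row ids to include as network nodes.
#' @param condition treatment label whose samples are used (also stored
#'   on the edges).
#' @param min_abs_r see [significant_edges()].
#' @return Edge data frame as from [significant_edges()].
#' @export
pcit_network <- function(counts, meta, genes, condition, min_abs_r = 0) {
  expr <- log_cpm(counts)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  samples <- colnames(expr)[meta$treatment == condition]
  r <- correlation_matrix(expr[genes, samples, drop = FALSE])
  significant_edges(r, condition = condition, min_abs_r = min_abs_r)
}
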