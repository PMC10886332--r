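#' Select GO-annotated target genes
#'
#' Targets for the regulatory-impact-factor analysis: genes annotated to
#' any of the listed Gene Ontology terms and expressed in the data set.
#'
#' @param go_map data frame with columns `gene_id`, `go_id` (direct
#'   annotations).
#' @param go_terms character vector of GO ids (format `GO:nnnnnnn`).
#' @param expressed_ids ids of expressed genes.
#' @return List (`target_selection`) with `go_terms`, `target_gene_ids`
#'   (sorted), `n_expressed`.
#' @export
select_targets <- function(go_map, go_terms, expressed_ids) {
  if (!all(c("gene_id", "go_id") %in% names(go_map)))
    stop("go_map needs columns gene_id and go_id")
  bad <- go_terms[!grepl("^GO:\\d{7}$", go_terms)]
  if (length(bad))
    stop("malformed GO id(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (!length(go_terms)) {
    warning("empty GO term list; no targets selected")
    return(structure(list(go_terms = character(0),
                          target_gene_ids = character(0),
                          n_expressed = length(expressed_ids)),
                     class = "target_selection"))
  }
  hits <- unique(go_map$gene_id[go_map$go_id %in% go_terms])
  structure(list(go_terms = go_terms,
                 target_gene_ids = sort(intersect(hits, expressed_ids)),
                 n_expressed = length(expressed_ids)),
            class = "target_selection")
}

#' Regulator-target correlations within one condition
#'
#' Pearson correlation between each regulator and each target across the
#' samples of one condition, on the log2(CPM+1) scale. Zero-variance
#' series give r = 0 (not NaN); such pairs are flagged in the
#' `"degenerate"` attribute.
#'
#' @param expr genes x samples log-expression matrix.
#' @param regulators,targets row ids.
#' @param samples column ids of the condition (>= 3 required).
#' @return Matrix `regulators x targets` of correlations.
#' @export
condition_correlations <- function(expr, regulators, targets, samples) {
  if (length(samples) < 3L) stop("need at least 3 samples per condition")
  miss <- setdiff(c(regulators, targets), rownames(expr))
  if (length(miss))
    stop("ids absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  rx <- t(expr[regulators, samples, drop = FALSE])
  tx <- t(expr[targets, samples, drop = FALSE])
  sd_r <- apply(rx, 2, stats::sd)
  sd_t <- apply(tx, 2, stats::sd)
  r <- matrix(0, length(regulators), length(targets),
              dimnames = list(regulators, targets))
  ok_r <- sd_r > 0; ok_t <- sd_t > 0
  if (any(ok_r) && any(ok_t))
    r[ok_r, ok_t] <- stats::cor(rx[, ok_r, drop = FALSE],
                                tx[, ok_t, drop = FALSE])
  deg <- which(outer(!ok_r, !ok_t, "|"), arr.ind = TRUE)
  attr(r, "degenerate") <- deg
  r
}

#' Regulatory impact factors
#'
#' Scores each regulator's change of regulatory behaviour between two
#' conditions. With target mean expressions `e1_j`, `e2_j`, average
#' abundance `a_j = (e1_j + e2_j)/2`, differential expression
#' `d_j = e1_j - e2_j`, phenotypic impact factor `PIF_j = a_j * d_j`, and
#' differential wiring `DW_ij = r1_ij - r2_ij`:
#' \deqn{RIF1_i = \frac{1}{n_t}\sum_j PIF_j \, DW_{ij}^2}
#' \deqn{RIF2_i = \frac{1}{n_t}\sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2}
#' Both score vectors are z-standardised across regulators.
#'
#' @param e1,e2 mean target expression per condition (named by target).
#' @param r1,r2 regulator x target correlation matrices per condition.
#' @param condition_pair optional `c(treatment, control)` labels.
#' @return Data frame `regulator_id`, `rif1`, `rif2`, `z1`, `z2`,
#'   `condition_pair`.
#' @export
rif_scores <- function(e1, e2, r1, r2, condition_pair = c("cond1", "cond2")) {
  if (length(e1) == 0L) stop("empty target set")
  stopifnot(length(e1) == length(e2), ncol(r1) == length(e1),
            all(dim(r1) == dim(r2)))
  a <- (e1 + e2) / 2
  d <- e1 - e2
  pif <- a * d
  dw <- r1 - r2
  n_t <- length(e1)
  rif1 <- as.vector(dw^2 %*% pif) / n_t
  rif2 <- as.vector(sweep(r1, 2, e1, "*")^2 %*% rep(1, n_t) -
                      sweep(r2, 2, e2, "*")^2 %*% rep(1, n_t)) / n_t
  z <- function(x) {
    s <- stats::sd(x)
    if (length(x) < 2L || s == 0) rep(NA_real_, length(x))
    else (x - mean(x)) / s
  }
  data.frame(regulator_id = rownames(r1), rif1 = rif1, rif2 = rif2,
             z1 = z(rif1), z2 = z(rif2),
             condition_pair = paste(condition_pair, collapse = " vs "),
             row.names = NULL)
}

#' Select key regulators by RIF z-score
#'
#' @param scores a [rif_scores()] table.
#' @param z_min absolute z threshold (default 1.96, the conventional
#'   2-SD rule).
#' @param use select by `"either"` score (default), `"rif1"` or `"rif2"`.
#' @return Character vector of selected regulator ids.
#' @export
key_regulators <- function(scores, z_min = 1.96,
                           use = c("either", "rif1", "rif2")) {
  use <- match.arg(use)
  sel <- switch(use,
                either = abs(scores$z1) >= z_min | abs(scores$z2) >= z_min,
                rif1 = abs(scores$z1) >= z_min,
                rif2 = abs(scores$z2) >= z_min)
  sel[is.na(sel)] <- FALSE
  scores$regulator_id[sel]
}

#' End-to-end RIF analysis from counts
#'
#' Convenience wrapper: normalises counts to log2(CPM+1), computes
#' per-condition target means and regulator-target correlations for a
#' treatment/control pair, and returns the RIF score table.
#'
#' @param counts genes x samples count matrix containing regulators and
#'   targets.
#' @param meta metadata with `sample_id` and `treatment`.
#' @param regulators,targets row ids.
#' @param pair `c(treatment, control)`.
#' @return A [rif_scores()] table.
#' @export
rif_analysis <- function(counts, meta, regulators, targets, pair) {
  expr <- log_cpm(counts)
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  s1 <- colnames(expr)[meta$treatment == pair[1]]
  s2 <- colnames(expr)[meta$treatment == pair[2]]
  r1 <- condition_correlations(expr, regulators, targets, s1)
  r2 <- condition_correlations(expr, regulators, targets, s2)
  e1 <- rowMeans(expr[targets, s1, drop = FALSE])
  e2 <- rowMeans(expr[targets, s2, drop = FALSE])
  rif_scores(e1, e2, r1, r2, condition_pair = pair)
}
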