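.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative entries in count matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("count matrix needs unique gene-id rownames")
  if (is.null(colnames(counts))) stop("count matrix needs sample-id colnames")
  counts
}

#' TMM normalisation factors
#'
#' Per-sample scaling factors from trimmed-mean-of-M-values
#' normalisation (30% M trim, 5% A trim, zero-count genes excluded
#' pairwise, computed with edgeR; the reference sample is the column
#' whose upper quartile is closest to the mean upper quartile). The
#' returned factor is the *effective* scale of each sample — the TMM
#' composition factor times the library size — rescaled so the factors
#' have geometric mean 1, so identical columns give factors of exactly
#' 1 and doubling a column doubles its factor.
#'
#' @param counts genes x samples non-negative integer matrix with
#'   dimnames.
#' @return Named numeric vector of per-sample factors (geometric mean
#'   1).
#' @export
tmm_factors <- function(counts) {
  eff <- .tmm_effective_sizes(counts)
  f <- eff / exp(mean(log(eff)))
  stats::setNames(f, colnames(counts))
}

# absolute effective library sizes: TMM composition factor x library size
.tmm_effective_sizes <- function(counts) {
  counts <- .check_counts(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y$samples$norm.factors * tot
}

#' Common negative-binomial dispersion
#'
#' Maximum adjusted-profile-likelihood estimate of the common dispersion
#' for a negative-binomial log-linear model with TMM offsets, via edgeR.
#'
#' @param counts genes x samples count matrix.
#' @param design model matrix; must leave at least one residual degree of
#'   freedom.
#' @return The common dispersion (positive scalar).
#' @export
estimate_dispersion <- function(counts, design) {
  counts <- .check_counts(counts)
  if (ncol(counts) - qr(design)$rank < 1L)
    stop("no residual degrees of freedom for dispersion estimation")
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateGLMCommonDisp(y, design)
  y$common.dispersion
}

.build_design <- function(meta, covariates) {
  meta$treatment <- factor(meta$treatment)
  df <- data.frame(treatment = meta$treatment)
  for (cv in covariates) {
    v <- meta[[cv]]
    if (is.null(v)) stop("covariate not in metadata: ", cv)
    df[[cv]] <- if (is.numeric(v)) as.numeric(scale(v)) else factor(v)
  }
  design <- stats::model.matrix(~ 0 + ., data = df)
  colnames(design) <- sub("^treatment", "", colnames(design))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("confounded design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  design
}

#' Negative-binomial differential-expression test
#'
#' Fits a negative-binomial log-linear model per gene (TMM offsets,
#' common dispersion, covariates entered as standardised continuous
#' terms) and tests the treatment contrast with a likelihood-ratio test;
#' p-values are Benjamini-Hochberg adjusted across the genes tested
#' within the contrast.
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata data frame with `sample_id`, `treatment`
#'   and the covariate columns; rows must cover every count column.
#' @param contrast length-2 character vector `c(treatment, control)`; the
#'   reported log2 fold change is treatment minus control.
#' @param covariates covariate column names (default age of dam and age
#'   of animal).
#' @return Data frame `gene_id`, `log2fc`, `mean_log_cpm`, `pvalue`,
#'   `qvalue`, `contrast`.
#' @export
de_test <- function(counts, meta, contrast,
                    covariates = c("age_of_dam", "age_of_animal")) {
  counts <- .check_counts(counts)
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("metadata missing for some samples")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (!all(contrast %in% meta$treatment))
    stop("contrast level(s) absent from metadata: ",
         paste(setdiff(contrast, meta$treatment), collapse = ", "))
  design <- .build_design(meta, covariates)
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y, method = "TMM")
  y <- edgeR::estimateGLMCommonDisp(y, design)
  fit <- edgeR::glmFit(y, design, dispersion = y$common.dispersion)
  cv <- rep(0, ncol(design))
  names(cv) <- colnames(design)
  cv[contrast[1]] <- 1
  cv[contrast[2]] <- -1
  lrt <- edgeR::glmLRT(fit, contrast = cv)
  tab <- lrt$table
  data.frame(gene_id = rownames(tab), log2fc = tab$logFC,
             mean_log_cpm = tab$logCPM, pvalue = tab$PValue,
             qvalue = stats::p.adjust(tab$PValue, method = "BH"),
             contrast = paste(contrast[1], "vs", contrast[2]),
             row.names = NULL)
}

#' Dual-threshold differential-expression calling
#'
#' Tiers results as `"fdr"` when the adjusted p-value (Q value) is below
#' `q_max`, else `"exploratory"` when the raw p-value is below
#' `exploratory_p`, else not called (`NA`).
#'
#' @param results a [de_test()] table.
#' @param q_max FDR threshold (default 0.05).
#' @param exploratory_p raw p-value threshold for the exploratory tier
#'   (default 0.01).
#' @return `results` with an added `tier` column.
#' @export
call_de <- function(results, q_max = 0.05, exploratory_p = 0.01) {
  tier <- rep(NA_character_, nrow(results))
  tier[results$pvalue < exploratory_p] <- "exploratory"
  tier[results$qvalue < q_max] <- "fdr"
  results$tier <- tier
  results
}

#' Subset a count matrix to a gene panel
#'
#' @param counts genes x samples count matrix.
#' @param gene_list character vector of gene ids, or path to a
#'   one-id-per-line text file.
#' @return The subset matrix in panel order; ids absent from the matrix
#'   are reported with a warning (an empty intersection is an error).
#' @export
panel_subset <- function(counts, gene_list) {
  counts <- .check_counts(counts)
  if (length(gene_list) == 1L && file.exists(gene_list))
    gene_list <- readLines(gene_list)
  gene_list <- gene_list[nzchar(gene_list)]
  if (!length(gene_list)) stop("empty gene panel")
  present <- gene_list[gene_list %in% rownames(counts)]
  if (!length(present)) stop("no panel gene found in the count matrix")
  absent <- setdiff(gene_list, present)
  if (length(absent))
    warning(length(absent), " panel gene(s) absent from the count matrix: ",
            paste(utils::head(absent, 5), collapse = ", "))
  counts[present, , drop = FALSE]
}

#' Normalised log2 CPM expression
#'
#' `log2(CPM + 1)` on TMM-effective library sizes; the expression scale
#' used for the RIF and PCIT stages.
#'
#' @param counts genes x samples count matrix.
#' @return Matrix of the same shape.
#' @export
log_cpm <- function(counts) {
  counts <- .check_counts(counts)
  eff <- .tmm_effective_sizes(counts)
  log2(sweep(counts, 2, eff / 1e6, "/") + 1)
}
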