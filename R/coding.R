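#' Sequence features for coding-potential assessment
#'
#' Computes, per transcript sequence, the feature set used by CPC2-style
#' coding-potential classifiers: Fickett TESTCODE score, longest-ORF
#' length and coverage, ORF integrity (complete = has both start and stop)
#' and the isoelectric point of the longest-ORF peptide. Transcripts
#' without any ATG-initiated ORF get length 0, coverage 0, integrity
#' `"partial"` and a neutral pI of 7 (documented placeholder so the
#' downstream logistic model stays defined).
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of transcript sequences.
#' @return Data frame with columns `transcript_id`, `fickett`,
#'   `orf_length_nt`, `orf_coverage`, `orf_integrity`, `pI`.
#' @export
coding_features <- function(sequences) {
  sequences <- .as_seq_vector(sequences)
  rows <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    orfs <- find_orfs(s, include_partial = TRUE)
    if (nrow(orfs) == 0L) {
      len <- 0L; cov <- 0; integ <- "partial"; pi_val <- 7
    } else {
      top <- orfs[1L, ]
      len <- top$length_nt
      cov <- len / nchar(s)
      integ <- if (top$has_stop) "complete" else "partial"
      pep <- .translate_orf(s, top$start, top$end, top$has_stop)
      pi_val <- if (nzchar(pep)) as.numeric(isoelectric_point(pep)) else 7
    }
    data.frame(transcript_id = names(sequences)[i],
               fickett = fickett_score(s), orf_length_nt = len,
               orf_coverage = cov, orf_integrity = integ, pI = pi_val)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.translate_orf <- function(s, start, end, has_stop) {
  if (has_stop) end <- end - 3L  # drop the stop codon
  if (end < start + 2L) return("")
  cds <- substr(s, start, start + ((end - start + 1L) %/% 3L) * 3L - 1L)
  if (grepl("N", cds, fixed = TRUE)) cds <- gsub("N", "A", cds)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  gsub("\\*.*$", "", pep)
}

.as_seq_vector <- function(sequences) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  sequences
}

#' Default coding-potential model weights
#'
#' Loads the packaged logistic-regression weights (fit once on simulator
#' training data and versioned with the package) used by
#' [coding_potential()].
#'
#' @param path optional path to an alternative weights TSV with columns
#'   `term`, `weight`.
#' @return Named numeric vector of coefficients (including `(Intercept)`).
#' @export
coding_model_weights <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "coding_model_weights.tsv",
                        package = "lncnet")
  if (is.null(path) || !nzchar(path) || !file.exists(path))
    stop("coding-potential weights file not found",
         if (!is.null(path) && nzchar(path)) paste0(": ", path) else "")
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(w$weight, w$term)
}

#' Coding-potential classification
#'
#' Labels each transcript `coding` or `noncoding` with a logistic
#' combination of [coding_features()] (Fickett score, log10 ORF length,
#' ORF coverage, ORF integrity, pI), using the packaged default weights.
#' An externally produced CPC2 result table can be supplied instead via
#' `cpc2_table` (a data frame with columns `transcript_id` and `label`),
#' in which case it is consumed verbatim.
#'
#' @param sequences named sequences as in [coding_features()].
#' @param weights named coefficient vector, default
#'   [coding_model_weights()].
#' @param cpc2_table optional external classification table.
#' @return Data frame `transcript_id`, `score` (probability of coding),
#'   `label`.
#' @export
coding_potential <- function(sequences, weights = coding_model_weights(),
                             cpc2_table = NULL) {
  if (!is.null(cpc2_table)) {
    if (!all(c("transcript_id", "label") %in% names(cpc2_table)))
      stop("cpc2_table needs columns transcript_id and label")
    out <- data.frame(transcript_id = cpc2_table$transcript_id,
                      score = ifelse(cpc2_table$label == "coding", 1, 0),
                      label = cpc2_table$label)
    return(out)
  }
  feats <- coding_features(sequences)
  x <- .coding_design(feats)
  terms <- setdiff(names(weights), "(Intercept)")
  miss <- setdiff(terms, colnames(x))
  if (length(miss))
    stop("weights reference unknown features: ", paste(miss, collapse = ", "))
  eta <- weights[["(Intercept)"]] +
    as.vector(x[, terms, drop = FALSE] %*% weights[terms])
  p <- 1 / (1 + exp(-eta))
  data.frame(transcript_id = feats$transcript_id, score = p,
             label = ifelse(p >= 0.5, "coding", "noncoding"))
}

.coding_design <- function(feats) {
  cbind(fickett = feats$fickett,
        log_orf = log10(feats$orf_length_nt + 1),
        orf_coverage = feats$orf_coverage,
        complete = as.numeric(feats$orf_integrity == "complete"),
        pI = feats$pI)
}

# fit the packaged logistic head from labelled training features; used
# once to produce inst/extdata/coding_model_weights.tsv. Ridge-penalised
# IRLS (intercept unpenalised) so the fit stays finite when the planted
# classes are linearly separable.
fit_coding_model <- function(feats, labels, penalty = 0.01, max_iter = 100L) {
  x <- cbind("(Intercept)" = 1, .coding_design(feats))
  y <- as.numeric(labels == "coding")
  p <- ncol(x)
  pen <- diag(c(0, rep(penalty, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- solve(crossprod(x, w * x) + pen, crossprod(x, w * z))
    if (max(abs(new_beta - beta)) < 1e-8) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  stats::setNames(as.vector(beta), colnames(x))
}
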