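# Fickett TESTCODE lookup tables (position and composition probabilities
# and weights per base). Position parameter bins are "value >= threshold",
# thresholds descending from 1.9 to 0; content bins likewise from 0.33.
.fickett_tables <- local({
  pos_prob <- rbind(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  cont_prob <- rbind(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  list(
    pos_prob = pos_prob,
    pos_weight = c(A = 0.26, C = 0.18, G = 0.31, T = 0.33),
    pos_thresholds = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
    cont_prob = cont_prob,
    cont_weight = c(A = 0.11, C = 0.12, G = 0.15, T = 0.14),
    cont_thresholds = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                        0.17, 0.0))
})

#' Fickett TESTCODE lookup tables
#'
#' The packaged position/composition probability tables and weights used
#' by [fickett_score()], exposed so that scores can be recomputed by hand.
#'
#' @return A list with elements `pos_prob`, `pos_weight`,
#'   `pos_thresholds`, `cont_prob`, `cont_weight`, `cont_thresholds`.
#' @export
fickett_tables <- function() .fickett_tables

#' Fickett TESTCODE coding-potential score
#'
#' Computes the classic TESTCODE statistic discriminating protein-coding
#' from non-coding nucleotide sequence. For each base the *position
#' parameter* is the ratio of the largest to the smallest (+1) count of
#' that base over the three codon positions, and the *content parameter*
#' is its overall fraction; each is converted to a probability through the
#' packaged lookup tables and the eight probabilities are combined with
#' the packaged weights. Values lie in roughly \[0.26, 1.82\]; higher
#' means more coding-like. `N` bases are ignored.
#'
#' @param sequence nucleotide string of length >= 2.
#' @return A single numeric score.
#' @export
fickett_score <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) < 2L)
    stop("sequence must be a single string of length >= 2")
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  keep <- s %in% c("A", "C", "G", "T")
  tb <- .fickett_tables
  score <- 0
  bases <- c("A", "C", "G", "T")
  phase <- ((seq_along(s) - 1L) %% 3L) + 1L
  total <- sum(keep)
  for (b in bases) {
    isb <- keep & s == b
    cnt <- vapply(1:3, function(p) sum(isb & phase == p), numeric(1))
    position <- max(cnt) / (min(cnt) + 1)
    content <- if (total > 0) sum(cnt) / total else 0
    pi <- which(position >= tb$pos_thresholds)[1]
    ci <- which(content >= tb$cont_thresholds)[1]
    score <- score + tb$pos_prob[b, pi] * tb$pos_weight[[b]] +
      tb$cont_prob[b, ci] * tb$cont_weight[[b]]
  }
  unname(score)
}
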