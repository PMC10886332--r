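# EMBOSS pKa values: ionisable side chains plus free termini
.pka_tables <- list(
  emboss = list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)))

#' Isoelectric point of a peptide
#'
#' Solves net charge = 0 by bisection on pH in \[0, 14\] using a packaged
#' pKa table (EMBOSS values by default). Positive groups (free N-terminus,
#' Lys, Arg, His) contribute `1/(1+10^(pH-pKa))`; negative groups (free
#' C-terminus, Asp, Glu, Cys, Tyr) contribute `-1/(1+10^(pKa-pH))`.
#'
#' @param peptide amino-acid string over the 20-letter alphabet.
#' @param pka_set name of the packaged pKa table.
#' @param tol bisection tolerance in pH units.
#' @return The pI (numeric), with attribute `pka_set` recording the table
#'   used.
#' @examples
#' isoelectric_point("GGGGG")  # free termini only: (8.6 + 3.6) / 2
#' @export
isoelectric_point <- function(peptide, pka_set = "emboss", tol = 1e-4) {
  if (length(peptide) != 1L || is.na(peptide) || !nzchar(peptide))
    stop("peptide must be a single non-empty string")
  peptide <- toupper(peptide)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptide))
    stop("peptide contains letters outside the 20 amino-acid alphabet")
  pka <- .pka_tables[[pka_set]]
  if (is.null(pka)) stop("unknown pKa set: ", pka_set)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  npos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
            H = sum(aa == "H"))
  nneg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
            C = sum(aa == "C"), Y = sum(aa == "Y"))
  charge <- function(ph) {
    sum(npos / (1 + 10^(ph - pka$positive[names(npos)]))) -
      sum(nneg / (1 + 10^(pka$negative[names(nneg)] - ph)))
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, pka_set = pka_set)
}
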