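#' Find open reading frames
#'
#' Scans a nucleotide sequence for open reading frames. The default policy
#' (`"sense-atg"`) scans the three sense-strand frames for `ATG` to
#' `TAA`/`TAG`/`TGA` spans, the stop codon included in the length; nested
#' ORFs sharing a stop codon report only the longest. `"six-frame"` also
#' scans the reverse complement; `"stop-to-stop"` reports the spans
#' between consecutive stop codons per frame (GetOrf `-find 0` semantics),
#' for parity experiments. Codons containing `N` never match a start or a
#' stop.
#'
#' @param sequence a single nucleotide string over `A,C,G,T,N`
#'   (case-insensitive).
#' @param mode ORF policy, see above.
#' @param include_partial for `"sense-atg"`/`"six-frame"`: also report
#'   trailing `ATG`-to-sequence-end spans that lack a stop codon
#'   (`has_stop = FALSE`).
#' @return Data frame sorted by `length_nt` descending with columns
#'   `start`, `end` (1-based positions on the given strand), `frame`
#'   (0/1/2), `strand`, `length_nt`, `has_start`, `has_stop`. Positions of
#'   reverse-strand ORFs refer to the reverse-complemented sequence.
#' @examples
#' find_orfs("ATGAAATAG")
#' @export
find_orfs <- function(sequence,
                      mode = c("sense-atg", "six-frame", "stop-to-stop"),
                      include_partial = FALSE) {
  mode <- match.arg(mode)
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains non-ACGTN letters")
  empty <- data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), strand = character(0),
                      length_nt = integer(0), has_start = logical(0),
                      has_stop = logical(0))
  strands <- if (mode == "six-frame") c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    s <- if (st == "-") .revcomp(sequence) else sequence
    scan <- if (mode == "stop-to-stop") .scan_stop2stop(s) else
      .scan_atg(s, include_partial)
    if (nrow(scan)) {
      scan$strand <- st
      out[[st]] <- scan
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$length_nt, res$start, res$frame),
             c("start", "end", "frame", "strand", "length_nt",
               "has_start", "has_stop")]
  rownames(res) <- NULL
  res
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# codon starts and types per frame; returns list(frame -> data.frame(pos, codon))
.codons <- function(s) {
  n <- nchar(s)
  lapply(0:2, function(f) {
    pos <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(pos) == 0L || n - f < 3L) return(character(0))
    substring(s, pos, pos + 2L)
  })
}

.STOPS <- c("TAA", "TAG", "TGA")

.scan_atg <- function(s, include_partial) {
  n <- nchar(s)
  rows <- list()
  if (n < 3L) return(.orf_rows(rows))
  for (f in 0:2) {
    pos <- seq.int(1L + f, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (!length(pos)) next
    cod <- substring(s, pos, pos + 2L)
    starts <- which(cod == "ATG")
    stops <- which(cod %in% .STOPS)
    if (!length(starts)) next
    prev_stop <- 0L
    for (k in stops) {
      cand <- starts[starts > prev_stop & starts <= k]
      if (length(cand)) {
        i <- cand[1L]  # earliest start before this stop -> longest ORF
        rows[[length(rows) + 1L]] <- c(start = pos[i], end = pos[k] + 2L,
                                       frame = f, has_stop = 1L)
      }
      prev_stop <- k
    }
    if (include_partial) {
      cand <- starts[starts > prev_stop]
      if (length(cand)) {
        i <- cand[1L]
        rows[[length(rows) + 1L]] <- c(start = pos[i], end = n,
                                       frame = f, has_stop = 0L)
      }
    }
  }
  .orf_rows(rows)
}

.scan_stop2stop <- function(s) {
  n <- nchar(s)
  rows <- list()
  if (n < 3L) return(.orf_rows(rows))
  for (f in 0:2) {
    pos <- seq.int(1L + f, by = 3L, length.out = max(0L, (n - f) %/% 3L))
    if (!length(pos)) next
    cod <- substring(s, pos, pos + 2L)
    stops <- which(cod %in% .STOPS)
    bounds <- c(0L, stops, length(cod) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L
      hi <- bounds[b + 1L] - 1L
      if (hi < lo) next
      rows[[length(rows) + 1L]] <- c(start = pos[lo], end = pos[hi] + 2L,
                                     frame = f,
                                     has_stop = as.integer(b < length(bounds) - 1L ||
                                                             bounds[b + 1L] <= length(cod)))
    }
  }
  .orf_rows(rows)
}

.orf_rows <- function(rows) {
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0),
                      length_nt = integer(0), has_start = logical(0),
                      has_stop = logical(0)))
  m <- do.call(rbind, rows)
  data.frame(start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
             frame = as.integer(m[, "frame"]),
             length_nt = as.integer(m[, "end"] - m[, "start"] + 1L),
             has_start = TRUE, has_stop = m[, "has_stop"] == 1L)
}

#' Length of the longest complete ORF
#'
#' Convenience wrapper used by the identification cascade: the length in
#' nucleotides (stop codon included) of the longest sense-strand
#' ATG-to-stop ORF, or 0 if there is none.
#'
#' @param sequence nucleotide string.
#' @return Integer length in nucleotides.
#' @export
longest_orf <- function(sequence) {
  o <- find_orfs(sequence)
  if (nrow(o) == 0L) 0L else o$length_nt[1L]
}
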