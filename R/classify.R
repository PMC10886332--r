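#' Class-code classification of assembled transcripts
#'
#' Assigns a Cufflinks/Cuffcompare-style class code to each assembled
#' transcript relative to a reference annotation. Codes, in precedence
#' order:
#'
#' * `=` identical (non-empty) intron chain to a reference transcript on
#'   the same strand;
#' * `c` contained within a reference transcript with a compatible intron
#'   sub-chain (mono-exonic: exon inside a single reference exon);
#' * `j` shares at least one splice junction with a same-strand reference
#'   transcript but the chains differ (a putative novel isoform);
#' * `e` single-exon transcript straddling a reference exon/intron
#'   boundary (possible pre-mRNA fragment);
#' * `o` generic same-strand exonic overlap without shared junctions;
#' * `i` all exons fall within a single reference intron;
#' * `p` possible polymerase run-on: no overlap, but within
#'   `runon_distance` downstream of a reference transcript's 3' end;
#' * `x` exonic overlap with the reference on the opposite strand;
#' * `u` intergenic — no overlap with any reference transcript span.
#'
#' Overlap means at least 1 bp of exonic intersection. Unstranded (`.`)
#' features match either strand for the same-strand codes unless
#' `strict_strand = TRUE`; unstranded transcripts can therefore receive
#' `i`/`u` (and same-strand codes) but never `x`, which requires two known,
#' opposite strands.
#'
#' @param asm,ref `transcript_models` frames for the assembled transcripts
#'   and the reference annotation.
#' @param strict_strand if `TRUE`, unstranded features match nothing.
#' @param runon_distance window (bp) downstream of a reference 3' end
#'   within which a non-overlapping transcript is called `p` (default
#'   2000, the Cufflinks convention).
#' @return Data frame with one row per assembled transcript:
#'   `transcript_id`, `class_code`, `ref_transcript_id` (`NA` for `u`),
#'   `strand_match`.
#' @export
classify_transcripts <- function(asm, ref, strict_strand = FALSE,
                                 runon_distance = 2000L) {
  asm_tx <- .tx_records(asm)
  ref_tx <- .tx_records(ref)
  ref_chroms <- unique(vapply(ref_tx, `[[`, character(1), "chrom"))
  bad <- setdiff(vapply(asm_tx, `[[`, character(1), "chrom"), ref_chroms)
  if (length(bad))
    stop("assembled transcripts on chromosome(s) unknown to the reference: ",
         paste(bad, collapse = ", "))
  ref_spans <- GenomicRanges::GRanges(
    seqnames = vapply(ref_tx, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      vapply(ref_tx, function(t) t$span[1], numeric(1)),
      vapply(ref_tx, function(t) t$span[2], numeric(1))))
  asm_spans <- GenomicRanges::GRanges(
    seqnames = vapply(asm_tx, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      vapply(asm_tx, function(t) t$span[1], numeric(1)),
      vapply(asm_tx, function(t) t$span[2], numeric(1))))
  hits <- GenomicRanges::findOverlaps(asm_spans, ref_spans,
                                      maxgap = runon_distance)
  cand <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  out <- lapply(seq_along(asm_tx), function(qi) {
    t <- asm_tx[[qi]]
    refs <- ref_tx[cand[[as.character(qi)]]]
    ans <- .classify_one(t, refs, strict_strand, runon_distance)
    data.frame(transcript_id = t$id, class_code = ans$code,
               ref_transcript_id = ans$ref_id, strand_match = ans$strand_match)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# strand compatibility for the same-strand codes
.strand_ok <- function(a, r, strict) {
  if (strict) return(a != "." && a == r)
  a == "." || r == "." || a == r
}

.classify_one <- function(t, refs, strict, runon) {
  sm <- function(r) !is.na(t$strand) && t$strand != "." && r$strand != "." &&
    t$strand == r$strand
  res <- function(code, r = NULL)
    list(code = code,
         ref_id = if (is.null(r)) NA_character_ else r$id,
         strand_match = if (is.null(r) || t$strand == "." || r$strand == ".")
           NA else t$strand == r$strand)
  if (length(refs) == 0L) return(res("u"))

  exonic <- vapply(refs, function(r) .exonic_overlap(t$exons, r$exons),
                   logical(1))
  span_ov <- vapply(refs, function(r)
    t$span[1] <= r$span[2] && t$span[2] >= r$span[1], logical(1))
  same <- vapply(refs, function(r) .strand_ok(t$strand, r$strand, strict),
                 logical(1))
  opp <- vapply(refs, function(r) t$strand != "." && r$strand != "." &&
                  t$strand != r$strand, logical(1))

  # "=": identical non-empty intron chain, same strand
  for (k in which(same)) {
    r <- refs[[k]]
    if (nrow(t$introns) > 0L && nrow(t$introns) == nrow(r$introns) &&
        all(t$introns == r$introns))
      return(res("=", r))
  }
  # "c": compatible containment
  for (k in which(same & exonic)) {
    r <- refs[[k]]
    if (.contained_compatible(t, r)) return(res("c", r))
  }
  # "j": >= 1 shared junction, chains differ
  if (nrow(t$introns) > 0L) {
    for (k in which(same)) {
      r <- refs[[k]]
      if (nrow(r$introns) > 0L && .shared_junctions(t$introns, r$introns) > 0L)
        return(res("j", r))
    }
  }
  # "e": single exon over an exon/intron boundary
  if (nrow(t$exons) == 1L) {
    for (k in which(same & exonic)) {
      r <- refs[[k]]
      if (nrow(r$introns) > 0L && .exonic_overlap(t$exons, r$introns))
        return(res("e", r))
    }
  }
  # "o": generic same-strand exonic overlap
  k <- which(same & exonic)
  if (length(k)) return(res("o", refs[[k[1]]]))
  # "i": wholly within a single reference intron (any strand; an
  # opposite-strand intronic transcript has no exonic overlap so "x"
  # cannot claim it, and Cuffcompare codes it "i")
  for (k in seq_along(refs)) {
    r <- refs[[k]]
    if (nrow(r$introns) > 0L &&
        any(t$span[1] >= r$introns[, 1] & t$span[2] <= r$introns[, 2]))
      return(res("i", r))
  }
  # "p": run-on within `runon` bp downstream of a 3' end, no overlap
  if (!any(span_ov)) {
    for (k in seq_along(refs)) {
      r <- refs[[k]]
      if (!.strand_ok(t$strand, r$strand, strict)) next
      d <- if (r$strand == "-") r$span[1] - t$span[2] else t$span[1] - r$span[2]
      if (!is.na(d) && d >= 1 && d <= runon) return(res("p", r))
    }
  }
  # "x": opposite-strand exonic overlap
  k <- which(opp & exonic)
  if (length(k)) return(res("x", refs[[k[1]]]))
  if (!any(span_ov)) return(res("u"))
  # residual overlap (e.g. opposite-strand, spanning exons without exonic
  # intersection): generic overlap
  k <- which(span_ov)
  res("o", refs[[k[1]]])
}

.exonic_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a)))
    if (any(a[i, 1] <= b[, 2] & a[i, 2] >= b[, 1])) return(TRUE)
  FALSE
}

.shared_junctions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  sum(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2]))
}

# containment with a compatible intron sub-chain: every asm exon inside a
# reference exon, and the asm introns a consecutive run of the reference's
.contained_compatible <- function(t, r) {
  in_ref_exon <- function(iv)
    any(iv[1] >= r$exons[, 1] & iv[2] <= r$exons[, 2])
  if (!all(apply(t$exons, 1, in_ref_exon))) return(FALSE)
  nt <- nrow(t$introns)
  if (nt == 0L) return(TRUE)
  nr <- nrow(r$introns)
  if (nt > nr) return(FALSE)
  key_t <- paste(t$introns[, 1], t$introns[, 2])
  key_r <- paste(r$introns[, 1], r$introns[, 2])
  for (k in seq_len(nr - nt + 1L))
    if (all(key_t == key_r[k:(k + nt - 1L)])) return(TRUE)
  FALSE
}

#' Select lncRNA candidates by class code
#'
#' Keeps exactly the transcripts whose class code is in `allowed_codes`
#' (default the intronic, novel-isoform, generic-overlap, intergenic and
#' antisense codes used for lncRNA discovery).
#'
#' @param assignments output of [classify_transcripts()].
#' @param allowed_codes character vector of codes to keep.
#' @return Character vector of candidate transcript ids.
#' @export
select_candidates <- function(assignments,
                              allowed_codes = c("i", "j", "o", "u", "x")) {
  if (nrow(assignments) == 0L) {
    warning("empty class-code assignment set")
    return(character(0))
  }
  assignments$transcript_id[assignments$class_code %in% allowed_codes]
}

#' Write class-code assignments as a tracking-style TSV
#'
#' @param assignments output of [classify_transcripts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(assignments, path) {
  utils::write.table(
    assignments[, c("transcript_id", "class_code", "ref_transcript_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
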