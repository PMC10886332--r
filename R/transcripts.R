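#' Transcript models
#'
#' A `transcript_models` object is a plain data frame of exons, one row per
#' exon, with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#' `start`, `end`. Coordinates are 1-based closed intervals, the native GTF
#' (and IRanges) convention, and are used unchanged throughout the package.
#' Exons of a transcript must be sorted, non-overlapping and on one
#' chromosome and strand.
#'
#' @param exons data frame with the columns above.
#' @return The validated data frame, sorted by transcript and start, with
#'   class `transcript_models`.
#' @examples
#' tm <- transcript_models(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   start = c(1, 201), end = c(100, 300)))
#' intron_chain(tm[, c("start", "end")])
#' @export
transcript_models <- function(exons) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stop("missing exon columns: ", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[, need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("no exons supplied")
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (!all(exons$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(unique(exons$chrom[idx])) != 1L)
      stop("transcript ", exons$transcript_id[idx[1]], " spans chromosomes")
    if (length(unique(exons$strand[idx])) != 1L)
      stop("transcript ", exons$transcript_id[idx[1]], " mixes strands")
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] <= e[-length(e)]))
        stop("overlapping exons in transcript ", exons$transcript_id[idx[1]])
    }
  }
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

#' Intron chain of one transcript
#'
#' Introns are the gaps between consecutive exons (1-based closed);
#' mono-exonic transcripts have an empty chain.
#'
#' @param exons two-column matrix or data frame of sorted exon
#'   `start`/`end` intervals of a single transcript.
#' @return Integer matrix with columns `start`, `end`, one row per intron
#'   (zero rows for mono-exonic transcripts).
#' @export
intron_chain <- function(exons) {
  exons <- as.matrix(exons[, 1:2, drop = FALSE])
  storage.mode(exons) <- "integer"
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("exons must be sorted and non-overlapping")
  n <- nrow(exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  cbind(start = exons[-n, 2L] + 1L, end = exons[-1L, 1L] - 1L)
}

# split a transcript_models frame into a per-transcript list of records
# (id, gene_id, chrom, strand, exons matrix, introns matrix, span)
.tx_records <- function(models) {
  idx <- split(seq_len(nrow(models)), models$transcript_id)
  lapply(idx, function(i) {
    ex <- cbind(start = models$start[i], end = models$end[i])
    list(id = models$transcript_id[i[1]],
         gene_id = models$gene_id[i[1]],
         chrom = models$chrom[i[1]],
         strand = models$strand[i[1]],
         exons = ex,
         introns = intron_chain(ex),
         span = c(ex[1, 1], ex[nrow(ex), 2]))
  })
}

#' Read transcript models from a GTF file
#'
#' Imports `exon` features and returns them as a [transcript_models()]
#' frame. Unknown strands are recorded as `"."`.
#'
#' @param path path to a GTF file.
#' @return A `transcript_models` data frame.
#' @export
read_transcript_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("failed to parse GTF '", path, "': ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  transcript_models(data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)))
}

#' Write transcript models to a GTF file
#'
#' @param models a `transcript_models` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(models, path) {
  strand <- models$strand
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = strand)
  gr$type <- "exon"
  gr$source <- "lncnet"
  gr$gene_id <- models$gene_id
  gr$transcript_id <- models$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# spliced (mature transcript) length per transcript, named vector
.tx_lengths <- function(models) {
  w <- models$end - models$start + 1L
  vapply(split(w, models$transcript_id), sum, integer(1))
}

# exon count per transcript, named vector
.tx_exon_counts <- function(models) {
  vapply(split(seq_len(nrow(models)), models$transcript_id), length, integer(1))
}
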