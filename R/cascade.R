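#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Columns follow the standard 12-column format: `qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`. A row
#' with the wrong number of fields raises an error naming the line.
#'
#' @param path path to the TSV.
#' @return Data frame of hits (zero rows for an empty file).
#' @export
read_blast_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(path)) stop("BLAST table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    for (k in c(3:10, 11, 12)) out[[k]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed BLAST tabular row at line ", which(nf != 12L)[1],
         " of ", path, " (expected 12 fields, got ", nf[nf != 12L][1], ")")
  m <- do.call(rbind, parts)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]))
  if (anyNA(out$evalue) || anyNA(out$pident))
    stop("non-numeric evalue/pident in BLAST table ", path)
  out
}

#' Protein-homology exclusion filter
#'
#' Removes every id with at least one hit at `evalue <= evalue_max`
#' (boundary hits are removed). Ids without hits survive.
#'
#' @param ids candidate transcript ids.
#' @param hits BLAST hit table as from [read_blast_table()] (may have
#'   zero rows).
#' @param evalue_max E-value threshold (default 1e-6).
#' @return Character vector of surviving ids.
#' @export
apply_homology_filter <- function(ids, hits, evalue_max = 1e-6) {
  if (is.null(hits) || nrow(hits) == 0L) return(ids)
  hit_ids <- unique(hits$qseqid[hits$evalue <= evalue_max])
  setdiff(ids, hit_ids)
}

#' Cascade configuration
#'
#' Thresholds of the sequential lncRNA identification cascade. The length
#' rule is strictly greater than `length_min`; the ORF rule strictly less
#' than `orf_max` (so boundary transcripts of exactly 200 nt or a 300-nt
#' ORF are excluded); both follow the published cascade and are
#' configurable here.
#'
#' @param allowed_codes class codes admitted to the cascade.
#' @param length_min minimum transcript length, exclusive (nt).
#' @param orf_max maximum longest-ORF length, exclusive (nt, stop codon
#'   included).
#' @param evalue_max protein-homology exclusion threshold.
#' @param min_exons minimum exon count (default 2: mono-exonic transcripts
#'   are dropped, the common lncRNA convention).
#' @return A list of settings.
#' @export
cascade_config <- function(allowed_codes = c("i", "j", "o", "u", "x"),
                           length_min = 200L, orf_max = 300L,
                           evalue_max = 1e-6, min_exons = 2L) {
  stopifnot(length_min > 0, orf_max > 0, evalue_max > 0, min_exons >= 1)
  list(allowed_codes = allowed_codes, length_min = as.integer(length_min),
       orf_max = as.integer(orf_max), evalue_max = evalue_max,
       min_exons = as.integer(min_exons))
}

#' Run the sequential lncRNA identification cascade
#'
#' Applies, in order: (1) class-code selection; (2) transcript length >
#' `length_min`; (3) longest complete ORF < `orf_max`; (4) protein
#' homology exclusion; (5) coding-potential exclusion; (6) exon filter
#' (at least `min_exons` exons). Each stage emits a filter-report row with
#' `n_in`, `n_excluded` and `n_surviving` such that
#' `n_in - n_excluded = n_surviving` and stages chain.
#'
#' @param models `transcript_models` of the assembled transcripts (for
#'   exon counts).
#' @param assignments class-code table from [classify_transcripts()].
#' @param sequences named transcript sequences (character vector or
#'   `DNAStringSet`); every candidate id must be present.
#' @param uniprot_hits optional BLASTx hit table for stage 4.
#' @param cpc2_table optional external coding-potential table passed to
#'   [coding_potential()].
#' @param config a [cascade_config()].
#' @return List with `lncrna_ids` (final set), `report` (data frame
#'   `stage`, `n_in`, `n_excluded`, `n_surviving`, `pct_of_initial`) and
#'   `surviving` (list of per-stage id vectors).
#' @export
run_cascade <- function(models, assignments, sequences, uniprot_hits = NULL,
                        cpc2_table = NULL, config = cascade_config()) {
  sequences <- .as_seq_vector(sequences)
  report <- list(); surviving <- list()
  note <- function(stage, ids_in, ids_out) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_in = length(ids_in),
      n_excluded = length(ids_in) - length(ids_out),
      n_surviving = length(ids_out))
    surviving[[stage]] <<- ids_out
    ids_out
  }

  ids0 <- assignments$transcript_id
  ids <- note("class_code", ids0, select_candidates(assignments,
                                                    config$allowed_codes))
  miss <- setdiff(ids, names(sequences))
  if (length(miss))
    stop("sequence missing for candidate transcript(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  lens <- nchar(sequences[ids])
  ids <- note("length", ids, ids[lens > config$length_min])
  orf_len <- vapply(sequences[ids], longest_orf, integer(1))
  ids <- note("orf", ids, ids[orf_len < config$orf_max])
  ids <- note("homology", ids,
              apply_homology_filter(ids, uniprot_hits, config$evalue_max))
  if (length(ids)) {
    cp <- coding_potential(sequences[ids], cpc2_table = cpc2_table)
    noncoding <- cp$transcript_id[cp$label == "noncoding"]
    ids <- note("coding_potential", ids, intersect(ids, noncoding))
  } else {
    ids <- note("coding_potential", ids, ids)
  }
  nex <- .tx_exon_counts(models)
  ids <- note("exon", ids, ids[nex[ids] >= config$min_exons])

  report <- do.call(rbind, report)
  report$pct_of_initial <- round(100 * report$n_surviving /
                                   max(1L, length(ids0)), 2)
  list(lncrna_ids = ids, report = report, surviving = surviving)
}

#' Characterise lncRNAs against a non-coding database
#'
#' For each lncRNA, reports the best nucleotide-database hit passing both
#' the identity and E-value thresholds (best bitscore, ties broken by
#' lower E-value then lexicographic subject id), or `"novel"` when no hit
#' passes.
#'
#' @param lnc_ids lncRNA transcript ids.
#' @param db_hits BLAST hit table against a NONCODE-style database.
#' @param identity_min minimum percent identity (default 80).
#' @param evalue_max maximum E-value (default 1e-6).
#' @return Data frame `transcript_id`, `identification`, `pct_identity`,
#'   `evalue`, `bitscore` (NA features for novel transcripts).
#' @export
characterize_homology <- function(lnc_ids, db_hits, identity_min = 80,
                                  evalue_max = 1e-6) {
  pass <- db_hits[db_hits$pident >= identity_min &
                    db_hits$evalue <= evalue_max, , drop = FALSE]
  rows <- lapply(lnc_ids, function(id) {
    h <- pass[pass$qseqid == id, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(transcript_id = id, identification = "novel",
                        pct_identity = NA_real_, evalue = NA_real_,
                        bitscore = NA_real_))
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    data.frame(transcript_id = id, identification = h$sseqid[1],
               pct_identity = h$pident[1], evalue = h$evalue[1],
               bitscore = h$bitscore[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
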