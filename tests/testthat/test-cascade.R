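# small hand-built fixture: four transcripts exercising each filter stage
cascade_fixture <- function() {
  mk <- function(id, n_ex, len) {
    # n_ex exons of equal length on chr1, far from anything
    w <- len %/% n_ex
    starts <- 100000 + (seq_len(n_ex) - 1) * (w + 500)
    data.frame(transcript_id = id, gene_id = paste0("X", id), chrom = "chr1",
               strand = "+", start = starts,
               end = starts + w - 1 + c(rep(0, n_ex - 1), len %% n_ex))
  }
  models <- transcript_models(rbind(
    mk("short", 2, 150), mk("coding", 2, 900), mk("homol", 2, 600),
    mk("mono", 1, 400), mk("keep", 2, 600)))
  set.seed(99)
  seqs <- c(
    short = lncnet:::.rand_noncoding(150, 90),
    coding = paste0(lncnet:::.strip_atg(lncnet:::.rand_noncoding(120, 90)),
                    "ATG", strrep("GCTACC", 65), "TAA",
                    lncnet:::.rand_noncoding(384, 90)),
    homol = lncnet:::.rand_noncoding(600, 90),
    mono = lncnet:::.rand_noncoding(400, 90),
    keep = lncnet:::.rand_noncoding(600, 90))
  hits <- data.frame(qseqid = "homol", sseqid = "UP_1", pident = 60,
                     length = 100L, mismatch = 1L, gapopen = 0L, qstart = 1L,
                     qend = 100L, sstart = 1L, send = 100L, evalue = 1e-30,
                     bitscore = 200)
  assignments <- data.frame(
    transcript_id = c("short", "coding", "homol", "mono", "keep"),
    class_code = "u", ref_transcript_id = NA, strand_match = NA)
  list(models = models, seqs = seqs, hits = hits, assignments = assignments)
}

test_that("each cascade stage excludes its planted offender", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$models, fx$assignments, fx$seqs,
                     uniprot_hits = fx$hits)
  expect_equal(res$lncrna_ids, "keep")
  rep <- res$report
  expect_equal(rep$stage, c("class_code", "length", "orf", "homology",
                            "coding_potential", "exon"))
  # one transcript lost at each of: length (150), orf (396-nt ORF),
  # homology (1e-30 hit), exon (mono-exonic)
  expect_equal(rep$n_excluded, c(0L, 1L, 1L, 1L, 0L, 1L))
})

test_that("filter-report bookkeeping always balances", {
  fx <- cascade_fixture()
  res <- run_cascade(fx$models, fx$assignments, fx$seqs,
                     uniprot_hits = fx$hits)
  rep <- res$report
  expect_equal(rep$n_in - rep$n_excluded, rep$n_surviving)
  expect_equal(rep$n_in[-1], rep$n_surviving[-nrow(rep)])
  expect_equal(sum(rep$n_excluded) + length(res$lncrna_ids), rep$n_in[1])
})

test_that("length and ORF thresholds are strict inequalities", {
  set.seed(1)
  seqs <- c(at200 = lncnet:::.rand_noncoding(200, 90),
            at201 = lncnet:::.rand_noncoding(201, 90))
  asg <- data.frame(transcript_id = c("at200", "at201"), class_code = "u",
                    ref_transcript_id = NA, strand_match = NA)
  models <- transcript_models(rbind(
    data.frame(transcript_id = "at200", gene_id = "a", chrom = "chr1",
               strand = "+", start = c(1, 200), end = c(100, 299)),
    data.frame(transcript_id = "at201", gene_id = "b", chrom = "chr1",
               strand = "+", start = c(1000, 1200), end = c(1100, 1299))))
  res <- run_cascade(models, asg, seqs)
  expect_equal(res$surviving$length, "at201")  # > 200, not >= 200
  # exactly-300-nt ORF is excluded (< 300 rule)
  s300 <- paste0("ATG", strrep("GCTACC", 49), "TAA")
  expect_equal(nchar(s300), 300L)
  seqs2 <- c(orf300 = paste0(s300, lncnet:::.rand_noncoding(100, 90)))
  asg2 <- data.frame(transcript_id = "orf300", class_code = "u",
                     ref_transcript_id = NA, strand_match = NA)
  m2 <- transcript_models(
    data.frame(transcript_id = "orf300", gene_id = "c", chrom = "chr1",
               strand = "+", start = c(1, 300), end = c(200, 499)))
  res2 <- run_cascade(m2, asg2, seqs2)
  expect_equal(res2$report$n_excluded[res2$report$stage == "orf"], 1L)
})

test_that("homology exclusion removes boundary hits and spares no-hit ids", {
  hits <- data.frame(qseqid = c("a", "b"), sseqid = "s", pident = 50,
                     length = 10L, mismatch = 0L, gapopen = 0L, qstart = 1L,
                     qend = 10L, sstart = 1L, send = 10L,
                     evalue = c(1e-30, 1e-6), bitscore = 100)
  expect_equal(apply_homology_filter(c("a", "b", "c"), hits, 1e-6), "c")
  expect_equal(apply_homology_filter(c("a", "b"), hits[0, ], 1e-6),
               c("a", "b"))
})

test_that("filters are conjunctive: stage order cannot change the final set", {
  cfg <- sim_config(n_assembled_transcripts = 60, seed = 31)
  ref <- sim_reference(cfg)
  tx <- sim_transcripts(ref, cfg)
  sq <- sim_sequences(tx, cfg)
  asg <- classify_transcripts(tx$models, ref$models)
  res <- run_cascade(tx$models, asg, sq$sequences)
  # recompute each filter independently and intersect in a different order
  seqs <- as.character(sq$sequences)
  ids <- asg$transcript_id
  pass_code <- select_candidates(asg)
  pass_len <- ids[nchar(seqs[ids]) > 200]
  pass_orf <- ids[vapply(seqs[ids], longest_orf, integer(1)) < 300]
  cp <- coding_potential(seqs)
  pass_cp <- cp$transcript_id[cp$label == "noncoding"]
  pass_ex <- names(which(table(tx$models$transcript_id) >= 2))
  want <- Reduce(intersect, list(pass_ex, pass_cp, pass_orf, pass_len,
                                 pass_code))
  expect_setequal(res$lncrna_ids, want)
})

test_that("malformed BLAST rows raise an error naming the line", {
  path <- withr::local_tempfile()
  writeLines(c("q\ts\t90\t100\t1\t0\t1\t100\t1\t100\t1e-20\t200",
               "bad\trow"), path)
  expect_error(read_blast_table(path), "line 2")
  writeLines(character(0), path)
  expect_equal(nrow(read_blast_table(path)), 0L)
})

test_that("database characterisation picks the best passing hit or novel", {
  hits <- data.frame(
    qseqid = c("l1", "l1", "l2", "l3"),
    sseqid = c("N2", "N1", "N3", "N4"), pident = c(85, 90, 70, 85),
    length = 100L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, evalue = c(1e-20, 1e-25, 1e-30, 1e-3),
    bitscore = c(200, 150, 300, 400))
  out <- characterize_homology(c("l1", "l2", "l3"), hits)
  # l1: bitscore 200 hit wins despite the other hit's lower evalue
  expect_equal(out$identification[out$transcript_id == "l1"], "N2")
  # l2 fails identity, l3 fails evalue
  expect_equal(out$identification[out$transcript_id == "l2"], "novel")
  expect_equal(out$identification[out$transcript_id == "l3"], "novel")
})
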