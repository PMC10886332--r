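small_cfg <- function(...) {
  sim_config(n_assembled_transcripts = 60, n_genes = 150,
             n_regulators = 4L, n_planted_regulators = 2L, n_targets = 10L,
             ...)
}

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_reference_genes = 0), "sizing")
  mix <- c("=" = 0.5, c = 0.5, j = 0, e = 0, i = 0, o = 0, p = 0, u = 0.1,
           x = 0)
  expect_error(sim_config(class_code_mix = mix), "sum to 1")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(wiring_delta = 3), "wiring_delta")
  expect_error(sim_config(coding_orf_length = 500), "multiple of 3")
  expect_error(sim_config(n_planted_regulators = 5, n_regulators = 2),
               "planted")
})

test_that("reference generation is deterministic, seed-sensitive and sized", {
  cfg <- sim_config(n_reference_genes = 10, seed = 1)
  a <- sim_reference(cfg)
  b <- sim_reference(cfg)
  expect_identical(a$models, b$models)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_true(all(table(a$models$gene_id) >= 2))
  other <- sim_reference(sim_config(n_reference_genes = 10, seed = 2))
  expect_false(identical(a$models$start, other$models$start))
  expect_error(sim_reference(sim_config(n_reference_genes = 200)),
               "sizing error")
})

test_that("reference genes are separated and covered by the genome", {
  cfg <- sim_config(seed = 2)
  ref <- sim_reference(cfg)
  expect_true(all(ref$models$end <= cfg$chrom_length))
  for (ch in unique(ref$models$chrom)) {
    m <- ref$models[ref$models$chrom == ch, ]
    spans <- t(vapply(split(seq_len(nrow(m)), m$gene_id), function(i)
      c(min(m$start[i]), max(m$end[i])), numeric(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] - spans[-nrow(spans), 2] >= 1000))
  }
})

test_that("forced class-code mixes produce the forced geometry", {
  all_u <- c("=" = 0, c = 0, j = 0, e = 0, i = 0, o = 0, p = 0, u = 1,
             x = 0)
  cfg <- sim_config(n_assembled_transcripts = 20, class_code_mix = all_u,
                    seed = 4)
  ref <- sim_reference(cfg)
  tx <- sim_transcripts(ref, cfg)
  expect_true(all(tx$truth$class_codes == "u"))
  # every u transcript sits >= 1 kb from every reference exon
  ref_gr <- GenomicRanges::GRanges(ref$models$chrom,
                                   IRanges::IRanges(ref$models$start,
                                                    ref$models$end))
  u_gr <- GenomicRanges::GRanges(tx$models$chrom,
                                 IRanges::IRanges(tx$models$start,
                                                  tx$models$end))
  expect_equal(length(GenomicRanges::findOverlaps(u_gr, ref_gr,
                                                  maxgap = 1000L)), 0L)

  all_eq <- c("=" = 1, c = 0, j = 0, e = 0, i = 0, o = 0, p = 0, u = 0,
              x = 0)
  cfg2 <- sim_config(n_assembled_transcripts = 10, class_code_mix = all_eq,
                     seed = 4)
  tx2 <- sim_transcripts(sim_reference(cfg2), cfg2)
  expect_true(all(tx2$truth$class_codes == "="))
  ref_chains <- lapply(lncnet:::.tx_records(sim_reference(cfg2)$models),
                       function(t) paste(t$introns, collapse = ","))
  for (t in lncnet:::.tx_records(tx2$models))
    expect_true(paste(t$introns, collapse = ",") %in% unlist(ref_chains))
})

test_that("planted ORF structure is exactly realised in the sequences", {
  cfg <- small_cfg(seed = 6)
  tx <- sim_transcripts(sim_reference(cfg), cfg)
  sq <- sim_sequences(tx, cfg)
  lab <- sq$truth$coding_labels
  lo <- vapply(as.character(sq$sequences), longest_orf, integer(1))
  expect_true(all(lo[names(lab)[lab == "coding"]] == 600L))
  expect_true(all(lo[names(lab)[lab == "noncoding"]] <= 90L))
  expect_equal(sq$truth$planted_orf_lengths[lab == "coding"],
               setNames(rep(600L, sum(lab == "coding")),
                        names(lab)[lab == "coding"]))
  # sequence lengths match the spliced exon structure
  expect_equal(Biostrings::width(sq$sequences),
               unname(lncnet:::.tx_lengths(tx$models)[names(sq$sequences)]))
  cfg0 <- small_cfg(seed = 6, coding_fraction = 0)
  sq0 <- sim_sequences(tx, cfg0)
  expect_true(all(sq0$truth$coding_labels == "noncoding"))
})

test_that("count simulation honours the design and its ground truth", {
  cfg <- small_cfg(seed = 8)
  cm <- sim_counts(cfg)
  expect_true(all(cm$counts >= 0))
  expect_equal(ncol(cm$counts), 15L)
  expect_equal(sort(unique(cm$meta$treatment)), c("CP", "NP", "PP"))
  expect_true(all(cm$meta$sample_id %in% colnames(cm$counts)))
  wiring <- cm$truth$regulator_wiring
  expect_true(all(wiring$w_wired >= -1 & wiring$w_wired <= 1))
  expect_true(all(wiring$w_control >= -1 & wiring$w_control <= 1))
  de <- cm$truth$de_genes[["PP vs NP"]]
  expect_true(all(names(de) %in% rownames(cm$counts)))
  expect_true(all(abs(de) == cfg$de_log2fc))
  expect_error(sim_counts(small_cfg(n_samples_per_group = 1)),
               "design error")
})

test_that("planted fold changes are recovered in the observed counts", {
  cfg <- sim_config(n_genes = 1000, de_fraction = 0.1, de_log2fc = 2,
                    lib_size_variation = 0, seed = 13)
  cm <- sim_counts(cfg)
  de <- cm$truth$de_genes[["PP vs NP"]]
  up <- names(de)[de > 0]
  pp <- cm$meta$sample_id[cm$meta$treatment == "PP"]
  np <- cm$meta$sample_id[cm$meta$treatment == "NP"]
  obs <- log2(rowMeans(cm$counts[up, pp]) + 1) -
    log2(rowMeans(cm$counts[up, np]) + 1)
  expect_equal(mean(obs), 2, tolerance = 0.15)
})

test_that("a written data set is reproducible byte for byte under one seed", {
  cfg <- small_cfg(seed = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim_dataset(cfg, d1)
  sim_dataset(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  # every truth id exists in the written files
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  gtf_ids <- unique(read_transcript_gtf(file.path(d1,
                                                  "assembled.gtf"))$transcript_id)
  expect_setequal(names(truth$class_codes), gtf_ids)
  counts <- read.delim(file.path(d1, "counts.tsv"), check.names = FALSE)
  expect_true(all(unlist(truth$regulator_ids) %in% counts$gene_id))
})
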