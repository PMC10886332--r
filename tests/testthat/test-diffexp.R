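nb_fixture <- function(seed = 1, n_genes = 300, n = 5, mu = 100,
                       disp = 0.1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * 3 * n, mu = mu, size = 1 / disp),
              nrow = n_genes,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(3 * n))))
  meta <- data.frame(sample_id = colnames(m),
                     treatment = rep(c("NP", "PP", "CP"), each = n),
                     age_of_dam = runif(3 * n, 1800, 4000),
                     age_of_animal = runif(3 * n, 650, 700))
  list(counts = m, meta = meta)
}

test_that("TMM factors satisfy their normalisation contracts", {
  fx <- nb_fixture()
  ident <- fx$counts[, c(1, 1, 1)]
  colnames(ident) <- c("a", "b", "c")
  expect_equal(unname(tmm_factors(ident)), rep(1, 3), tolerance = 1e-12)
  dbl <- cbind(fx$counts[, 1:4], dbl = fx$counts[, 1] * 2L)
  f <- tmm_factors(dbl)
  expect_equal(unname(f[["dbl"]] / f[[1]]), 2, tolerance = 0.01)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  z <- fx$counts[, 1:3]; z[, 2] <- 0L
  expect_error(tmm_factors(z), "all-zero")
  expect_error(tmm_factors(fx$counts[, 1, drop = FALSE]), "2 samples")
})

test_that("common dispersion is recovered from simulated counts", {
  fx <- nb_fixture(seed = 4, n_genes = 2000, n = 5, disp = 0.1)
  design <- model.matrix(~treatment, fx$meta)
  d <- estimate_dispersion(fx$counts[, 1:10], design[1:10, 1:2])
  expect_gte(d, 0.07); expect_lte(d, 0.13)
  set.seed(5)
  pois <- matrix(rpois(2000 * 10, 100), nrow = 2000,
                 dimnames = list(sprintf("g%04d", 1:2000),
                                 sprintf("s%02d", 1:10)))
  d0 <- estimate_dispersion(pois, cbind(1, rep(0:1, each = 5)))
  expect_lte(d0, 0.01)
  # permutation invariance over gene order
  perm <- sample(nrow(pois))
  expect_equal(estimate_dispersion(pois[perm, ], cbind(1, rep(0:1, each = 5))),
               d0)
})

test_that("contrast direction only flips the sign of the fold change", {
  fx <- nb_fixture(seed = 9, n_genes = 100)
  a <- de_test(fx$counts, fx$meta, c("PP", "NP"))
  b <- de_test(fx$counts, fx$meta, c("NP", "PP"))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-8)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-8)
  expect_equal(unique(a$contrast), "PP vs NP")
})

test_that("de_test results are invariant to sample-column permutation", {
  fx <- nb_fixture(seed = 12, n_genes = 80)
  a <- de_test(fx$counts, fx$meta, c("PP", "NP"))
  set.seed(2); perm <- sample(ncol(fx$counts))
  b <- de_test(fx$counts[, perm], fx$meta[perm, ], c("PP", "NP"))
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
})

test_that("design problems are reported as errors", {
  fx <- nb_fixture(seed = 3, n_genes = 50)
  meta <- fx$meta
  meta$aliased <- as.numeric(meta$treatment == "PP")
  expect_error(de_test(fx$counts, meta, c("PP", "NP"),
                       covariates = c("age_of_dam", "aliased")),
               "aliased")
  expect_error(de_test(fx$counts, fx$meta, c("PP", "XX")), "absent")
  expect_error(de_test(fx$counts, fx$meta[-1, ], c("PP", "NP")), "missing")
})

test_that("BH adjustment agrees with an independent step-up oracle", {
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  fx <- nb_fixture(seed = 21, n_genes = 60)
  res <- de_test(fx$counts, fx$meta, c("PP", "NP"))
  expect_equal(res$qvalue, bh_oracle(res$pvalue), tolerance = 1e-12)
})

test_that("dual-threshold calling tiers results like the published rule", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = 0, mean_log_cpm = 5,
                    pvalue = c(2.26e-7, 0.003, 0.02, 0.5),
                    qvalue = c(1e-4, 0.80, 0.3, 0.9),
                    contrast = "NP vs CP")
  out <- call_de(res)
  expect_equal(out$tier, c("fdr", "exploratory", NA, NA))
})

test_that("panel subsetting keeps order, warns on missing, errors on none", {
  fx <- nb_fixture(seed = 14, n_genes = 20)
  ids <- c("g0005", "g0001", "g9999")
  expect_warning(sub <- panel_subset(fx$counts, ids), "absent")
  expect_equal(rownames(sub), c("g0005", "g0001"))
  expect_error(panel_subset(fx$counts, c("x", "y")), "no panel gene")
  expect_error(panel_subset(fx$counts, character(0)), "empty")
  path <- withr::local_tempfile()
  writeLines(c("g0002", "g0003"), path)
  expect_equal(rownames(panel_subset(fx$counts, path)), c("g0002", "g0003"))
})

test_that("panel-restricted testing matches post-hoc restriction except BH", {
  fx <- nb_fixture(seed = 17, n_genes = 120)
  panel <- sprintf("g%04d", 1:30)
  full <- de_test(fx$counts, fx$meta, c("PP", "NP"))
  sub <- de_test(panel_subset(fx$counts, panel), fx$meta, c("PP", "NP"))
  m <- match(panel, full$gene_id)
  # per-gene statistics agree up to the normalisation factors and common
  # dispersion being re-estimated on the subset; only the BH universe
  # legitimately differs (documented behaviour)
  expect_lt(max(abs(sub$log2fc - full$log2fc[m])), 0.1)
  expect_gt(cor(log(sub$pvalue), log(full$pvalue[m])), 0.95)
  expect_equal(sub$qvalue, bh_oracle(sub$pvalue), tolerance = 1e-12)
})
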