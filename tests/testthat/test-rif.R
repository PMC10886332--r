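test_that("RIF formulas match hand arithmetic", {
  # single regulator, single target: e1=2, e2=1, r1=1, r2=0
  r1 <- matrix(1, 1, 1, dimnames = list("reg", "tgt"))
  r2 <- matrix(0, 1, 1, dimnames = list("reg", "tgt"))
  sc <- rif_scores(c(tgt = 2), c(tgt = 1), r1, r2)
  expect_equal(sc$rif1, ((2 + 1) / 2) * (2 - 1) * 1^2)  # 1.5
  expect_equal(sc$rif2, (2 * 1)^2 - (1 * 0)^2)          # 4
})

test_that("identical conditions give zero raw RIF1 for every regulator", {
  set.seed(8)
  r <- matrix(runif(20, -1, 1), 4, 5,
              dimnames = list(paste0("r", 1:4), paste0("t", 1:5)))
  e <- runif(5, 2, 8); names(e) <- colnames(r)
  sc <- rif_scores(e, e, r, r)
  expect_equal(sc$rif1, rep(0, 4))
})

test_that("z-standardisation contract holds exactly", {
  set.seed(5)
  r1 <- matrix(runif(50, -1, 1), 10, 5)
  r2 <- matrix(runif(50, -1, 1), 10, 5)
  dimnames(r1) <- dimnames(r2) <- list(paste0("r", 1:10), paste0("t", 1:5))
  e1 <- runif(5, 2, 8); e2 <- runif(5, 2, 8)
  names(e1) <- names(e2) <- colnames(r1)
  sc <- rif_scores(e1, e2, r1, r2)
  expect_equal(mean(sc$z1), 0, tolerance = 1e-9)
  expect_equal(sd(sc$z1), 1, tolerance = 1e-9)
  expect_equal(mean(sc$z2), 0, tolerance = 1e-9)
  expect_equal(sd(sc$z2), 1, tolerance = 1e-9)
})

test_that("RIF1 is order-invariant and quadratic in differential wiring", {
  set.seed(6)
  r1 <- matrix(runif(30, -0.5, 0.5), 6, 5)
  dw <- matrix(runif(30, -0.4, 0.4), 6, 5)
  r2 <- r1 - dw
  dimnames(r1) <- dimnames(r2) <- list(paste0("r", 1:6), paste0("t", 1:5))
  e1 <- runif(5, 2, 8); e2 <- runif(5, 2, 8)
  names(e1) <- names(e2) <- colnames(r1)
  base <- rif_scores(e1, e2, r1, r2)
  perm <- c(3, 1, 5, 2, 4)
  permuted <- rif_scores(e1[perm], e2[perm], r1[, perm], r2[, perm])
  expect_equal(base$rif1, permuted$rif1)
  # doubling DW quadruples raw RIF1
  doubled <- rif_scores(e1, e2, r1, r1 - 2 * dw)
  expect_equal(doubled$rif1, 4 * base$rif1)
})

test_that("condition correlations handle duplicates and degeneracy", {
  set.seed(3)
  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(c("reg", "dup", "flat", "tgt"),
                                 paste0("s", 1:10)))
  expr["dup", ] <- expr["reg", ]
  expr["flat", ] <- 5
  r <- condition_correlations(expr, "reg", c("dup", "flat", "tgt"),
                              paste0("s", 1:10))
  expect_equal(r["reg", "dup"], 1)
  expect_equal(r["reg", "flat"], 0)  # flagged, not NaN
  expect_gt(nrow(attr(r, "degenerate")), 0)
  expect_error(condition_correlations(expr, "reg", "tgt", paste0("s", 1:2)),
               "3 samples")
  expect_error(condition_correlations(expr, "nope", "tgt", paste0("s", 1:5)),
               "absent")
})

test_that("null regulator-target correlations rarely reach |r| = 0.8", {
  set.seed(44)
  hits <- 0; total <- 0
  for (i in 1:50) {
    expr <- matrix(rnorm(20 * 10), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
    r <- condition_correlations(expr, paste0("g", 1:5), paste0("g", 6:20),
                                paste0("s", 1:10))
    hits <- hits + sum(abs(r) >= 0.8)
    total <- total + length(r)
  }
  expect_lt(hits / total, 0.01)
})

test_that("GO target selection filters by term list and expression", {
  go_map <- data.frame(gene_id = c("g1", "g2", "g3"),
                       go_id = c("GO:0048641", "GO:0000001", "GO:0048741"))
  sel <- select_targets(go_map, c("GO:0048641", "GO:0048741"),
                        c("g1", "g2"))
  expect_equal(sel$target_gene_ids, "g1")  # g3 not expressed
  expect_equal(sel$n_expressed, 2L)
  expect_warning(empty <- select_targets(go_map, character(0), "g1"),
                 "empty")
  expect_length(empty$target_gene_ids, 0L)
  expect_error(select_targets(go_map, "GO:12", "g1"), "malformed")
})

test_that("a planted 1222-of-14125 annotation yields 1222 targets", {
  set.seed(12)
  expressed <- sprintf("G%05d", 1:14125)
  chosen <- sample(expressed, 1222)
  go_map <- data.frame(gene_id = chosen,
                       go_id = sample(muscle_go_terms(), 1222, TRUE))
  sel <- select_targets(go_map, muscle_go_terms(), expressed)
  expect_length(sel$target_gene_ids, 1222L)
})

test_that("key regulators are selected by either score beyond the threshold", {
  sc <- data.frame(regulator_id = c("a", "b", "c", "d"),
                   z1 = c(2.5, 1.0, 0.5, -2.2), z2 = c(0, -2.0, 1.0, 0))
  expect_setequal(key_regulators(sc), c("a", "b", "d"))
  expect_setequal(key_regulators(sc, use = "rif1"), c("a", "d"))
  expect_setequal(key_regulators(sc, use = "rif2"), "b")
  expect_setequal(key_regulators(sc, z_min = 0.4), c("a", "b", "c", "d"))
})

test_that("planted regulator rank improves monotonically with wiring delta", {
  regs <- sprintf("REG_%02d", 1:10)
  tgts <- sprintf("TGT_%03d", 1:50)
  med_rank <- sapply(c(0.2, 0.5, 0.8), function(delta) {
    ranks <- sapply(1:8, function(s) {
      cfg <- sim_config(n_genes = 500, n_samples_per_group = 10,
                        wiring_delta = delta, seed = 300 + s)
      cm <- sim_counts(cfg)
      sc <- rif_analysis(cm$counts, cm$meta, regs, tgts, c("PP", "NP"))
      median(match(sprintf("REG_%02d", 1:3),
                   sc$regulator_id[order(-sc$rif1)]))
    })
    mean(ranks)
  })
  expect_true(all(diff(med_rank) < 0))
  expect_lt(med_rank[3], 3.5)
})
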