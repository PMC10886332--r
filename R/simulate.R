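#' Simulation configuration
#'
#' Parameters of the synthetic-data generator that emulates every input
#' of the pipeline with known ground truth: a toy genome and reference
#' annotation, assembled transcripts with planted class codes, transcript
#' sequences with planted coding structure, and negative-binomial count
#' matrices with planted differential expression and planted
#' differentially wired regulators.
#'
#' The defaults define the simulated study conditions: three
#' maternal-nutrition groups (NP control, PP, CP) of
#' `n_samples_per_group` animals; a class-code mix dominated by novel
#' isoforms (`j`) as reference-guided assembly produces, with all nine
#' codes represented; 600-nt planted ORFs for coding transcripts versus a
#' 90-nt ORF ceiling for non-coding ones; and a latent-factor wiring
#' model in which a planted regulator is correlated with its targets at
#' `wiring_base + wiring_delta` in the `wired_treatment` group but only
#' `wiring_base` elsewhere, with an activity shift that also moves the
#' target means (differential wiring comes with target response).
#'
#' @param n_chromosomes,chrom_length,n_reference_genes toy genome sizing.
#' @param n_assembled_transcripts transcripts to plant.
#' @param class_code_mix named proportions over the nine class codes;
#'   must sum to 1.
#' @param coding_fraction fraction of transcripts given a planted ORF.
#' @param coding_orf_length planted ORF length (nt, multiple of 3,
#'   includes the stop codon).
#' @param noncoding_orf_ceiling maximum complete-ORF length (nt) allowed
#'   in non-coding sequences.
#' @param n_genes background genes in the count matrix.
#' @param n_samples_per_group samples per treatment group (>= 2).
#' @param nb_dispersion negative-binomial dispersion (> 0).
#' @param de_fraction,de_log2fc fraction of background genes planted as
#'   differentially expressed in the programmed (PP, CP) groups, and
#'   their absolute log2 fold change.
#' @param n_regulators,n_planted_regulators,n_targets regulator/target
#'   layout; the first `n_planted_regulators` regulators are wired.
#' @param wiring_delta,wiring_base per-condition target correlations:
#'   wired treatment `wiring_base + wiring_delta`, elsewhere
#'   `wiring_base`.
#' @param wiring_shift regulator activity shift accompanying wiring (log2
#'   units): wired targets respond in mean as well as in correlation.
#' @param latent_sd biological log2-scale standard deviation of the
#'   regulator/target latent factors; large relative to count-sampling
#'   noise so planted correlations survive the negative-binomial layer.
#' @param wired_treatment group in which planted wiring is active.
#' @param lib_size_variation half-width of the uniform library-size
#'   factor (0 = equal libraries).
#' @param n_panel_genes size of the epigenetic gene panel drawn from the
#'   background genes (never planted as DE).
#' @param seed integer seed; every generator output is a deterministic
#'   function of it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 250000L,
                       n_reference_genes = 30L,
                       n_assembled_transcripts = 200L,
                       class_code_mix = c("=" = 0.04, "c" = 0.04, "j" = 0.60,
                                          "e" = 0.02, "i" = 0.06, "o" = 0.06,
                                          "p" = 0.02, "u" = 0.12, "x" = 0.04),
                       coding_fraction = 0.3, coding_orf_length = 600L,
                       noncoding_orf_ceiling = 90L,
                       n_genes = 2000L, n_samples_per_group = 5L,
                       nb_dispersion = 0.1, de_fraction = 0.1, de_log2fc = 2,
                       n_regulators = 10L, n_planted_regulators = 3L,
                       n_targets = 50L, wiring_delta = 0.8, wiring_base = 0,
                       wiring_shift = 2, latent_sd = 2, wired_treatment = "PP",
                       lib_size_variation = 0.3, n_panel_genes = 164L,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_reference_genes = as.integer(n_reference_genes),
              n_assembled_transcripts = as.integer(n_assembled_transcripts),
              class_code_mix = class_code_mix,
              coding_fraction = coding_fraction,
              coding_orf_length = as.integer(coding_orf_length),
              noncoding_orf_ceiling = as.integer(noncoding_orf_ceiling),
              n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              de_log2fc = de_log2fc, n_regulators = as.integer(n_regulators),
              n_planted_regulators = as.integer(n_planted_regulators),
              n_targets = as.integer(n_targets), wiring_delta = wiring_delta,
              wiring_base = wiring_base, wiring_shift = wiring_shift,
              latent_sd = latent_sd,
              wired_treatment = wired_treatment,
              lib_size_variation = lib_size_variation,
              n_panel_genes = as.integer(n_panel_genes),
              seed = as.integer(seed))
  codes <- c("=", "c", "j", "e", "i", "o", "p", "u", "x")
  if (!setequal(names(cfg$class_code_mix), codes))
    stop("class_code_mix must name exactly the nine class codes")
  if (abs(sum(cfg$class_code_mix) - 1) > 1e-9)
    stop("class_code_mix proportions must sum to 1")
  if (any(cfg$class_code_mix < 0)) stop("negative class-code proportion")
  if (cfg$n_reference_genes < 1L)
    stop("sizing error: need at least 1 reference gene")
  counts <- c(cfg$n_chromosomes, cfg$n_assembled_transcripts, cfg$n_genes)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$wiring_delta < 0 || cfg$wiring_delta > 2)
    stop("wiring_delta must lie in [0, 2]")
  if (cfg$coding_fraction < 0 || cfg$coding_fraction > 1)
    stop("coding_fraction must lie in [0, 1]")
  if (cfg$coding_orf_length %% 3L != 0L)
    stop("coding_orf_length must be a multiple of 3")
  if (cfg$n_planted_regulators > cfg$n_regulators)
    stop("more planted regulators than regulators")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a toy genome and reference annotation
#'
#' Places multi-exon genes (3-5 exons) on each chromosome, separated by
#' intergenic gaps of 6-9 kb, alternating randomly between strands, and
#' draws a random genome sequence covering them. Coordinates are 1-based
#' closed GTF coordinates.
#'
#' @param config a [sim_config()].
#' @return List with `models` (a [transcript_models()] frame, one
#'   transcript per gene) and `genome` (a named `DNAStringSet`).
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  rows <- list()
  for (g in seq_len(config$n_reference_genes)) {
    chrom <- chroms[((g - 1L) %% length(chroms)) + 1L]
    gap <- sample(6000:9000, 1L)
    start <- cursor[chrom] + gap
    n_ex <- sample(3:5, 1L)
    widths <- sample(120:400, n_ex, replace = TRUE)
    introns <- sample(600:1500, n_ex - 1L, replace = TRUE)
    s <- integer(n_ex); e <- integer(n_ex)
    pos <- start
    for (k in seq_len(n_ex)) {
      s[k] <- pos
      e[k] <- pos + widths[k] - 1L
      pos <- e[k] + 1L + if (k < n_ex) introns[k] else 0L
    }
    if (e[n_ex] + 2000L > config$chrom_length)
      stop("sizing error: ", config$n_reference_genes,
           " genes do not fit on chromosomes of length ",
           config$chrom_length)
    cursor[chrom] <- e[n_ex]
    gid <- sprintf("G%04d", g)
    rows[[g]] <- data.frame(transcript_id = paste0(gid, ".1"), gene_id = gid,
                            chrom = chrom, strand = sample(c("+", "-"), 1L),
                            start = s, end = e)
  }
  models <- transcript_models(do.call(rbind, rows))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = ""), character(1)))
  names(genome) <- chroms
  list(models = models, genome = genome)
}

# per-code geometric constructions; each returns an exon data frame or
# NULL when the chosen reference gene cannot host the code
.construct_code <- function(code, ref_tx, gaps) {
  pick <- function(pred = function(r) TRUE) {
    ok <- Filter(pred, ref_tx)
    if (!length(ok)) return(NULL)
    ok[[sample.int(length(ok), 1L)]]
  }
  ex <- function(r, s, e, strand = r$strand)
    data.frame(chrom = r$chrom, strand = strand, start = as.integer(s),
               end = as.integer(e))
  switch(code,
    "=" = {
      r <- pick(function(r) nrow(r$exons) >= 2L)
      if (is.null(r)) return(NULL)
      ex(r, r$exons[, 1], r$exons[, 2])
    },
    "c" = {
      r <- pick(function(r) nrow(r$exons) >= 3L)
      if (is.null(r)) return(NULL)
      n <- nrow(r$exons)
      if (n >= 4L) ex(r, r$exons[2:(n - 1L), 1], r$exons[2:(n - 1L), 2])
      else {
        w <- r$exons[2, 2] - r$exons[2, 1] + 1L
        off <- max(0L, (w - sample(80:200, 1L)) %/% 2L)
        ex(r, r$exons[2, 1] + off, r$exons[2, 2] - off)
      }
    },
    "j" = {
      r <- pick(function(r) nrow(r$introns) >= 2L)
      if (is.null(r)) return(NULL)
      n <- nrow(r$exons)
      s <- r$exons[, 1]; e <- r$exons[, 2]
      s[n] <- s[n] - sample(30:80, 1L)  # shift the last splice junction
      ex(r, s, e)
    },
    "e" = {
      r <- pick(function(r) nrow(r$exons) >= 2L)
      if (is.null(r)) return(NULL)
      k <- sample.int(nrow(r$exons) - 1L, 1L)
      mid <- (r$exons[k, 1] + r$exons[k, 2]) %/% 2L
      ex(r, mid, r$exons[k, 2] + sample(60:150, 1L))
    },
    "o" = {
      r <- pick()
      gs <- r$exons[1, 1]
      ex(r, c(gs - 900L, gs - 300L), c(gs - 650L, gs + 80L))
    },
    "i" = {
      r <- pick(function(r) nrow(r$introns) > 0L &&
                  max(r$introns[, 2] - r$introns[, 1]) >= 450L)
      if (is.null(r)) return(NULL)
      k <- which.max(r$introns[, 2] - r$introns[, 1])
      is <- r$introns[k, 1]
      ex(r, c(is + 40L, is + 40L + 200L), c(is + 40L + 120L, is + 40L + 320L))
    },
    "p" = {
      r <- pick()
      d <- sample(150:400, 1L); w <- sample(250:400, 1L)
      if (r$strand == "-") ex(r, r$span[1] - d - w, r$span[1] - d)
      else ex(r, r$span[2] + d, r$span[2] + d + w)
    },
    "x" = {
      r <- pick(function(r) nrow(r$exons) >= 2L)
      if (is.null(r)) return(NULL)
      flip <- if (r$strand == "+") "-" else "+"
      ex(r, r$exons[1:2, 1], r$exons[1:2, 2], strand = flip)
    },
    "u" = {
      slot <- gaps[sample.int(nrow(gaps), 1L), ]
      width <- min(1200L, slot$end - slot$start + 1L)
      s0 <- slot$start + sample.int(max(1L, slot$end - slot$start + 1L -
                                          width), 1L) - 1L
      w1 <- sample(220:380, 1L); gap1 <- sample(120:200, 1L)
      w2 <- min(sample(220:380, 1L), width - w1 - gap1)
      data.frame(chrom = slot$chrom, strand = sample(c("+", "-"), 1L),
                 start = as.integer(c(s0, s0 + w1 + gap1)),
                 end = as.integer(c(s0 + w1 - 1L, s0 + w1 + gap1 + w2 - 1L)))
    })
}

# intergenic slots at least 2.1 kb away from every reference span
.u_slots <- function(ref_models, chrom_length) {
  margin <- 2100L
  out <- list()
  for (ch in unique(ref_models$chrom)) {
    m <- ref_models[ref_models$chrom == ch, ]
    spans <- vapply(split(seq_len(nrow(m)), m$gene_id), function(i)
      c(min(m$start[i]), max(m$end[i])), numeric(2))
    spans <- spans[, order(spans[1, ]), drop = FALSE]
    bounds <- c(1L, as.vector(spans), chrom_length)
    for (k in seq_len(ncol(spans) + 1L)) {
      lo <- if (k == 1L) 1L else spans[2, k - 1L] + margin
      hi <- if (k > ncol(spans)) chrom_length - 100L else spans[1, k] - margin
      if (hi - lo >= 700L)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = lo, end = hi)
    }
  }
  do.call(rbind, out)
}

#' Simulate assembled transcripts with planted class codes
#'
#' Constructs, for each requested class code, a transcript whose geometry
#' satisfies that code's definition relative to the reference (see
#' [classify_transcripts()]): intron-chain copies for `=`, compatible
#' truncations for `c`, shifted splice junctions for `j`, boundary
#' single-exon fragments for `e`, intronic transcripts for `i`, partial
#' exonic overlaps for `o`, downstream run-on fragments for `p`,
#' opposite-strand exon copies for `x`, and intergenic transcripts placed
#' more than 2 kb from every reference span for `u`.
#'
#' @param reference output of [sim_reference()].
#' @param config a [sim_config()].
#' @return List with `models` (`transcript_models`) and `truth` (list
#'   with `class_codes`, a named vector).
#' @export
sim_transcripts <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ref_tx <- .tx_records(reference$models)
  gaps <- .u_slots(reference$models, config$chrom_length)
  n <- config$n_assembled_transcripts
  mix <- config$class_code_mix
  cnt <- floor(mix * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(mix * n - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  codes <- sample(rep(names(cnt), cnt))
  rows <- list(); truth_codes <- character(n)
  for (t in seq_len(n)) {
    exdf <- .construct_code(codes[t], ref_tx, gaps)
    if (is.null(exdf))
      stop("construction error: no reference gene can host class code '",
           codes[t], "'")
    tid <- sprintf("TCONS_%05d", t)
    exdf$transcript_id <- tid
    exdf$gene_id <- sprintf("XLOC_%05d", t)
    rows[[t]] <- exdf
    truth_codes[t] <- codes[t]
    names(truth_codes)[t] <- tid
  }
  models <- transcript_models(do.call(rbind, rows))
  list(models = models, truth = list(class_codes = truth_codes))
}

.load_codon_table <- function() {
  path <- system.file("extdata", "codon_usage.tsv", package = "lncnet")
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tb$per_thousand, tb$codon)
}

# random sequence without any long complete ORF; stops are inserted into
# offending ORFs (TAA insertion can never create a new ATG)
.rand_noncoding <- function(len, ceiling_nt) {
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  repeat {
    orfs <- find_orfs(s)
    bad <- orfs[orfs$length_nt > ceiling_nt, , drop = FALSE]
    if (nrow(bad) == 0L) return(s)
    for (i in seq_len(nrow(bad))) {
      b <- bad[i, ]
      # random in-frame codon inside the ORF: overlapping ORFs in other
      # frames can overwrite a freshly planted stop, so a deterministic
      # position could cycle forever
      k <- sample.int(max(1L, b$length_nt %/% 3L - 2L), 1L)
      at <- b$start + 3L * k
      substr(s, at, at + 2L) <- "TAA"
    }
  }
}

.strip_atg <- function(s) {
  while (grepl("ATG", s, fixed = TRUE)) s <- sub("ATG", "ACG", s, fixed = TRUE)
  s
}

#' Simulate transcript sequences with planted coding structure
#'
#' Coding-labelled transcripts carry one planted sense-strand ORF of
#' `coding_orf_length` nucleotides (`ATG` ... in-frame stop) whose codons
#' are drawn from the packaged codon-usage table, flanked by ATG-free
#' UTRs, so the planted ORF is exactly the longest ORF of the sequence.
#' Non-coding transcripts have every complete sense-frame ORF at or below
#' `noncoding_orf_ceiling` nucleotides. Labels are assigned to a
#' `coding_fraction` of the transcripts long enough to host the ORF.
#'
#' @param transcripts output of [sim_transcripts()].
#' @param config a [sim_config()].
#' @return List with `sequences` (named `DNAStringSet`) and `truth`
#'   (adds `coding_labels` and `planted_orf_lengths` to the transcript
#'   truth).
#' @export
sim_sequences <- function(transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lens <- .tx_lengths(transcripts$models)
  ids <- names(lens)
  orf_len <- config$coding_orf_length
  eligible <- ids[lens >= orf_len + 60L]
  n_coding <- min(round(config$coding_fraction * length(ids)),
                  length(eligible))
  coding_ids <- if (n_coding > 0) sort(sample(eligible, n_coding)) else character(0)
  codon_w <- .load_codon_table()
  sense <- setdiff(names(codon_w), c("TAA", "TAG", "TGA"))
  seqs <- character(length(ids)); names(seqs) <- ids
  planted <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    len <- lens[[id]]
    if (id %in% coding_ids) {
      for (try in 1:25) {
        utr5 <- sample.int(len - orf_len + 1L, 1L) - 1L
        utr3 <- len - orf_len - utr5
        cds <- paste0("ATG",
                      paste(sample(sense, orf_len / 3L - 2L, replace = TRUE,
                                   prob = codon_w[sense]), collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L,
                             prob = c(0.3, 0.2, 0.5)))
        s <- paste0(
          if (utr5 > 0) .strip_atg(.rand_noncoding(utr5, config$noncoding_orf_ceiling)) else "",
          cds,
          if (utr3 > 0) .rand_noncoding(utr3, config$noncoding_orf_ceiling) else "")
        if (longest_orf(s) == orf_len) break
        s <- NA_character_
      }
      if (is.na(s))
        stop("construction error: could not plant a ", orf_len,
             "-nt ORF in transcript ", id, " of length ", len)
      seqs[id] <- s
      planted[id] <- orf_len
    } else {
      seqs[id] <- .rand_noncoding(len, config$noncoding_orf_ceiling)
    }
  }
  truth <- transcripts$truth
  truth$coding_labels <- stats::setNames(
    ifelse(ids %in% coding_ids, "coding", "noncoding"), ids)
  truth$planted_orf_lengths <- planted
  list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Simulate count matrices with planted signal
#'
#' Draws a genes x samples matrix of negative-binomial counts for three
#' treatment groups (NP control, PP, CP), with planted differential
#' expression in the programmed groups and a planted regulator/target
#' block: each wired target's log2 expression follows
#' `mu + w * (delta_reg + shift) + sqrt(1 - w^2) * noise`, giving a
#' population regulator-target correlation of about `w` per condition and
#' a mean response proportional to the wiring.
#'
#' @param config a [sim_config()].
#' @param regulator_ids,target_ids optional row names for the regulator
#'   and target genes (defaults `REG_xx`, `TGT_xxx`).
#' @return List with `counts` (integer matrix), `meta` (sample metadata:
#'   `sample_id`, `treatment`, `age_of_dam`, `age_of_animal`,
#'   `timepoint`) and `truth` (`de_genes` per contrast with signed
#'   log2 fold changes, `regulator_wiring`, `target_regulator`).
#' @export
sim_counts <- function(config, regulator_ids = NULL, target_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_per_group < 2L)
    stop("design error: need >= 2 samples per group to estimate dispersion")
  set.seed(config$seed + 3L)
  n <- config$n_samples_per_group
  groups <- rep(c("NP", "PP", "CP"), each = n)
  ns <- length(groups)
  sample_ids <- sprintf("S%02d_%s", seq_len(ns), groups)
  if (is.null(regulator_ids))
    regulator_ids <- sprintf("REG_%02d", seq_len(config$n_regulators))
  if (is.null(target_ids))
    target_ids <- sprintf("TGT_%03d", seq_len(config$n_targets))
  stopifnot(length(regulator_ids) == config$n_regulators,
            length(target_ids) == config$n_targets)
  gene_ids <- sprintf("GENE_%04d", seq_len(config$n_genes))

  # background genes with planted DE in the programmed groups
  mu_g <- stats::runif(config$n_genes, 3, 9)
  logmean <- matrix(rep(mu_g, ns), ncol = ns,
                    dimnames = list(gene_ids, sample_ids))
  n_de <- round(config$de_fraction * config$n_genes)
  de_ids <- if (n_de > 0) sample(gene_ids, n_de) else character(0)
  de_sign <- rep_len(c(1, -1), n_de)
  programmed <- groups %in% c("PP", "CP")
  if (n_de > 0)
    logmean[de_ids, programmed] <- logmean[de_ids, programmed] +
      de_sign * config$de_log2fc
  de_lfc <- stats::setNames(de_sign * config$de_log2fc, de_ids)

  # regulator / target latent-factor block
  w1 <- min(0.99, config$wiring_base + config$wiring_delta)
  w2 <- config$wiring_base
  wired <- groups == config$wired_treatment
  mu_r <- stats::runif(config$n_regulators, 5, 8)
  delta_r <- matrix(stats::rnorm(config$n_regulators * ns),
                    nrow = config$n_regulators)
  reg_log <- mu_r + config$latent_sd * delta_r
  dimnames(reg_log) <- list(regulator_ids, sample_ids)
  tgt_reg <- if (config$n_planted_regulators > 0)
    rep_len(seq_len(config$n_planted_regulators), config$n_targets)
  else rep_len(NA_integer_, config$n_targets)
  mu_t <- stats::runif(config$n_targets, 5, 8)
  tgt_log <- matrix(0, config$n_targets, ns,
                    dimnames = list(target_ids, sample_ids))
  for (j in seq_len(config$n_targets)) {
    k <- tgt_reg[j]
    eps <- stats::rnorm(ns)
    if (is.na(k)) {
      tgt_log[j, ] <- mu_t[j] + eps
    } else {
      w <- ifelse(wired, w1, w2)
      tgt_log[j, ] <- mu_t[j] +
        w * (config$latent_sd * delta_r[k, ] + config$wiring_shift) +
        config$latent_sd * sqrt(1 - w^2) * eps
    }
  }

  logmean <- rbind(logmean, reg_log, tgt_log)
  size_f <- if (config$lib_size_variation > 0)
    stats::runif(ns, 1 - config$lib_size_variation,
                 1 + config$lib_size_variation)
  else rep(1, ns)
  mu <- sweep(2^logmean, 2, size_f, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  meta <- data.frame(sample_id = sample_ids, treatment = groups,
                     age_of_dam = sample(1800:4000, ns, replace = TRUE),
                     age_of_animal = sample(650:700, ns, replace = TRUE),
                     timepoint = "22m")
  wiring <- data.frame(
    regulator_id = regulator_ids,
    w_wired = c(rep(w1, config$n_planted_regulators),
                rep(w2, config$n_regulators - config$n_planted_regulators)),
    w_control = rep(w2, config$n_regulators))
  truth <- list(
    de_genes = list("PP vs NP" = de_lfc, "CP vs NP" = de_lfc,
                    "CP vs PP" = stats::setNames(numeric(0), character(0))),
    regulator_wiring = wiring,
    target_regulator = stats::setNames(
      ifelse(is.na(tgt_reg), NA_character_, regulator_ids[tgt_reg]),
      target_ids),
    seed = config$seed)
  list(counts = counts, meta = meta, truth = truth)
}

#' Write a complete simulated data set to disk
#'
#' Runs every generator stage under the configured seed and writes the
#' files the pipeline consumes: genome FASTA, reference GTF, assembled
#' GTF, transcript FASTA, counts TSV, sample-metadata TSV, gene-GO map
#' TSV, epigenetic panel list, BLAST-style homology tables (UniProt-like
#' exclusion hits for a small fraction of non-coding transcripts, and
#' NONCODE-like identification hits), and a ground-truth JSON.
#'
#' Count-matrix rows are the background genes, the GO-annotated targets,
#' and lncRNA rows named after planted non-coding multi-exon transcripts
#' (the regulators), so identification and quantification stages join on
#' the same ids.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisible list with all in-memory objects and a `paths`
#'   element mapping file roles to paths.
#' @export
sim_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ref <- sim_reference(config)
  tx <- sim_transcripts(ref, config)
  sq <- sim_sequences(tx, config)
  truth <- sq$truth

  # lncRNA-capable transcripts: planted non-coding, allowed class code,
  # long enough, multi-exon -> regulator rows of the count matrix
  lens <- .tx_lengths(tx$models)
  nex <- .tx_exon_counts(tx$models)
  lnc_like <- names(lens)[truth$coding_labels == "noncoding" &
                            truth$class_codes %in% c("i", "j", "o", "u", "x") &
                            lens > 200L & nex >= 2L]
  if (length(lnc_like) < config$n_regulators)
    stop("too few non-coding transcripts to serve as regulators; ",
         "increase n_assembled_transcripts")
  set.seed(config$seed + 4L)
  regulators <- sort(sample(lnc_like, config$n_regulators))
  cm <- sim_counts(config, regulator_ids = regulators)
  truth <- c(truth, cm$truth)
  truth$regulator_ids <- regulators

  # gene-GO map: targets annotated to muscle GO terms, background genes
  # to other terms
  target_ids <- sprintf("TGT_%03d", seq_len(config$n_targets))
  gene_ids <- sprintf("GENE_%04d", seq_len(config$n_genes))
  muscle_go <- muscle_go_terms()
  other_go <- sprintf("GO:%07d", sample(1000000:2000000, 50))
  go_map <- rbind(
    data.frame(gene_id = target_ids,
               go_id = sample(muscle_go, length(target_ids), replace = TRUE)),
    data.frame(gene_id = sample(gene_ids, min(500L, length(gene_ids))),
               go_id = sample(other_go, min(500L, length(gene_ids)),
                              replace = TRUE)))

  # epigenetic panel: background genes never planted as DE
  non_de <- setdiff(gene_ids, names(truth$de_genes[["PP vs NP"]]))
  panel <- sort(sample(non_de, min(config$n_panel_genes, length(non_de))))

  # UniProt-like exclusion hits for ~2% of the non-coding candidates, and
  # strong hits for planted coding transcripts
  noncod <- names(truth$coding_labels)[truth$coding_labels == "noncoding"]
  hom_excl <- sort(sample(noncod, max(1L, round(0.02 * length(noncod)))))
  coding <- names(truth$coding_labels)[truth$coding_labels == "coding"]
  mk_hit <- function(q, s, pid, ev, bits)
    data.frame(qseqid = q, sseqid = s, pident = pid, length = 200L,
               mismatch = 5L, gapopen = 0L, qstart = 1L, qend = 200L,
               sstart = 1L, send = 200L, evalue = ev, bitscore = bits)
  uniprot_hits <- rbind(
    if (length(hom_excl)) mk_hit(hom_excl, sprintf("UP_%04d", seq_along(hom_excl)),
                                 55, 1e-12, 180),
    if (length(coding)) mk_hit(coding, sprintf("UP_%04d", 1000 + seq_along(coding)),
                               85, 1e-40, 350))
  truth$homology_excluded <- hom_excl

  # NONCODE-like identification hits for some regulators
  known <- regulators[seq_len(ceiling(length(regulators) / 2))]
  noncode_hits <- mk_hit(known, sprintf("NONBTAT%06d.1", seq_along(known)),
                         stats::runif(length(known), 82, 99),
                         10^stats::runif(length(known), -40, -10),
                         stats::runif(length(known), 150, 400))
  truth$noncode_known <- stats::setNames(noncode_hits$sseqid, known)

  Biostrings::writeXStringSet(ref$genome, p("genome.fa"))
  write_transcript_gtf(ref$models, p("reference.gtf"))
  write_transcript_gtf(tx$models, p("assembled.gtf"))
  Biostrings::writeXStringSet(sq$sequences, p("transcripts.fa"))
  utils::write.table(data.frame(gene_id = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$meta, p("meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(go_map, p("go_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(panel, p("panel.txt"))
  writeLines(muscle_go, p("go_terms.txt"))
  .write_blast(uniprot_hits, p("uniprot_hits.tsv"))
  .write_blast(noncode_hits, p("noncode_hits.tsv"))
  jsonlite::write_json(.truth_json(truth), p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  paths <- list(genome = p("genome.fa"), reference_gtf = p("reference.gtf"),
                assembled_gtf = p("assembled.gtf"),
                transcripts_fa = p("transcripts.fa"), counts = p("counts.tsv"),
                meta = p("meta.tsv"), go_map = p("go_map.tsv"),
                panel = p("panel.txt"), go_terms = p("go_terms.txt"),
                uniprot_hits = p("uniprot_hits.tsv"),
                noncode_hits = p("noncode_hits.tsv"), truth = p("truth.json"))
  invisible(list(reference = ref, transcripts = tx, sequences = sq$sequences,
                 counts = cm$counts, meta = cm$meta, truth = truth,
                 go_map = go_map, panel = panel, config = config,
                 paths = paths))
}

.write_blast <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.truth_json <- function(truth) {
  list(class_codes = as.list(truth$class_codes),
       coding_labels = as.list(truth$coding_labels),
       planted_orf_lengths = as.list(truth$planted_orf_lengths),
       de_genes = lapply(truth$de_genes, as.list),
       regulator_wiring = truth$regulator_wiring,
       target_regulator = as.list(truth$target_regulator),
       regulator_ids = truth$regulator_ids,
       homology_excluded = truth$homology_excluded,
       noncode_known = as.list(truth$noncode_known),
       seed = truth$seed)
}

#' Skeletal-muscle GO terms used for target selection
#'
#' The 19 Gene Ontology identifiers associated with skeletal-muscle
#' development and function that define the co-expression target panel.
#'
#' @return Character vector of GO ids.
#' @export
muscle_go_terms <- function() {
  c("GO:0048641", "GO:0048630", "GO:0048631", "GO:0048741", "GO:0003009",
    "GO:0003010", "GO:0003011", "GO:0043501", "GO:0043503", "GO:0043403",
    "GO:0007519", "GO:0035914", "GO:0014856", "GO:0014734", "GO:0014732",
    "GO:1904204", "GO:0014816", "GO:0048644", "GO:0048634")
}
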