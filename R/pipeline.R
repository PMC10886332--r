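#' Pipeline configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Settings may
#' come from a YAML file (`pipeline_config(yaml = "config.yaml")`);
#' explicit arguments override file values.
#'
#' @param reference_gtf,assembled_gtf,transcripts_fa,counts,meta,go_map,panel,go_terms,uniprot_hits,noncode_hits
#'   input file paths (homology tables and panel are optional, `NULL` to
#'   skip).
#' @param out_dir output directory.
#' @param length_min,orf_max,evalue_max,identity_min,q_max,exploratory_p,z_min,min_exons
#'   stage thresholds (see the stage functions for semantics).
#' @param treatments treatment labels, control first.
#' @param seed integer seed recorded in the manifest.
#' @param yaml optional YAML file of the same keys.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_gtf = NULL, assembled_gtf = NULL,
                            transcripts_fa = NULL, counts = NULL, meta = NULL,
                            go_map = NULL, panel = NULL, go_terms = NULL,
                            uniprot_hits = NULL, noncode_hits = NULL,
                            out_dir = "lncnet_out", length_min = 200L,
                            orf_max = 300L, evalue_max = 1e-6,
                            identity_min = 80, q_max = 0.05,
                            exploratory_p = 0.01, z_min = 1.96,
                            min_exons = 2L,
                            treatments = c("NP", "PP", "CP"), seed = 1L,
                            yaml = NULL) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml)
    file_cfg <- yaml::read_yaml(yaml)
    explicit <- names(match.call())[-1]
    for (k in setdiff(names(file_cfg), c(explicit, "yaml")))
      cfg[[k]] <- file_cfg[[k]]
  }
  num <- c("length_min", "orf_max", "evalue_max", "identity_min", "q_max",
           "exploratory_p", "z_min", "min_exons")
  for (k in num) {
    cfg[[k]] <- as.numeric(cfg[[k]])
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      stop("threshold '", k, "' must be a positive number")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[lncnet:%s] %s", stage, paste0(...)))
}

.read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages over the configured inputs:
#' `identify` (class codes + lncRNA cascade), `de_panel` (epigenetic
#' panel differential expression), `de_lncrna` (lncRNA differential
#' expression with dual-threshold calling and non-coding database
#' characterisation), `rif` (regulatory impact factors per
#' treatment/control pair), `pcit` (per-treatment co-expression edges
#' over targets plus lncRNA), and `networks` (treatment-contrast
#' filters, connection counts, exports). A provenance manifest
#' (`manifest.json`) records package version, seed, thresholds, and
#' per-stage row counts. Any stage failure aborts with a stage-named
#' error.
#'
#' @param config a [pipeline_config()].
#' @return Invisible list of stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (k in c("reference_gtf", "assembled_gtf", "transcripts_fa", "counts",
              "meta", "go_map", "go_terms")) {
    if (is.null(config[[k]])) stop("pipeline input '", k, "' not set")
    if (!file.exists(config[[k]]))
      stop("pipeline input '", k, "' not found: ", config[[k]])
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "lncnet",
                   version = as.character(utils::packageVersion("lncnet")),
                   seed = config$seed,
                   thresholds = config[c("length_min", "orf_max",
                                         "evalue_max", "identity_min",
                                         "q_max", "exploratory_p", "z_min",
                                         "min_exons")],
                   stages = list())
  stage <- function(name, expr) {
    .stage_msg(name, "running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- identify ------------------------------------------------------------
  identify <- stage("identify", {
    ref <- read_transcript_gtf(config$reference_gtf)
    asm <- read_transcript_gtf(config$assembled_gtf)
    seqs <- Biostrings::readDNAStringSet(config$transcripts_fa)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    assignments <- classify_transcripts(asm, ref)
    hits <- if (!is.null(config$uniprot_hits))
      read_blast_table(config$uniprot_hits) else NULL
    casc <- run_cascade(asm, assignments, seqs, uniprot_hits = hits,
                        config = cascade_config(
                          length_min = config$length_min,
                          orf_max = config$orf_max,
                          evalue_max = config$evalue_max,
                          min_exons = config$min_exons))
    write_tracking(assignments, out("tracking.tsv"))
    utils::write.table(casc$report, out("filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(casc$lncrna_ids, out("lncrna_ids.txt"))
    write_transcript_gtf(asm[asm$transcript_id %in% casc$lncrna_ids, ],
                         out("lncrna.gtf"))
    Biostrings::writeXStringSet(seqs[casc$lncrna_ids], out("lncrna.fa"))
    list(assignments = assignments, cascade = casc, sequences = seqs)
  })
  manifest$stages$identify <- list(
    n_transcripts = nrow(identify$assignments),
    n_candidates = identify$cascade$report$n_surviving[1],
    n_lncrna = length(identify$cascade$lncrna_ids))

  counts <- .read_counts_tsv(config$counts)
  meta <- utils::read.delim(config$meta)
  control <- config$treatments[1]
  treats <- config$treatments[-1]
  pairs <- lapply(treats, function(tr) c(tr, control))
  contrasts <- pairs
  if (length(treats) == 2L) contrasts <- c(contrasts, list(treats))

  # -- de_panel ------------------------------------------------------------
  de_panel <- stage("de_panel", {
    if (is.null(config$panel)) return(NULL)
    pc <- panel_subset(counts, config$panel)
    res <- do.call(rbind, lapply(contrasts, function(ct)
      call_de(de_test(pc, meta, ct), config$q_max, config$exploratory_p)))
    utils::write.table(res, out("de_panel.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res
  })
  manifest$stages$de_panel <- list(
    n_tests = if (is.null(de_panel)) 0L else nrow(de_panel),
    n_fdr = if (is.null(de_panel)) 0L else sum(de_panel$tier %in% "fdr"))

  # -- de_lncrna -----------------------------------------------------------
  lnc_ids <- intersect(identify$cascade$lncrna_ids, rownames(counts))
  de_lnc <- stage("de_lncrna", {
    if (length(lnc_ids) < 1L)
      stop("no identified lncRNA has counts; check id consistency")
    lc <- counts[lnc_ids, , drop = FALSE]
    res <- do.call(rbind, lapply(contrasts, function(ct)
      call_de(de_test(lc, meta, ct), config$q_max, config$exploratory_p)))
    if (!is.null(config$noncode_hits)) {
      ident <- characterize_homology(lnc_ids,
                                     read_blast_table(config$noncode_hits),
                                     config$identity_min, config$evalue_max)
      res$identification <- ident$identification[match(res$gene_id,
                                                       ident$transcript_id)]
    }
    utils::write.table(res, out("de_lncrna.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res
  })
  manifest$stages$de_lncrna <- list(
    n_lncrna_tested = length(lnc_ids),
    n_fdr = sum(de_lnc$tier %in% "fdr"),
    n_exploratory = sum(de_lnc$tier %in% "exploratory"))

  # -- rif -----------------------------------------------------------------
  rif <- stage("rif", {
    go_map <- utils::read.delim(config$go_map)
    terms <- readLines(config$go_terms)
    targets <- select_targets(go_map, terms[nzchar(terms)], rownames(counts))
    if (!length(targets$target_gene_ids)) stop("no GO-selected target genes")
    tabs <- lapply(pairs, function(pr)
      rif_analysis(counts, meta, lnc_ids, targets$target_gene_ids, pr))
    tab <- do.call(rbind, tabs)
    keys <- sort(unique(unlist(lapply(tabs, key_regulators,
                                      z_min = config$z_min))))
    utils::write.table(tab, out("rif_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(keys, out("key_regulators.txt"))
    list(scores = tab, key_regulators = keys, targets = targets)
  })
  manifest$stages$rif <- list(
    n_regulators = length(lnc_ids),
    n_targets = length(rif$targets$target_gene_ids),
    n_key_regulators = length(rif$key_regulators))

  # -- pcit ----------------------------------------------------------------
  nodes <- c(rif$targets$target_gene_ids, lnc_ids)
  edges <- stage("pcit", {
    es <- lapply(config$treatments, function(tr)
      pcit_network(counts, meta, nodes, tr))
    names(es) <- config$treatments
    for (tr in config$treatments)
      export_network(es[[tr]], out(sprintf("edges_%s.tsv", tr)), "tsv")
    es
  })
  manifest$stages$pcit <- lapply(edges, nrow)

  # -- networks ------------------------------------------------------------
  networks <- stage("networks", {
    cf <- contrast_filters(edges$NP, edges$PP, edges$CP)
    counts_tab <- lapply(cf, connection_counts, lnc_ids = rif$key_regulators)
    for (nm in names(cf)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", nm)
      export_network(cf[[nm]], out(sprintf("network_%s.sif", slug)), "sif")
      export_network(cf[[nm]], out(sprintf("network_%s.graphml", slug)),
                     "graphml")
      suppressWarnings(export_gene_lists(cf[[nm]], rif$key_regulators,
                                         out(sprintf("genes_%s.txt", slug))))
    }
    list(filters = cf, connection_counts = counts_tab)
  })
  manifest$stages$networks <- lapply(networks$filters, nrow)

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  .stage_msg("done", "manifest written to ", out("manifest.json"))
  invisible(list(identify = identify, de_panel = de_panel,
                 de_lncrna = de_lnc, rif = rif, edges = edges,
                 networks = networks, manifest = manifest))
}
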