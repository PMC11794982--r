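#' Pipeline configuration
#'
#' Combines a [sim_config()] with the analysis parameters of every
#' downstream stage. The defaults carry the pipeline's reference
#' parameters: 50-bp bins, 500-bp merge gap, HMM segmentation,
#' strand-specific classification, upper-quartile marker labelling and
#' BH significance at q < 0.05.
#'
#' @param sim A [sim_config()].
#' @param bin_size Coverage bin width in bases.
#' @param merge_gap TAR merge gap in bases.
#' @param seg_mode `"hmm"` or `"presence"` segmentation.
#' @param strand_mode `"specific"` or `"ignore"` gene-overlap
#'   strandedness for classification.
#' @param quantile Signature-score quantile for spot labelling.
#' @param alpha Significance threshold on BH-adjusted q-values.
#' @param min_detect_frac Detection filter before DE testing.
#' @param seed Master seed; overrides the seed inside `sim` so one
#'   integer controls the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bin_size = 50L, merge_gap = 500L,
                            seg_mode = c("hmm", "presence"),
                            strand_mode = c("specific", "ignore"),
                            quantile = 0.75, alpha = 0.05,
                            min_detect_frac = 0.05,
                            seed = NULL) {
  seg_mode <- match.arg(seg_mode)
  strand_mode <- match.arg(strand_mode)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (bin_size <= 0L || merge_gap < 0L)
    abort("bin_size must be positive and merge_gap non-negative")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (quantile < 0 || quantile >= 1) abort("quantile must lie in [0, 1)")
  structure(list(sim = sim, bin_size = as.integer(bin_size),
                 merge_gap = as.integer(merge_gap), seg_mode = seg_mode,
                 strand_mode = strand_mode, quantile = quantile,
                 alpha = alpha, min_detect_frac = min_detect_frac,
                 seed = sim$seed),
            class = "pipeline_config")
}

#' Run the full simulate-to-DE pipeline
#'
#' Chains every stage under one seed: simulation (genome, databases,
#' spots, counts, reads), SAM round trip, coverage binning, TAR calling
#' and merging, aTAR/uTAR classification, database labelling, spot
#' quantification and QC, normalisation, marker labelling, Wilcoxon DE
#' of all features, spatial concordance of significant uTARs with the
#' marker signature, and recovery evaluation against the planted truth.
#' All artefacts (GTF, BED, SAM, bedGraph, MTX triplet, TSV tables,
#' JSON metadata, structured JSON-lines log, optional spatial plots)
#' are written under `outdir`; identical configurations and seeds yield
#' byte-identical text artefacts.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created).
#' @param make_plots Write spatial PNG maps (signature score and top
#'   uTAR expression)?
#' @return Invisibly, a list bundle with every intermediate object
#'   (`truth`, `tars`, `utars`, `spot_matrix`, `qc`, `de`,
#'   `concordance`, `recovery`, `report`, paths).
#' @export
run_pipeline <- function(config, outdir, make_plots = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      log_stage(stage, status = "error", message = conditionMessage(e))
      abort("pipeline stage '", stage, "' failed: ", conditionMessage(e))
    })
    log_stage(stage, status = "ok",
              elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }
  cfg <- config$sim

  sim <- run_stage("simulate", {
    g <- make_genome(cfg)
    db <- make_databases(g$loci, cfg)
    spots <- simulate_spots(cfg)
    counts <- simulate_counts(db$loci, spots, cfg)
    reads <- fragment_and_place_reads(counts, db$loci, cfg)
    list(genome = g$genome, loci = db$loci, db1 = db$db1, db2 = db$db2,
         spots = spots, counts = counts, reads = reads)
  })
  truth <- sim$loci
  write_tsv(sim$genome, file.path(outdir, "genome.tsv"))
  write_tsv(truth, file.path(outdir, "truth_loci.tsv"))
  write_tsv(sim$spots, file.path(outdir, "spots.tsv"))
  write_gtf(truth, file.path(outdir, "annotation.gtf"))
  write_bed6(sim$db1, file.path(outdir, "lnc_db1.bed"))
  write_bed6(sim$db2, file.path(outdir, "lnc_db2.bed"))
  sam_path <- file.path(outdir, "reads.sorted.sam")
  write_sam(sim$reads, sim$genome, file.path(outdir, "reads.sam"))
  write_sam(sim$reads, sim$genome, sam_path, sorted = TRUE)

  reads <- run_stage("read_sam", read_sam(sam_path))
  tracks <- run_stage("bin", bin_reads(reads, sim$genome,
                                       bin_size = config$bin_size))
  binned_total <- sum(vapply(tracks, function(t) sum(t$counts), 0))
  log_stage("conservation", check = "binned_counts_equal_reads",
            pass = binned_total == nrow(reads),
            binned = binned_total, reads = nrow(reads))

  tars <- run_stage("call_tars",
                    call_tars(tracks, mode = config$seg_mode,
                              max_gap = config$merge_gap))
  annotation <- truth[truth$annotated,
                      c("id", "contig", "start", "end", "strand")]
  tars <- run_stage("classify", classify_tars(
    tars, annotation, strand_mode = config$strand_mode))
  utars <- tars[tars$class == "uTAR", , drop = FALSE]
  utars <- run_stage("db_overlap",
                     overlap_databases(utars, sim$db1, sim$db2))
  tars$db_label[tars$class == "uTAR"] <- utars$db_label
  report <- classification_report(tars)
  tar_out <- cbind(tars,
                   name = sprintf("TAR%05d", seq_len(nrow(tars))))
  write_tsv(tar_out, file.path(outdir, "tars.tsv"))
  write_bed6(data.frame(tars[, c("contig", "start", "end", "strand")],
                        name = tar_out$name,
                        score = round(tars$mean_cov)),
             file.path(outdir, "tars.bed"))
  write_bedgraph(tracks, file.path(outdir, "coverage"))

  features <- rbind(
    data.frame(id = annotation$id, kind = "gene",
               annotation[, c("contig", "start", "end", "strand")]),
    if (nrow(utars)) data.frame(
      id = sprintf("uTAR%04d", seq_len(nrow(utars))), kind = "uTAR",
      utars[, c("contig", "start", "end", "strand")])
  )
  sm <- run_stage("quantify",
                  count_features_per_spot(reads, features, sim$spots))
  log_stage("conservation", check = "read_assignment_partition",
            pass = sum(unlist(sm$tally)) == nrow(reads),
            tally = sm$tally, reads = nrow(reads))
  qc <- run_stage("qc", qc_metrics(sm))
  write_spot_matrix(sm, file.path(outdir, "matrix"))
  write_tsv(qc$per_spot, file.path(outdir, "qc_per_spot.tsv"))

  norm <- run_stage("normalize", lognormalize(sm))
  markers <- truth$id[truth$role == "marker_kerat"]
  scores <- run_stage("signature", signature_score(norm, markers))
  labels <- label_spots(scores, config$quantile)
  write_tsv(data.frame(barcode = colnames(norm), score = scores,
                       labeled = labels),
            file.path(outdir, "spot_labels.tsv"))

  de <- run_stage("de", wilcoxon_de(norm, labels,
                                    min_detect_frac = config$min_detect_frac))
  de$kind <- sm$features$kind[match(de$feature, sm$features$id)]
  write_tsv(de, file.path(outdir, "de_results.tsv"))

  sig_utars <- de$feature[de$kind == "uTAR" & de$q < config$alpha]
  concordance <- do.call(rbind, lapply(sig_utars, function(f) {
    sc <- spatial_concordance(scores, as.numeric(norm[f, ]))
    data.frame(feature = f, rho = sc$rho, p = sc$p, n = sc$n,
               ok = sc$ok)
  }))
  if (is.null(concordance))
    concordance <- data.frame(feature = character(0), rho = numeric(0),
                              p = numeric(0), n = integer(0),
                              ok = logical(0))
  write_tsv(concordance, file.path(outdir, "concordance.tsv"))

  utar_features <- cbind(
    sm$features[sm$features$kind == "uTAR", , drop = FALSE],
    db_label = utars$db_label)
  recovery <- run_stage("recovery", recovery_eval(
    utar_features, de, truth, alpha = config$alpha))
  jsonlite::write_json(recovery[setdiff(names(recovery), "matches")],
                       file.path(outdir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(package = "utarscan",
         version = as.character(utils::packageVersion("utarscan")),
         seed = config$seed,
         config = unclass_deep(config)),
    file.path(outdir, "metadata.json"), auto_unbox = TRUE, digits = NA)

  if (make_plots) {
    plot_spot_map(sim$spots, scores, "signature score",
                  file.path(outdir, "plot_signature.png"))
    if (length(sig_utars)) {
      v <- as.numeric(norm[sig_utars[1], ])
      plot_spot_map(sim$spots, v, paste("uTAR", sig_utars[1]),
                    file.path(outdir, "plot_top_utar.png"))
    }
  }

  invisible(list(config = config, genome = sim$genome, truth = truth,
                 spots = sim$spots, reads = reads, tracks = tracks,
                 tars = tars, utars = utars, report = report,
                 spot_matrix = sm, qc = qc, norm = norm,
                 scores = scores, labels = labels, de = de,
                 concordance = concordance, recovery = recovery,
                 outdir = outdir))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

plot_spot_map <- function(spots, values, title, path) {
  df <- data.frame(x = spots$x, y = spots$y, value = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  invisible(path)
}

#' Evaluate uTAR recovery against simulation truth
#'
#' A called uTAR matches a planted unannotated locus iff their
#' strand-matched overlap covers at least half of the planted locus
#' length (an evaluation convention, not a biological claim). Reports
#' calling precision and recall over that match set, the agreement of
#' called database labels with the planted membership flags, and the
#' confusion between planted cell-type effects and DE calls at
#' q < `alpha`.
#'
#' @param utar_features data.frame of called uTAR features (`id`,
#'   `contig`, `start`, `end`, `strand`, optional `db_label`).
#' @param de_results DE table from [wilcoxon_de()] (may be `NULL` to
#'   skip the DE confusion).
#' @param truth Simulation truth table.
#' @param alpha Significance threshold on q.
#' @return List with `n_truth`, `n_called`, `precision`, `recall`,
#'   `empty_called` flag, `db_label_agreement` (fraction over matched
#'   pairs), `db_confusion` (expected vs called label table),
#'   `de_confusion` (tp/fp/fn/tn over uTARs) and `matches`.
#' @export
recovery_eval <- function(utar_features, de_results, truth,
                          alpha = 0.05) {
  tl <- truth[!truth$annotated, , drop = FALSE]
  n_truth <- nrow(tl)
  n_called <- nrow(utar_features)
  expected_label <- with(tl, ifelse(in_db1 & in_db2, "both",
                                    ifelse(in_db1, "db1",
                                           ifelse(in_db2, "db2", "novel"))))

  if (n_called == 0L) {
    return(list(n_truth = n_truth, n_called = 0L, precision = 0,
                recall = 0, empty_called = TRUE,
                db_label_agreement = NaN, db_confusion = NULL,
                de_confusion = NULL,
                matches = data.frame(truth_id = character(0),
                                     utar_id = character(0))))
  }

  hits <- GenomicRanges::findOverlaps(gr0(utar_features), gr0(tl))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(utar_features$end[q], tl$end[s]) -
    pmax(utar_features$start[q], tl$start[s])
  good <- ov >= 0.5 * (tl$end[s] - tl$start[s])
  q <- q[good]; s <- s[good]; ov <- ov[good]

  # each truth locus keeps its best-covering uTAR
  o <- order(s, -ov)
  keep <- !duplicated(s[o])
  m_q <- q[o][keep]; m_s <- s[o][keep]
  matches <- data.frame(truth_id = tl$id[m_s],
                        utar_id = utar_features$id[m_q],
                        stringsAsFactors = FALSE)

  precision <- length(unique(q)) / n_called
  recall <- length(unique(s)) / max(n_truth, 1L)

  db_agree <- NaN; db_conf <- NULL
  if (!is.null(utar_features$db_label) && nrow(matches)) {
    called_lab <- utar_features$db_label[m_q]
    exp_lab <- expected_label[m_s]
    db_agree <- mean(called_lab == exp_lab)
    db_conf <- as.data.frame(table(expected = exp_lab,
                                   called = called_lab))
  }

  de_conf <- NULL
  if (!is.null(de_results)) {
    de_u <- de_results[de_results$feature %in% utar_features$id, ,
                       drop = FALSE]
    sig <- de_u$feature[de_u$q < alpha]
    truth_de <- tl$id[tl$effect_keratinocyte_like != tl$effect_other]
    called_de_truth <- matches$truth_id[matches$utar_id %in% sig]
    # uTARs significant but not matched to any planted DE locus are
    # false positives (spurious or matched to a null locus)
    sig_matched_de <- matches$utar_id[matches$truth_id %in% truth_de &
                                        matches$utar_id %in% sig]
    de_conf <- list(
      tp = length(intersect(called_de_truth, truth_de)),
      fn = length(setdiff(truth_de, called_de_truth)),
      fp = length(setdiff(sig, sig_matched_de)),
      tn = length(setdiff(de_u$feature, union(sig, matches$utar_id[
        matches$truth_id %in% truth_de]))),
      n_sig_utars = length(sig))
  }

  list(n_truth = n_truth, n_called = n_called,
       precision = precision, recall = recall, empty_called = FALSE,
       db_label_agreement = db_agree, db_confusion = db_conf,
       de_confusion = de_conf, matches = matches)
}
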