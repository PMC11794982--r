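#' Generate a synthetic genome with planted transcribed loci
#'
#' Places `n_genes` annotated gene loci and `n_lnc` unannotated lncRNA
#' loci uniformly at random on a small multi-contig genome, subject to a
#' minimum same-strand gap so that downstream merging (500-bp rule) can
#' never fuse two distinct truth loci. Locus lengths are uniform over
#' `locus_len_range`. Expression roles are assigned here as well: per
#' cell-type programme (`keratinocyte_like`, `other`), `n_marker_genes`
#' genes and half of the `n_de_lnc` unannotated loci receive an
#' `effect_size`-fold elevation in that programme's domain. The two
#' programmes are sized identically so that expected library sizes are
#' balanced across domains and library-size normalisation does not
#' induce compositional artefacts in null features.
#'
#' All coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (data.frame: `contig`, `length`) and
#'   `loci` (the truth table: one row per planted locus with interval,
#'   strand, `annotated`, `role`, NB parameters, per-domain fold
#'   multipliers `effect_keratinocyte_like` / `effect_other`, and
#'   database flags `in_db1` / `in_db2`, initially `FALSE` until
#'   [make_databases()] is run).
#' @export
make_genome <- function(config) {
  validate_sim_config(config)
  genome <- data.frame(
    contig = sprintf("ctg%02d", seq_len(config$n_contigs)),
    length = rep(config$contig_length, config$n_contigs),
    stringsAsFactors = FALSE
  )
  n <- config$n_genes + config$n_lnc
  if (n == 0L) {
    return(list(genome = genome, loci = empty_truth()))
  }

  withr::with_seed(derive_seed(config$seed, "genome"), {
    lens <- sample(config$locus_len_range[1]:config$locus_len_range[2],
                   n, replace = TRUE)
    contig <- character(n); start <- integer(n); strand <- character(n)
    placed <- data.frame(contig = character(0), strand = character(0),
                         start = integer(0), end = integer(0))
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample.int(config$n_contigs, 1L)
        st <- sample(c("+", "-"), 1L)
        s <- sample.int(config$contig_length - lens[i] + 1L, 1L) - 1L
        e <- s + lens[i]
        same <- placed[placed$contig == genome$contig[ci] &
                         placed$strand == st, , drop = FALSE]
        if (nrow(same) == 0L ||
            all(s - same$end >= config$min_gap |
                  same$start - e >= config$min_gap)) {
          contig[i] <- genome$contig[ci]; start[i] <- s; strand[i] <- st
          placed <- rbind(placed, data.frame(
            contig = genome$contig[ci], strand = st, start = s, end = e))
          ok <- TRUE
          break
        }
      }
      if (!ok)
        abort("could not place locus ", i, " after 500 attempts; ",
              "the genome is too small for the requested loci and min_gap")
    }

    annotated <- rep(c(TRUE, FALSE), c(config$n_genes, config$n_lnc))
    id <- character(n)
    id[annotated] <- sprintf("GENE%03d", seq_len(config$n_genes))
    id[!annotated] <- sprintf("LNC%03d", seq_len(config$n_lnc))

    role <- rep("null", n)
    gene_idx <- which(annotated)
    if (config$n_marker_genes > 0L && config$n_genes > 0L) {
      mk <- sample(gene_idx, 2L * config$n_marker_genes)
      role[mk[seq_len(config$n_marker_genes)]] <- "marker_kerat"
      role[mk[-seq_len(config$n_marker_genes)]] <- "marker_other"
    }
    lnc_idx <- which(!annotated)
    if (config$n_de_lnc > 0L && config$n_lnc > 0L) {
      de <- sample(lnc_idx, config$n_de_lnc)
      n_k <- ceiling(config$n_de_lnc / 2)
      role[de[seq_len(n_k)]] <- "de_lnc_kerat"
      if (config$n_de_lnc > n_k) role[de[-seq_len(n_k)]] <- "de_lnc_other"
    }
  })

  eff_k <- ifelse(role %in% c("marker_kerat", "de_lnc_kerat"),
                  config$effect_size, 1)
  eff_o <- ifelse(role %in% c("marker_other", "de_lnc_other"),
                  config$effect_size, 1)

  loci <- data.frame(
    id = id, contig = contig, start = start, end = start + lens,
    strand = strand, annotated = annotated, role = role,
    base_mean = config$base_mean, dispersion = config$dispersion,
    effect_keratinocyte_like = eff_k, effect_other = eff_o,
    in_db1 = FALSE, in_db2 = FALSE, stringsAsFactors = FALSE
  )
  loci <- loci[order(loci$contig, loci$start), ]
  rownames(loci) <- NULL
  list(genome = genome, loci = loci)
}

empty_truth <- function() {
  data.frame(id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             annotated = logical(0), role = character(0),
             base_mean = numeric(0), dispersion = numeric(0),
             effect_keratinocyte_like = numeric(0),
             effect_other = numeric(0),
             in_db1 = logical(0), in_db2 = logical(0))
}

#' Build simulated lncRNA reference databases
#'
#' Deposits a seed-chosen fraction of the unannotated truth loci into
#' each of two stranded interval databases (emulating two independent
#' lncRNA catalogues). Membership flags are written back into the truth
#' table; database intervals are the exact planted intervals.
#'
#' @param loci Truth table from [make_genome()].
#' @param config A [sim_config()]; `db1_frac`/`db2_frac` give the
#'   fraction of unannotated loci placed in each database
#'   (`round(frac * n_lnc)` loci).
#' @return List with `loci` (flags updated) and `db1`, `db2`
#'   (data.frames: `contig`, `start`, `end`, `strand`, `name`).
#' @export
make_databases <- function(loci, config) {
  lnc <- which(!loci$annotated)
  pick <- function(frac, label) {
    k <- round(frac * length(lnc))
    if (k == 0L) return(integer(0))
    withr::with_seed(derive_seed(config$seed, label),
                     sample(lnc, k))
  }
  i1 <- pick(config$db1_frac, "db1")
  i2 <- pick(config$db2_frac, "db2")
  loci$in_db1 <- seq_len(nrow(loci)) %in% i1
  loci$in_db2 <- seq_len(nrow(loci)) %in% i2
  as_db <- function(idx) {
    d <- loci[sort(idx), c("contig", "start", "end", "strand", "id")]
    names(d)[5] <- "name"
    rownames(d) <- NULL
    d
  }
  list(loci = loci, db1 = as_db(i1), db2 = as_db(i2))
}
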