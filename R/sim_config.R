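#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults define the package's reference study conditions: a small
#' three-contig genome carrying 40 annotated genes and 20 unannotated
#' lncRNA loci, a 200-spot array with a keratinocyte-like band occupying
#' roughly a fifth of the tissue, negative-binomial expression
#' (mean/size parameterisation: `dispersion` is the NB *size*), two
#' balanced fold-8 cell-type programmes, and a fragment-length
#' degradation model with mean 500 bases.
#'
#' @param seed Integer master seed; every stochastic operation derives
#'   its own stream from it via [derive_seed()].
#' @param n_genes,n_lnc Number of annotated genes / unannotated lncRNA
#'   loci planted in the genome.
#' @param n_contigs,contig_length Genome shape: `n_contigs` contigs of
#'   `contig_length` bases each.
#' @param min_gap Minimum same-strand gap between planted loci, in
#'   bases. Must exceed the TAR merge gap (500) so that merging can
#'   never fuse two distinct truth loci.
#' @param locus_len_range Length range (bases) loci are drawn from,
#'   uniformly.
#' @param n_spots Number of spots; must admit a near-square rectangular
#'   grid (i.e. not prime).
#' @param domain_frac Fraction of the grid, split by a vertical line,
#'   assigned the `keratinocyte_like` domain before label noise.
#' @param flip_noise Probability that a spot's domain label is flipped,
#'   emulating a ragged histological boundary.
#' @param capture_mode `"probe"` (uniform read placement within the
#'   transcript, emulating hybridisation-probe capture) or `"polyA"`
#'   (reads biased toward the transcript 3' end, emulating oligo-dT
#'   capture of degraded RNA).
#' @param degradation Mean RNA fragment length in bases; smaller values
#'   mean more degraded RNA and a lower DV200.
#' @param read_len Read length cap in bases.
#' @param reads_per_count Reads emitted per true count unit.
#' @param db1_frac,db2_frac Fractions of unannotated loci deposited in
#'   each of the two simulated lncRNA databases.
#' @param base_mean Expected counts per spot per locus in a locus's
#'   baseline cell type.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param effect_size Fold change applied to programme loci in their
#'   high cell type.
#' @param n_marker_genes Genes per cell-type programme (two programmes:
#'   keratinocyte-like and other) acting as markers.
#' @param n_de_lnc Unannotated loci carrying a planted cell-type effect,
#'   split as evenly as possible between the two programmes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L, n_lnc = 20L,
                       n_contigs = 3L, contig_length = 300000L,
                       min_gap = 2000L,
                       locus_len_range = c(1000L, 10000L),
                       n_spots = 200L,
                       domain_frac = 0.2, flip_noise = 0.05,
                       capture_mode = c("probe", "polyA"),
                       degradation = 500, read_len = 50L,
                       reads_per_count = 1L,
                       db1_frac = 0.6, db2_frac = 0.5,
                       base_mean = 2, dispersion = 2,
                       effect_size = 8,
                       n_marker_genes = 5L, n_de_lnc = 6L) {
  capture_mode <- match.arg(capture_mode)
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_lnc = as.integer(n_lnc), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    min_gap = as.integer(min_gap),
    locus_len_range = as.integer(locus_len_range),
    n_spots = as.integer(n_spots), domain_frac = domain_frac,
    flip_noise = flip_noise, capture_mode = capture_mode,
    degradation = degradation, read_len = as.integer(read_len),
    reads_per_count = as.integer(reads_per_count),
    db1_frac = db1_frac, db2_frac = db2_frac,
    base_mean = base_mean, dispersion = dispersion,
    effect_size = effect_size,
    n_marker_genes = as.integer(n_marker_genes),
    n_de_lnc = as.integer(n_de_lnc)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (min_gap <= 500L)
      abort("min_gap must exceed the 500-bp TAR merge gap")
    if (n_genes < 0L || n_lnc < 0L || n_spots < 1L)
      abort("counts must be non-negative (n_spots >= 1)")
    if (any(c(db1_frac, db2_frac) < 0) || any(c(db1_frac, db2_frac) > 1))
      abort("database fractions must lie in [0, 1]")
    if (domain_frac <= 0 || domain_frac >= 1)
      abort("domain_frac must lie in (0, 1)")
    if (flip_noise < 0 || flip_noise > 1)
      abort("flip_noise must lie in [0, 1]")
    if (degradation <= 0) abort("degradation must be positive")
    if (dispersion <= 0) abort("dispersion must be positive")
    if (base_mean < 0) abort("base_mean must be non-negative")
    if (effect_size <= 0) abort("effect_size must be positive")
    if (locus_len_range[1] < 100L || diff(locus_len_range) < 0L)
      abort("locus_len_range must be increasing and >= 100 bases")
    if (n_marker_genes * 2L > n_genes)
      abort("two marker programmes cannot exceed n_genes")
    if (n_de_lnc > n_lnc)
      abort("n_de_lnc cannot exceed n_lnc")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d genes + %d lncRNA loci on %d x %d-bp contigs;",
              x$n_genes, x$n_lnc, x$n_contigs, x$contig_length),
      sprintf("%d spots (%s capture, mean fragment %g bp); seed %d\n",
              x$n_spots, x$capture_mode, x$degradation, x$seed))
  invisible(x)
}

#' Read a pipeline/simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()] and [pipeline_config()];
#' unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- unique(c(names(formals(sim_config)),
                    names(formals(pipeline_config))))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort("unknown configuration keys: ", paste(bad, collapse = ", "))
  sim_keys <- intersect(names(vals), names(formals(sim_config)))
  pipe_keys <- setdiff(names(vals), setdiff(sim_keys, "seed"))
  sim <- do.call(sim_config, vals[sim_keys])
  do.call(pipeline_config, c(list(sim = sim), vals[setdiff(pipe_keys, sim_keys)]))
}
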