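#' Fragment transcripts and place spot-barcoded reads
#'
#' Converts the true count table into individual read placements. Each
#' count unit yields `reads_per_count` reads from its origin locus. An
#' RNA fragment length is drawn from an exponential distribution with
#' mean `degradation` (the degradation model: more degraded RNA = a
#' smaller mean), truncated to `[30, locus length]`. The read length is
#' `min(fragment_length, read_len)`. Placement depends on capture mode:
#'
#' * `polyA`: the read's 3' end sits at an exponential(`degradation`)
#'   distance from the locus 3' end (truncated to fit), emulating
#'   oligo-dT capture where degraded fragments keep only the 3' tail.
#' * `probe`: the read start is uniform within the locus, emulating
#'   hybridisation probes tiled along the transcript.
#'
#' Reads always lie within their origin locus, on its strand, and carry
#' the originating spot barcode.
#'
#' @param counts Integer matrix from [simulate_counts()].
#' @param loci Truth table from [make_genome()].
#' @param config A [sim_config()].
#' @return data.frame of reads: `contig`, `start`, `length`, `strand`
#'   (0-based half-open interval `[start, start + length)`), `barcode`,
#'   `origin` (truth locus id), `fragment_length`.
#' @export
fragment_and_place_reads <- function(counts, loci, config) {
  stopifnot(nrow(counts) == nrow(loci))
  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_reads())
  times <- counts[idx] * config$reads_per_count
  li <- rep(idx[, 1], times)
  bc <- rep(colnames(counts)[idx[, 2]], times)
  n <- length(li)

  L <- loci$end[li] - loci$start[li]
  withr::with_seed(derive_seed(config$seed, "reads"), {
    frag <- pmin(pmax(round(rexp(n, rate = 1 / config$degradation)), 30L), L)
    rl <- pmin(frag, config$read_len)
    if (config$capture_mode == "polyA") {
      d3 <- pmin(round(rexp(n, rate = 1 / config$degradation)), L - rl)
      start <- ifelse(loci$strand[li] == "+",
                      loci$end[li] - d3 - rl,    # 3' end at end - d3
                      loci$start[li] + d3)       # 3' end at start + d3
    } else {
      start <- loci$start[li] + floor(runif(n) * (L - rl + 1))
    }
  })

  data.frame(
    contig = loci$contig[li],
    start = as.integer(start),
    length = as.integer(rl),
    strand = loci$strand[li],
    barcode = bc,
    origin = loci$id[li],
    fragment_length = as.integer(frag),
    stringsAsFactors = FALSE
  )
}

empty_reads <- function() {
  data.frame(contig = character(0), start = integer(0),
             length = integer(0), strand = character(0),
             barcode = character(0), origin = character(0),
             fragment_length = integer(0))
}

#' DV200 RNA-quality metric
#'
#' The percentage of RNA fragments strictly longer than 200 bases. DV200
#' is the standard electrophoresis-based quality score for FFPE RNA;
#' values of at least 30% are conventionally considered acceptable for
#' sequencing.
#'
#' @param fragment_lengths Numeric vector of fragment lengths in bases.
#' @return Percentage in `[0, 100]`.
#' @examples
#' dv200(c(100, 150, 250, 300)) # 50
#' @export
dv200 <- function(fragment_lengths) {
  if (length(fragment_lengths) == 0L)
    abort("dv200 requires at least one fragment length")
  if (any(!is.finite(fragment_lengths)) || any(fragment_lengths <= 0))
    abort("fragment lengths must be positive and finite")
  100 * mean(fragment_lengths > 200)
}
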