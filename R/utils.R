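#' Derive a reproducible per-stage seed from a master seed
#'
#' Each pipeline stage draws its random numbers under a seed derived from
#' the master seed and the stage label, so that stages are independently
#' reproducible and inserting a stage never perturbs the randomness of a
#' later one. The derivation is a fixed integer hash kept inside the
#' 32-bit signed range.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

# Internal: 0-based half-open data.frame -> GRanges (1-based closed).
# All genomic interval queries go through GenomicRanges; the package's
# own tables stay 0-based half-open and convert only here and at file
# boundaries.
gr0 <- function(df, keep = character(0)) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# Internal: stop() with a call-free message.
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("x", "y", "value"))
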