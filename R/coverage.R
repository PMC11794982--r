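#' Bin reads into fixed-width, strand-specific genome coverage
#'
#' Splits every contig into non-overlapping bins of `bin_size` bases
#' (default 50) and counts, per strand, the reads whose 5' end falls in
#' each bin. The 5' end is the leftmost aligned base for `+` reads and
#' the rightmost for `-` reads, so each read contributes exactly once
#' and total binned counts always equal the number of input reads. The
#' final partial bin at a contig end is retained.
#'
#' @param reads data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `strand`, e.g. from [read_sam()] or
#'   [fragment_and_place_reads()] (whose `start`+`length` imply `end`).
#' @param genome data.frame with `contig`, `length`.
#' @param bin_size Bin width in bases.
#' @param stranded Keep strands separate (`TRUE`, default) or pool all
#'   reads onto a single `*` track per contig.
#' @return A `binned_coverage_set`: a named list of tracks, each a
#'   `binned_coverage` list with `contig`, `strand`, `bin_size`,
#'   `contig_length` and integer `counts` (length
#'   `ceiling(contig_length / bin_size)`).
#' @export
bin_reads <- function(reads, genome, bin_size = 50L, stranded = TRUE) {
  if (bin_size <= 0L) abort("bin_size must be positive")
  if (!"end" %in% names(reads) && all(c("start", "length") %in% names(reads)))
    reads$end <- reads$start + reads$length
  unknown <- setdiff(unique(reads$contig), genome$contig)
  if (length(unknown))
    abort("reads reference contigs absent from the genome: ",
          paste(unknown, collapse = ", "))
  clen <- setNames(genome$length, genome$contig)
  if (nrow(reads)) {
    if (any(reads$start < 0) ||
        any(reads$end > clen[reads$contig]))
      abort("reads extend outside contig bounds")
  }

  pos5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  strands <- if (stranded) c("+", "-") else "*"
  rstrand <- if (stranded) reads$strand else rep("*", nrow(reads))

  tracks <- list()
  for (ctg in genome$contig) {
    n_bins <- as.integer(ceiling(clen[[ctg]] / bin_size))
    for (s in strands) {
      sel <- reads$contig == ctg & rstrand == s
      counts <- tabulate(pos5[sel] %/% bin_size + 1L, nbins = n_bins)
      tracks[[paste0(ctg, ":", s)]] <- structure(
        list(contig = ctg, strand = s, bin_size = as.integer(bin_size),
             contig_length = as.integer(clen[[ctg]]),
             counts = as.integer(counts)),
        class = "binned_coverage")
    }
  }
  structure(tracks, class = "binned_coverage_set")
}

#' Summarise a binned coverage track
#'
#' @param track A `binned_coverage` track from [bin_reads()].
#' @return List with `n_bins`, `n_nonzero`, `max_count`, `total`.
#' @export
coverage_summary <- function(track) {
  stopifnot(inherits(track, "binned_coverage"))
  list(n_bins = length(track$counts),
       n_nonzero = sum(track$counts > 0L),
       max_count = if (length(track$counts)) max(track$counts) else 0L,
       total = sum(track$counts))
}

#' @export
print.binned_coverage <- function(x, ...) {
  s <- coverage_summary(x)
  cat(sprintf(
    "binned_coverage %s(%s): %d bins of %d bp, %d nonzero, total %d\n",
    x$contig, x$strand, s$n_bins, x$bin_size, s$n_nonzero, s$total))
  invisible(x)
}

#' @export
print.binned_coverage_set <- function(x, ...) {
  cat("binned_coverage_set with", length(x), "tracks; total reads",
      sum(vapply(x, function(t) sum(t$counts), numeric(1))), "\n")
  invisible(x)
}
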