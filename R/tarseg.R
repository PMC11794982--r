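#' Presence-rule segmentation of a coverage track
#'
#' The literal reading of the calling rule: a bin is transcriptionally
#' active iff any read is detected in it.
#'
#' @param track A `binned_coverage` track.
#' @return Integer 0/1 vector, one element per bin.
#' @export
call_active_bins_presence <- function(track) {
  as.integer(track$counts > 0L)
}

#' Convert a decoded state vector into TAR intervals
#'
#' Maximal runs of state 1 become transcriptionally active regions with
#' bin-aligned genomic coordinates (the final TAR is closed at the
#' contig length when the last bin is partial), carrying the track's
#' strand and the mean bin count over the run.
#'
#' @param states Integer 0/1 vector (from [decode_states()] or
#'   [call_active_bins_presence()]), one element per bin of `track`.
#' @param track The `binned_coverage` track the states were decoded
#'   from.
#' @return data.frame of TARs: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `n_bins`, `mean_cov`, `class`, `db_label`
#'   (the last two `"unset"` until classification).
#' @export
states_to_tars <- function(states, track) {
  if (length(states) != length(track$counts))
    abort("states length must equal the number of bins in the track")
  r <- rle(states == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty_tars())
  bs <- track$bin_size
  data.frame(
    contig = track$contig,
    start = (starts[keep] - 1L) * bs,
    end = pmin(ends[keep] * bs, track$contig_length),
    strand = track$strand,
    n_bins = r$lengths[keep],
    mean_cov = vapply(keep, function(k) {
      mean(track$counts[starts[k]:ends[k]])
    }, numeric(1)),
    class = "unset", db_label = "unset",
    stringsAsFactors = FALSE
  )
}

empty_tars <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), n_bins = integer(0),
             mean_cov = numeric(0), class = character(0),
             db_label = character(0), stringsAsFactors = FALSE)
}

#' Merge nearby TARs
#'
#' Same-contig, same-strand TARs separated by no more than `max_gap`
#' bases (gap = next start - previous end; a gap of exactly `max_gap`
#' merges, `max_gap + 1` does not) are merged transitively into one
#' unit. The merged `mean_cov` is the bin-count-weighted mean of the
#' members and `n_bins` their sum.
#'
#' @param tars TAR data.frame (any row order).
#' @param max_gap Maximum gap in bases (default 500).
#' @return Merged TAR data.frame, sorted by contig, strand and start;
#'   consecutive same-strand output TARs are always more than `max_gap`
#'   apart. The operation is idempotent.
#' @export
merge_tars <- function(tars, max_gap = 500L) {
  if (nrow(tars) == 0L) return(tars)
  tars <- tars[order(tars$contig, tars$strand, tars$start, tars$end), ,
               drop = FALSE]
  key <- paste(tars$contig, tars$strand)
  out <- lapply(split(seq_len(nrow(tars)), key), function(idx) {
    t <- tars[idx, , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      t$start[-1L] - cummax(t$end)[-nrow(t)] > max_gap)))
    do.call(rbind, lapply(split(seq_len(nrow(t)), grp), function(j) {
      m <- t[j, , drop = FALSE]
      data.frame(
        contig = m$contig[1L], start = min(m$start), end = max(m$end),
        strand = m$strand[1L], n_bins = sum(m$n_bins),
        mean_cov = sum(m$mean_cov * m$n_bins) / sum(m$n_bins),
        class = "unset", db_label = "unset",
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call transcriptionally active regions from binned coverage
#'
#' Segments every track of a coverage set into TARs and merges nearby
#' ones. Two segmentation modes are available: `"hmm"` (default) fits a
#' single two-state Gaussian HMM on `log(count + 1)` bins pooled across
#' all tracks and Viterbi-decodes each track; `"presence"` applies the
#' literal any-read rule per bin.
#'
#' @param tracks A `binned_coverage_set` from [bin_reads()].
#' @param mode `"hmm"` or `"presence"`.
#' @param max_gap Merge gap in bases (default 500).
#' @param params Optional pre-fitted `hmm_params` (skips fitting).
#' @param ... Passed to [fit_hmm()].
#' @return Merged TAR data.frame; the fitted `hmm_params` (if any) are
#'   attached as attribute `"params"`.
#' @export
call_tars <- function(tracks, mode = c("hmm", "presence"),
                      max_gap = 500L, params = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "hmm" && is.null(params)) params <- fit_hmm(tracks, ...)
  tar_list <- lapply(tracks, function(tr) {
    states <- if (mode == "hmm") decode_states(tr, params)
              else call_active_bins_presence(tr)
    states_to_tars(states, tr)
  })
  tars <- merge_tars(do.call(rbind, c(tar_list, list(make.row.names = FALSE))),
                     max_gap = max_gap)
  attr(tars, "params") <- params
  tars
}
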