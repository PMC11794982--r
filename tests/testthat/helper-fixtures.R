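# Shared fixture builders and independent oracles. Oracles deliberately
# avoid the package's own code paths: enumeration, pairwise closure and
# dense recomputation from first principles.

make_track <- function(counts, contig = "ctgA", strand = "+",
                       bin_size = 50L,
                       contig_length = length(counts) * bin_size) {
  structure(list(contig = contig, strand = strand,
                 bin_size = as.integer(bin_size),
                 contig_length = as.integer(contig_length),
                 counts = as.integer(counts)),
            class = "binned_coverage")
}

make_tar <- function(contig, start, end, strand = "+", n_bins = NULL,
                     mean_cov = 1, class = "unset", db_label = "unset") {
  data.frame(contig = contig, start = start, end = end, strand = strand,
             n_bins = n_bins %||% pmax(1L, (end - start) %/% 50L),
             mean_cov = mean_cov, class = class, db_label = db_label,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive Viterbi oracle: scores every 2^n state path with the same
# left-to-right accumulation order the dynamic programme uses and keeps
# the first maximum in colexicographic path order. Returns the best
# path, its score, and whether the maximum was attained uniquely.
enum_viterbi <- function(logpi, logA, logB) {
  n <- nrow(logB)
  K <- 2L^n
  k <- 0:(K - 1)
  paths <- sapply(0:(n - 1), function(b) bitwAnd(bitwShiftR(k, b), 1L))
  if (n == 1L) paths <- matrix(paths, ncol = 1L)
  score <- logpi[paths[, 1] + 1L] + logB[1L, paths[, 1] + 1L]
  if (n > 1L) for (t in 2:n) {
    score <- (score + logA[cbind(paths[, t - 1] + 1L, paths[, t] + 1L)]) +
      logB[t, paths[, t] + 1L]
  }
  best <- which.max(score)   # first max = colex-smallest maximiser
  list(path = paths[best, ], score = score[best],
       unique = sum(score == score[best]) == 1L)
}

path_logdens <- function(x, mu, s2) {
  cbind(dnorm(x, mu[1], sqrt(s2[1]), log = TRUE),
        dnorm(x, mu[2], sqrt(s2[2]), log = TRUE))
}

# Brute-force transitive-closure merge oracle: repeatedly merges any
# same-contig same-strand pair within the gap until a fixpoint.
merge_oracle <- function(tars, max_gap = 500L) {
  iv <- tars[, c("contig", "start", "end", "strand")]
  repeat {
    merged <- FALSE
    n <- nrow(iv)
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i >= j) next
        if (iv$contig[i] != iv$contig[j] || iv$strand[i] != iv$strand[j])
          next
        gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
        if (gap <= max_gap) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv <- iv[order(iv$contig, iv$strand, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

# Step-up BH recomputation from the definition:
# q_(i) = min(1, min_{j >= i} p_(j) * m / j) in sorted order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  q
}

# A tiny deterministic read table spanning two contigs and both strands.
tiny_genome <- data.frame(contig = c("ctgA", "ctgB"),
                          length = c(1000L, 600L))
tiny_reads <- function() {
  data.frame(
    contig = c("ctgA", "ctgA", "ctgA", "ctgB"),
    start = c(0L, 120L, 100L, 580L),
    end = c(50L, 170L, 150L, 600L),
    strand = c("+", "+", "-", "+"),
    barcode = c("BC1", "BC1", "BC2", "BC2"),
    origin = c("L1", "L1", "L2", "L3"),
    stringsAsFactors = FALSE)
}

default_cfg <- function(seed = 1L, ...) sim_config(seed = seed, ...)
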