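#' Count features per spot from barcoded reads
#'
#' Assigns each read to at most one feature (gene or uTAR) by
#' strand-matched overlap of its 5' end position; when the position
#' falls in several same-strand features, the feature with the longest
#' overlap with the full read wins, and exact ties are discarded as
#' ambiguous. Reads whose barcode is not in the spot layout are tallied
#' as off-tissue and excluded from the matrix. The tallies always
#' satisfy `assigned + unassigned + ambiguous + off_tissue = input
#' reads`.
#'
#' @param reads data.frame with `contig`, `start`, `end` (or `length`),
#'   `strand`, `barcode`.
#' @param features data.frame with `id`, `kind` (`"gene"`/`"uTAR"`),
#'   `contig`, `start`, `end`, `strand` (0-based half-open).
#' @param spots Spot layout data.frame (`barcode`, `x`, `y`, ...).
#' @return A `spot_matrix`: list with `counts` (sparse integer
#'   features x barcodes matrix), `features`, `barcodes`, `coords`
#'   (the spot layout) and `tally` (assigned / unassigned / ambiguous /
#'   off_tissue).
#' @export
count_features_per_spot <- function(reads, features, spots) {
  if (anyDuplicated(features$id))
    abort("feature ids must be unique")
  if (anyDuplicated(spots$barcode))
    abort("spot barcodes must be unique")
  if (!"end" %in% names(reads) && all(c("start", "length") %in% names(reads)))
    reads$end <- reads$start + reads$length
  n <- nrow(reads)
  tally <- c(assigned = 0L, unassigned = 0L, ambiguous = 0L,
             off_tissue = 0L)

  on_tissue <- reads$barcode %in% spots$barcode
  tally[["off_tissue"]] <- sum(!on_tissue)
  r <- reads[on_tissue, , drop = FALSE]

  fi <- integer(0); bj <- integer(0)
  if (nrow(r) && nrow(features)) {
    pos5 <- ifelse(r$strand == "+", r$start, r$end - 1L)
    p5 <- data.frame(contig = r$contig, start = pos5, end = pos5 + 1L,
                     strand = r$strand)
    hits <- GenomicRanges::findOverlaps(gr0(p5), gr0(features))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(r$end[q], features$end[s]) -
      pmax(r$start[q], features$start[s])
    assign <- rep(NA_integer_, nrow(r))
    ambiguous <- rep(FALSE, nrow(r))
    if (length(q)) {
      o <- order(q, -ov)
      q <- q[o]; s <- s[o]; ov <- ov[o]
      first <- which(!duplicated(q))
      assign[q[first]] <- s[first]
      # ambiguous when the runner-up candidate ties the best overlap
      second <- first + 1L
      has2 <- second <= length(q) & q[pmin(second, length(q))] == q[first]
      tied <- q[first[has2][ov[second[has2]] == ov[first[has2]]]]
      if (length(tied)) {
        ambiguous[tied] <- TRUE
        assign[tied] <- NA_integer_
      }
    }
    ok <- !is.na(assign)
    tally[["assigned"]] <- sum(ok)
    tally[["ambiguous"]] <- sum(ambiguous)
    tally[["unassigned"]] <- nrow(r) - sum(ok) - sum(ambiguous)
    fi <- assign[ok]
    bj <- match(r$barcode[ok], spots$barcode)
  } else {
    tally[["unassigned"]] <- nrow(r)
  }

  counts <- Matrix::sparseMatrix(
    i = fi, j = bj, x = rep(1L, length(fi)),
    dims = c(nrow(features), nrow(spots)),
    dimnames = list(features$id, spots$barcode))
  structure(list(counts = counts, features = features,
                 barcodes = spots$barcode, coords = spots,
                 tally = as.list(tally)),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d features x %d spots, %d assigned reads\n",
              nrow(x$counts), ncol(x$counts), x$tally$assigned))
  invisible(x)
}

#' Per-spot and per-sample QC metrics
#'
#' Reads per spot (column sums), features detected per spot (nonzero
#' entries per column), total features detected in the sample (rows
#' with any nonzero count) and the median features per spot.
#'
#' @param sm A `spot_matrix`.
#' @return List with `per_spot` (data.frame: `barcode`, `reads`,
#'   `features_detected`) and `per_sample` (list: `total_features`,
#'   `median_features_per_spot`, `total_reads`).
#' @export
qc_metrics <- function(sm) {
  m <- sm$counts
  per_spot <- data.frame(
    barcode = colnames(m),
    reads = Matrix::colSums(m),
    features_detected = Matrix::colSums(m > 0),
    stringsAsFactors = FALSE)
  rownames(per_spot) <- NULL
  list(per_spot = per_spot,
       per_sample = list(
         total_features = sum(Matrix::rowSums(m) > 0),
         median_features_per_spot = median(per_spot$features_detected),
         total_reads = sum(per_spot$reads)))
}

#' Library-size log-normalisation
#'
#' `value = log(1 + count * scale / spot_total)` with `scale` the
#' median spot total: a simple median-scaling log1p normalisation (the
#' package's stand-in for smoothing-based spatial normalisations, which
#' are out of scope). Zero-total spots are excluded with a warning
#' naming their barcodes.
#'
#' @param m A `spot_matrix`, or a (sparse) features x spots count
#'   matrix.
#' @return Sparse normalised matrix (zero-total spots dropped), with
#'   attribute `scale`.
#' @export
lognormalize <- function(m) {
  if (inherits(m, "spot_matrix")) m <- m$counts
  m <- methods::as(m, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (all(totals == 0)) abort("all spots have zero total counts")
  if (any(totals == 0)) {
    warning("excluding zero-total spots: ",
            paste(colnames(m)[totals == 0], collapse = ", "),
            call. = FALSE)
    m <- m[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  scale <- median(totals)
  out <- m
  out@x <- log1p(m@x * scale / rep(totals, diff(m@p)))
  attr(out, "scale") <- scale
  out
}

#' Write a spot matrix as a MatrixMarket triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv` (`id`, `kind`, `locus` as
#' `contig:start-end:strand`), `barcodes.tsv` and `positions.tsv`
#' (`barcode`, `x`, `y` and any further layout columns), the 10x-style
#' layout.
#'
#' @param sm A `spot_matrix`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(sm$counts, file.path(dir, "matrix.mtx"))
  f <- sm$features
  write_tsv(data.frame(
    id = f$id, kind = f$kind,
    locus = sprintf("%s:%d-%d:%s", f$contig, f$start, f$end, f$strand)),
    file.path(dir, "features.tsv"))
  writeLines(sm$barcodes, file.path(dir, "barcodes.tsv"))
  write_tsv(sm$coords, file.path(dir, "positions.tsv"))
  invisible(dir)
}

#' Read a spot matrix written by [write_spot_matrix()]
#'
#' Integer counts round-trip exactly.
#'
#' @param dir Directory containing the triplet files.
#' @return A `spot_matrix`.
#' @export
read_spot_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  ftab <- read_tsv(file.path(dir, "features.tsv"))
  parts <- regmatches(ftab$locus,
                      regexec("^(.+):(\\d+)-(\\d+):([+-])$", ftab$locus))
  features <- data.frame(
    id = ftab$id, kind = ftab$kind,
    contig = vapply(parts, `[`, "", 2L),
    start = as.integer(vapply(parts, `[`, "", 3L)),
    end = as.integer(vapply(parts, `[`, "", 4L)),
    strand = vapply(parts, `[`, "", 5L),
    stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  coords <- read_tsv(file.path(dir, "positions.tsv"))
  dimnames(m) <- list(features$id, barcodes)
  structure(list(counts = m, features = features, barcodes = barcodes,
                 coords = coords,
                 tally = list(assigned = sum(m), unassigned = NA,
                              ambiguous = NA, off_tissue = NA)),
            class = "spot_matrix")
}
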