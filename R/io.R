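#' Write simulated reads as a minimal SAM file
#'
#' Emits the mandatory 11 SAM fields plus `CB:Z:` (spot barcode) and
#' `XT:Z:` (origin truth locus) tags. Sequence and quality are `*`
#' (the simulator is coordinate-level, not nucleotide-level); the CIGAR
#' is a single match run of the read length. Coordinates convert from
#' the internal 0-based half-open convention to SAM's 1-based at this
#' boundary.
#'
#' @param reads data.frame from [fragment_and_place_reads()].
#' @param genome data.frame (`contig`, `length`) from [make_genome()].
#' @param path Output path.
#' @param sorted Write coordinate-sorted records (and say so in `@HD`)?
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path, sorted = FALSE) {
  ord <- if (sorted) {
    order(match(reads$contig, genome$contig), reads$start)
  } else {
    seq_len(nrow(reads))
  }
  r <- reads[ord, , drop = FALSE]
  header <- c(
    sprintf("@HD\tVN:1.6\tSO:%s",
            if (sorted) "coordinate" else "unsorted"),
    sprintf("@SQ\tSN:%s\tLN:%d", genome$contig, genome$length),
    "@PG\tID:utarscan\tPN:utarscan"
  )
  body <- if (nrow(r)) {
    sprintf("r%07d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tCB:Z:%s\tXT:Z:%s",
            ord, ifelse(r$strand == "+", 0L, 16L), r$contig,
            r$start + 1L, r$length, r$barcode, r$origin)
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read spot-barcoded alignments from SAM/BAM
#'
#' Converts SAM to BAM with Rsamtools and loads alignments with their
#' `CB` (barcode) and `XT` (origin) tags, returning the package's
#' internal 0-based half-open read table.
#'
#' @param path Path to a SAM or BAM file.
#' @return data.frame with `contig`, `start`, `end`, `length`,
#'   `strand`, `barcode`, `origin` (the latter two `NA` when the tags
#'   are absent).
#' @export
read_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    dest <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                     indexDestination = FALSE, overwrite = TRUE)
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(tag = c("CB", "XT")))
  mc <- S4Vectors::mcols(aln)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(aln)),
    start = GenomicRanges::start(aln) - 1L,
    end = GenomicRanges::end(aln),
    length = GenomicRanges::width(aln),
    strand = as.character(GenomicRanges::strand(aln)),
    barcode = if (!is.null(mc$CB)) as.character(mc$CB) else NA_character_,
    origin = if (!is.null(mc$XT)) as.character(mc$XT) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write gene annotation as GTF
#'
#' One `gene` feature line per annotated locus; internal 0-based
#' half-open intervals convert to GTF's 1-based closed convention at
#' this boundary.
#'
#' @param loci Truth table; only rows with `annotated = TRUE` are
#'   written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(loci, path) {
  genes <- loci[loci$annotated, , drop = FALSE]
  gr <- gr0(genes)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "utarscan_sim", type = "gene",
    gene_id = genes$id, gene_name = genes$id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene annotation from GTF
#'
#' Loads `gene`-typed features (falling back to the union of all
#' features per `gene_id` when no `gene` lines exist) into the internal
#' 0-based half-open annotation table.
#'
#' @param path Path to a GTF file.
#' @return data.frame with `id`, `contig`, `start`, `end`, `strand`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  data.frame(
    id = if (!is.null(gr$gene_id)) gr$gene_id else
      sprintf("gene%05d", seq_along(gr)),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write a stranded interval set as 6-column BED
#'
#' @param intervals data.frame with `contig`, `start`, `end`, `strand`
#'   and optionally `name` and `score` (0-based half-open, BED's native
#'   convention).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  gr <- gr0(intervals)
  gr$name <- intervals$name %||% sprintf("iv%05d", seq_len(nrow(intervals)))
  gr$score <- intervals$score %||% rep(0, nrow(intervals))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a stranded interval set from BED
#'
#' @param path Path to a BED file (>= 6 columns for strand).
#' @return data.frame with `contig`, `start`, `end`, `strand`, `name`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(gr$name)) gr$name else
      sprintf("iv%05d", seq_along(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write binned coverage as bedGraph (one file per strand)
#'
#' Bins with zero counts are omitted; intervals are 0-based half-open.
#'
#' @param tracks A `binned_coverage_set` from [bin_reads()].
#' @param prefix Output path prefix; files are
#'   `<prefix>.plus.bedGraph` / `<prefix>.minus.bedGraph`.
#' @return The two paths, invisibly.
#' @export
write_bedgraph <- function(tracks, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedGraph"),
             minus = paste0(prefix, ".minus.bedGraph"))
  for (s in c("+", "-")) {
    rows <- list()
    for (tr in tracks) {
      if (tr$strand != s) next
      nz <- which(tr$counts > 0)
      if (!length(nz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        contig = tr$contig,
        start = (nz - 1L) * tr$bin_size,
        end = pmin(nz * tr$bin_size, tr$contig_length),
        score = tr$counts[nz])
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(contig = character(0), start = integer(0),
                 end = integer(0), score = integer(0))
    path <- paths[[if (s == "+") "plus" else "minus"]]
    gr <- GenomicRanges::GRanges(
      df$contig, IRanges::IRanges(df$start + 1L, df$end), score = df$score)
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(paths)
}

#' Write a tab-separated table
#'
#' Plain TSV with a header, no quoting, no row names: the package's
#' uniform sidecar format for truth tables, spot layouts, TAR tables
#' and DE results.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path Path to the TSV file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
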