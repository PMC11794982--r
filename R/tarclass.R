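#' Classify TARs as annotated (aTAR) or unannotated (uTAR)
#'
#' A TAR is an aTAR iff it overlaps an annotated gene by at least
#' `min_overlap` bases (default 1); otherwise it is a uTAR. Under
#' `strand_mode = "specific"` only same-strand gene overlap counts;
#' `"ignore"` accepts either strand. Every TAR receives exactly one
#' class.
#'
#' @param tars TAR data.frame from [call_tars()]/[merge_tars()].
#' @param annotation Gene table (`id`, `contig`, `start`, `end`,
#'   `strand`; 0-based half-open), e.g. from [read_annotation_gtf()] or
#'   the annotated rows of a simulation truth table.
#' @param strand_mode `"specific"` (default) or `"ignore"`.
#' @param min_overlap Minimum overlap in bases for aTAR assignment.
#' @return `tars` with `class` filled in (`"aTAR"`/`"uTAR"`).
#' @export
classify_tars <- function(tars, annotation,
                          strand_mode = c("specific", "ignore"),
                          min_overlap = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(tars) == 0L) return(tars)
  tars$class <- "uTAR"
  if (nrow(annotation)) {
    hits <- GenomicRanges::findOverlaps(
      gr0(tars), gr0(annotation),
      minoverlap = min_overlap,
      ignore.strand = (strand_mode == "ignore"))
    tars$class[unique(S4Vectors::queryHits(hits))] <- "aTAR"
  }
  tars
}

#' Label uTARs by lncRNA-database membership
#'
#' Overlaps uTARs with two stranded lncRNA reference sets in a
#' strand-specific manner (>= `min_overlap` bases on the same strand)
#' and assigns `db_label`: `"db1"`, `"db2"`, `"both"` or `"novel"`.
#'
#' @param utars TAR data.frame, all rows with `class == "uTAR"`.
#' @param db1,db2 Stranded interval data.frames (`contig`, `start`,
#'   `end`, `strand`), e.g. from [read_bed6()] or [make_databases()].
#' @param min_overlap Minimum overlap in bases.
#' @return `utars` with `db_label` filled in.
#' @export
overlap_databases <- function(utars, db1, db2, min_overlap = 1L) {
  if (nrow(utars) == 0L) return(utars)
  if (any(utars$class != "uTAR"))
    abort("overlap_databases expects uTARs only; run classify_tars first")
  in_db <- function(db) {
    if (nrow(db) == 0L) return(rep(FALSE, nrow(utars)))
    GenomicRanges::countOverlaps(
      gr0(utars), gr0(db), minoverlap = min_overlap) > 0L
  }
  h1 <- in_db(db1)
  h2 <- in_db(db2)
  utars$db_label <- ifelse(h1 & h2, "both",
                           ifelse(h1, "db1",
                                  ifelse(h2, "db2", "novel")))
  utars
}

#' Cross-sample uTAR sharing
#'
#' Builds a graph whose nodes are the uTARs of all samples and whose
#' edges join strand-matched, overlapping uTARs from *different*
#' samples; connected components are the shared units. A component
#' spanning k distinct samples counts as "shared by k" (k = 1 means
#' unique to one sample). Chained overlaps (A-B, B-C) therefore group A,
#' B and C even when A and C are disjoint.
#'
#' @param utar_sets Named list (>= 2 elements) of uTAR data.frames, one
#'   per sample.
#' @param min_overlap Minimum overlap in bases for an edge.
#' @return A `sharing_table`: list with `members` (data.frame: sample,
#'   uTAR row index within its sample, interval, component id) and
#'   `counts` (data.frame: `n_samples`, `n_components`). Component
#'   counts sum to the number of components.
#' @export
share_across_samples <- function(utar_sets, min_overlap = 1L) {
  if (length(utar_sets) < 2L)
    abort("sharing requires at least two samples")
  if (is.null(names(utar_sets)) || any(names(utar_sets) == ""))
    names(utar_sets) <- sprintf("sample%d", seq_along(utar_sets))
  pooled <- do.call(rbind, lapply(names(utar_sets), function(s) {
    u <- utar_sets[[s]]
    if (nrow(u) == 0L) return(NULL)
    data.frame(sample = s, index = seq_len(nrow(u)),
               contig = u$contig, start = u$start, end = u$end,
               strand = u$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L)
    return(structure(list(members = data.frame(), counts = data.frame(
      n_samples = integer(0), n_components = integer(0))),
      class = "sharing_table"))

  gr <- gr0(pooled)
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = min_overlap,
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  cross <- pooled$sample[q] != pooled$sample[s]
  g <- igraph::graph_from_data_frame(
    data.frame(from = q[cross], to = s[cross]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(pooled))))
  comp <- igraph::components(g)$membership
  pooled$component <- as.integer(comp[as.character(seq_len(nrow(pooled)))])

  per_comp <- tapply(pooled$sample, pooled$component,
                     function(x) length(unique(x)))
  tab <- table(factor(per_comp, levels = seq_along(utar_sets)))
  counts <- data.frame(n_samples = as.integer(names(tab)),
                       n_components = as.integer(tab))
  structure(list(members = pooled, counts = counts),
            class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("uTAR sharing across", length(unique(x$members$sample)),
      "samples:", max(x$members$component %||% 0), "components\n")
  print(x$counts)
  invisible(x)
}

#' Tally TAR classes and database labels
#'
#' @param tars Classified TAR data.frame (after [classify_tars()] and,
#'   for uTARs, [overlap_databases()]).
#' @return List with `n_tars`, `by_class`, `by_db_label` (uTARs only)
#'   and `frac_utar_in_db` (fraction of uTARs found in at least one
#'   database; `NaN` when there are no uTARs).
#' @export
classification_report <- function(tars) {
  by_class <- table(factor(tars$class, levels = c("aTAR", "uTAR")))
  u <- tars[tars$class == "uTAR", , drop = FALSE]
  by_db <- table(factor(u$db_label,
                        levels = c("novel", "db1", "db2", "both")))
  list(
    n_tars = nrow(tars),
    by_class = as.list(by_class),
    by_db_label = as.list(by_db),
    frac_utar_in_db = if (nrow(u)) mean(u$db_label != "novel") else NaN
  )
}
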