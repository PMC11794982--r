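genes <- data.frame(id = c("g1", "g2"), contig = c("c1", "c1"),
                    start = c(0L, 5000L), end = c(1000L, 6000L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)

test_that("TARs partition into aTARs and uTARs by strand-aware gene overlap", {
  tars <- rbind(make_tar("c1", 100L, 200L, "+"),   # inside g1, same strand
                make_tar("c1", 3000L, 3100L, "+"), # no gene
                make_tar("c1", 5100L, 5200L, "+")) # only opposite-strand g2
  spec <- classify_tars(tars, genes, strand_mode = "specific")
  expect_equal(spec$class, c("aTAR", "uTAR", "uTAR"))
  ign <- classify_tars(tars, genes, strand_mode = "ignore")
  expect_equal(ign$class, c("aTAR", "uTAR", "aTAR"))
  # strand-mode flip changes exactly the opposite-strand-overlap cases
  expect_equal(which(spec$class != ign$class), 3L)

  # partition: every TAR exactly one class; uTARs have no strand-matched
  # overlap on re-query
  expect_true(all(spec$class %in% c("aTAR", "uTAR")))
  u <- spec[spec$class == "uTAR", ]
  requery <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(u$contig,
                           IRanges::IRanges(u$start + 1L, u$end), u$strand),
    GenomicRanges::GRanges(genes$contig,
                           IRanges::IRanges(genes$start + 1L, genes$end),
                           genes$strand))
  expect_true(all(requery == 0L))
})

test_that("a one-base overlap is enough for aTAR unless a threshold is set", {
  tars <- make_tar("c1", 999L, 1100L, "+")   # overlaps g1 by exactly 1 base
  expect_equal(classify_tars(tars, genes)$class, "aTAR")
  expect_equal(classify_tars(tars, genes, min_overlap = 2L)$class, "uTAR")
})

test_that("database labels follow strand-specific overlap", {
  db1 <- data.frame(contig = "c1", start = 100L, end = 300L, strand = "+",
                    name = "L1")
  db2 <- data.frame(contig = "c1", start = 250L, end = 400L, strand = "+",
                    name = "L2")
  utars <- rbind(make_tar("c1", 150L, 260L, "+", class = "uTAR"),  # both
                 make_tar("c1", 120L, 200L, "+", class = "uTAR"),  # db1
                 make_tar("c1", 320L, 380L, "+", class = "uTAR"),  # db2
                 make_tar("c1", 150L, 260L, "-", class = "uTAR"),  # opp strand
                 make_tar("c1", 900L, 950L, "+", class = "uTAR"))  # none
  lab <- overlap_databases(utars, db1, db2)
  expect_equal(lab$db_label, c("both", "db1", "db2", "novel", "novel"))
  expect_error(overlap_databases(make_tar("c1", 1L, 2L, class = "aTAR"),
                                 db1, db2), "uTARs only")
})

test_that("cross-sample sharing groups overlapping uTARs into components", {
  iv <- function(s, e, strand = "+")
    make_tar("c1", s, e, strand, class = "uTAR")
  # identical interval in three samples -> one component spanning 3
  same <- list(A = iv(100L, 200L), B = iv(100L, 200L), C = iv(100L, 200L))
  sh <- share_across_samples(same)
  expect_equal(max(sh$members$component), 1L)
  expect_equal(sh$counts$n_components[sh$counts$n_samples == 3], 1L)
  expect_equal(sum(sh$counts$n_components), 1L)

  # disjoint sets -> every uTAR unique
  disj <- list(A = iv(0L, 50L), B = iv(1000L, 1050L), C = iv(2000L, 2050L))
  shd <- share_across_samples(disj)
  expect_equal(shd$counts$n_components[shd$counts$n_samples == 1], 3L)

  # chain A-B, B-C with A,C disjoint -> one 3-sample component
  chain <- list(A = iv(0L, 120L), B = iv(100L, 300L), C = iv(280L, 400L))
  shc <- share_across_samples(chain)
  expect_equal(max(shc$members$component), 1L)
  expect_equal(shc$counts$n_components[shc$counts$n_samples == 3], 1L)

  # opposite strands never join
  opp <- list(A = iv(0L, 120L), B = iv(0L, 120L, "-"))
  expect_equal(max(share_across_samples(opp)$members$component), 2L)

  expect_error(share_across_samples(list(A = iv(0L, 10L))), "two samples")
})

test_that("sharing components are invariant to sample input order", {
  withr::with_seed(5, {
    mk <- function() {
      n <- sample(3:8, 1)
      s <- sort(sample(seq(0, 5000, 10), n))
      make_tar("c1", s, s + sample(50:400, n, replace = TRUE),
               strand = sample(c("+", "-"), n, replace = TRUE),
               class = "uTAR")
    }
    sets <- list(A = mk(), B = mk(), C = mk())
  })
  sh1 <- share_across_samples(sets)
  sh2 <- share_across_samples(rev(sets))
  comp_sets <- function(sh) {
    key <- paste(sh$members$sample, sh$members$index)
    unname(sort(vapply(split(key, sh$members$component),
                       function(k) paste(sort(k), collapse = "|"), "")))
  }
  expect_identical(comp_sets(sh1), comp_sets(sh2))
  expect_identical(sh1$counts, sh2$counts)
})

test_that("classification reports tally classes and database fractions", {
  tars <- rbind(make_tar("c1", 0L, 100L, class = "aTAR"),
                make_tar("c1", 200L, 300L, class = "uTAR",
                         db_label = "db1"),
                make_tar("c1", 400L, 500L, class = "uTAR",
                         db_label = "novel"))
  rep <- classification_report(tars)
  expect_equal(rep$n_tars, 3L)
  expect_equal(rep$by_class$aTAR, 1L)
  expect_equal(rep$by_class$uTAR, 2L)
  expect_equal(rep$frac_utar_in_db, 0.5)

  empty <- classification_report(make_tar("c1", 0L, 100L,
                                          class = "aTAR")[0, ])
  expect_equal(empty$n_tars, 0L)
  expect_true(is.nan(empty$frac_utar_in_db))
})

test_that("GTF and BED round-trip annotation and databases", {
  cfg <- default_cfg()
  g <- make_genome(cfg)
  db <- make_databases(g$loci, cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(db$loci, gtf)
  ann <- read_annotation_gtf(gtf)
  genes0 <- db$loci[db$loci$annotated, c("id", "contig", "start", "end",
                                         "strand")]
  rownames(genes0) <- NULL
  expect_equal(ann[order(ann$id), ], genes0[order(genes0$id), ],
               ignore_attr = TRUE)

  bed <- tempfile(fileext = ".bed")
  write_bed6(db$db1, bed)
  back <- read_bed6(bed)
  expect_equal(back[, c("contig", "start", "end", "strand")],
               db$db1[, c("contig", "start", "end", "strand")],
               ignore_attr = TRUE)
})
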