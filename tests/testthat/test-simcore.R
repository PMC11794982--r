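test_that("genome generation is deterministic and respects the same-strand gap", {
  cfg <- default_cfg(seed = 5)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1, g2)

  loci <- g1$loci
  expect_equal(nrow(loci), cfg$n_genes + cfg$n_lnc)
  expect_true(all(loci$start < loci$end))
  expect_true(all(loci$end <= cfg$contig_length))
  expect_true(all(loci$end - loci$start >= cfg$locus_len_range[1]))
  expect_true(all(loci$end - loci$start <= cfg$locus_len_range[2]))

  # exhaustive pairwise same-strand gap scan
  for (i in seq_len(nrow(loci))) for (j in seq_len(nrow(loci))) {
    if (i >= j) next
    if (loci$contig[i] != loci$contig[j] ||
        loci$strand[i] != loci$strand[j]) next
    gap <- max(loci$start[i], loci$start[j]) -
      min(loci$end[i], loci$end[j])
    expect_gte(gap, cfg$min_gap)
  }
})

test_that("an all-gene genome yields an empty uTAR truth set", {
  cfg <- default_cfg(n_lnc = 0L, n_de_lnc = 0L)
  loci <- make_genome(cfg)$loci
  expect_true(all(loci$annotated))
  db <- make_databases(loci, cfg)
  expect_equal(nrow(db$db1), 0L)
  expect_equal(nrow(db$db2), 0L)
})

test_that("an oversubscribed genome raises a sizing error", {
  cfg <- default_cfg(n_genes = 40L, n_lnc = 20L, n_contigs = 1L,
                     contig_length = 30000L)
  expect_error(make_genome(cfg), "too small")
})

test_that("database membership matches the configured fractions exactly", {
  cfg <- default_cfg(seed = 3, db1_frac = 0.6, db2_frac = 0.5)
  db <- make_databases(make_genome(cfg)$loci, cfg)
  expect_equal(nrow(db$db1), 12L)            # 0.6 * 20
  expect_equal(nrow(db$db2), 10L)            # 0.5 * 20
  expect_equal(sum(db$loci$in_db1), nrow(db$db1))
  expect_equal(sum(db$loci$in_db2), nrow(db$db2))
  expect_true(all(db$db1$name %in% db$loci$id[db$loci$in_db1]))
  expect_false(any(db$loci$in_db1 & db$loci$annotated))

  all_cfg <- default_cfg(db1_frac = 1, db2_frac = 1)
  db_all <- make_databases(make_genome(all_cfg)$loci, all_cfg)
  expect_true(all(db_all$loci$in_db1[!db_all$loci$annotated]))
  none_cfg <- default_cfg(db1_frac = 0, db2_frac = 0)
  db_none <- make_databases(make_genome(none_cfg)$loci, none_cfg)
  expect_false(any(db_none$loci$in_db1 | db_none$loci$in_db2))
})

test_that("spot layouts form a unique grid with a noisy half-plane domain", {
  cfg <- default_cfg()
  spots <- simulate_spots(cfg)
  expect_equal(nrow(spots), 200L)
  expect_false(any(duplicated(spots[, c("x", "y")])))
  expect_false(any(duplicated(spots$barcode)))
  expect_setequal(unique(spots$domain), c("keratinocyte_like", "other"))

  clean <- simulate_spots(default_cfg(flip_noise = 0))
  split_x <- ceiling((1 - cfg$domain_frac) * (max(clean$x) + 1L))
  expect_identical(clean$domain,
                   ifelse(clean$x >= split_x, "keratinocyte_like", "other"))

  # flipped fraction within 3 binomial SDs of the noise rate
  big <- simulate_spots(default_cfg(n_spots = 10000L, flip_noise = 0.05))
  big_clean <- simulate_spots(default_cfg(n_spots = 10000L, flip_noise = 0))
  flipped <- mean(big$domain != big_clean$domain)
  expect_lt(abs(flipped - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))

  expect_error(simulate_spots(default_cfg(n_spots = 199L)), "prime")
})

test_that("count simulation follows the NB mean model", {
  cfg <- default_cfg()
  g <- make_genome(cfg)
  spots <- simulate_spots(cfg)

  zero <- g$loci
  zero$base_mean <- 0
  expect_true(all(simulate_counts(zero, spots, cfg) == 0))

  # moment check: base_mean 2, dispersion 2, one null locus, 10,000 spots
  many <- simulate_spots(default_cfg(n_spots = 10000L))
  one <- g$loci[g$loci$role == "null" & !g$loci$annotated, ][1, ]
  counts <- simulate_counts(one, many, cfg)
  se <- sqrt((2 + 2^2 / 2) / 10000)
  expect_lt(abs(mean(counts) - 2), 3 * se)

  # cell-type effect shows up in the domain means
  k_marker <- g$loci[g$loci$role == "marker_kerat", ][1, ]
  mk <- simulate_counts(k_marker, many, cfg)
  kerat <- many$domain == "keratinocyte_like"
  expect_gt(mean(mk[, kerat]), 4 * mean(mk[, !kerat]))
})

test_that("reads stay inside their origin locus and conserve counts", {
  cfg <- default_cfg()
  g <- make_genome(cfg)
  db <- make_databases(g$loci, cfg)
  spots <- simulate_spots(cfg)
  counts <- simulate_counts(db$loci, spots, cfg)
  reads <- fragment_and_place_reads(counts, db$loci, cfg)

  expect_equal(nrow(reads), cfg$reads_per_count * sum(counts))
  li <- match(reads$origin, db$loci$id)
  expect_true(all(reads$start >= db$loci$start[li]))
  expect_true(all(reads$start + reads$length <= db$loci$end[li]))
  expect_identical(reads$strand, db$loci$strand[li])
  expect_true(all(reads$barcode %in% spots$barcode))
  expect_true(all(reads$length >= 1L & reads$length <= cfg$read_len))

  # reads_per_count multiplies read count
  cfg2 <- default_cfg(reads_per_count = 3L)
  reads3 <- fragment_and_place_reads(counts, db$loci, cfg2)
  expect_equal(nrow(reads3), 3L * sum(counts))
})

test_that("polyA capture biases read 3' ends toward the locus 3' end", {
  g <- make_genome(default_cfg())
  spots <- simulate_spots(default_cfg())
  counts <- simulate_counts(g$loci, spots, default_cfg())
  d3 <- function(deg) {
    cfg <- default_cfg(capture_mode = "polyA", degradation = deg)
    r <- fragment_and_place_reads(counts, g$loci, cfg)
    li <- match(r$origin, g$loci$id)
    mean(ifelse(r$strand == "+",
                g$loci$end[li] - (r$start + r$length),
                r$start - g$loci$start[li]))
  }
  expect_lt(d3(200), d3(2000))
  expect_lt(d3(200), 250)
})

test_that("dv200 is exact on hand cases and errors on bad input", {
  expect_equal(dv200(rep(500, 10)), 100)
  expect_equal(dv200(c(100, 150, 250, 300)), 50)
  expect_equal(dv200(c(200, 201)), 50)  # strictly greater than 200
  expect_error(dv200(numeric(0)), "at least one")
  expect_error(dv200(c(100, -5)), "positive")
})

test_that("dv200 is monotone in the degradation scale on seeded averages", {
  degs <- c(100, 200, 400, 800, 1600)
  dv <- vapply(degs, function(d) {
    mean(vapply(1:5, function(s) {
      withr::with_seed(s, dv200(rexp(2000, rate = 1 / d)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(dv) > 0))
})
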