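#' Simulate a spot array with two spatial cell-type domains
#'
#' Lays `n_spots` barcoded spots on a rectangular grid and assigns each
#' a hard cell-type domain label by a vertical half-plane split: the
#' rightmost `domain_frac` of grid columns form a `keratinocyte_like`
#' band (emulating an epidermal margin), the rest are `other`. A small
#' fraction `flip_noise` of labels is then flipped to emulate a ragged
#' histological boundary. Spot capacity (cells per spot) is not
#' modelled; the label is the domain of the spot as a unit.
#'
#' @param config A [sim_config()]. `n_spots` must factor into a
#'   rectangular grid (prime counts are rejected).
#' @return data.frame with `barcode`, `x`, `y` (integer grid
#'   coordinates) and `domain`.
#' @export
simulate_spots <- function(config) {
  n <- config$n_spots
  d <- max(which(n %% seq_len(floor(sqrt(n))) == 0L))
  if (d == 1L && n > 3L)
    abort("n_spots = ", n, " is prime and cannot form a grid")
  ny <- d
  nx <- n %/% d
  grid <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  split_x <- ceiling((1 - config$domain_frac) * nx)
  domain <- ifelse(grid$x >= split_x, "keratinocyte_like", "other")
  flip <- withr::with_seed(derive_seed(config$seed, "spots"),
                           runif(n) < config$flip_noise)
  domain[flip] <- ifelse(domain[flip] == "other",
                         "keratinocyte_like", "other")
  data.frame(
    barcode = sprintf("BC%05d", seq_len(n)),
    x = grid$x, y = grid$y, domain = domain,
    stringsAsFactors = FALSE
  )
}

#' Simulate true expression counts per locus and spot
#'
#' Draws `count(locus, spot) ~ NB(mean = base_mean * effect[domain],
#' size = dispersion)` where `effect[domain]` is the locus's fold
#' multiplier in the spot's cell-type domain
#' (`effect_keratinocyte_like` or `effect_other` in the truth table).
#' The NB is parameterised as mean/size: `dispersion` is the size
#' parameter, so variance = mean + mean^2 / size.
#'
#' @param loci Truth table from [make_genome()].
#' @param spots Spot layout from [simulate_spots()].
#' @param config A [sim_config()].
#' @return Integer matrix (loci x spots) with dimnames.
#' @export
simulate_counts <- function(loci, spots, config) {
  eff <- cbind(keratinocyte_like = loci$effect_keratinocyte_like,
               other = loci$effect_other)
  mu <- loci$base_mean * eff[, spots$domain, drop = FALSE]
  counts <- withr::with_seed(
    derive_seed(config$seed, "counts"),
    matrix(rnbinom(length(mu), size = rep(loci$dispersion, ncol(mu)),
                   mu = as.vector(mu)),
           nrow = nrow(loci),
           dimnames = list(loci$id, spots$barcode))
  )
  counts
}
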