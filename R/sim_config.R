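#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' saturation-mutagenesis library of a 150-residue DNA-binding domain read
#' out by barcoded competitive growth: every position from 2 to 150 carries
#' all 19 missense substitutions plus a premature stop, variants carry a
#' negative-binomial number of barcodes (median 19), the wild type carries
#' 8655 barcodes, and samples are drawn at 0/12/24/36 h.
#'
#' True per-variant selection coefficients `s_plus` (antibiotic arm) are
#' drawn from a five-part mixture (tolerated mass near 0, hypomorphic and
#' loss-of-function tails, a small gain-of-function tail and a small toxic
#' tail); the no-antibiotic arm is anticorrelated,
#' `s_minus = anticorrelation * s_plus + noise`.
#'
#' @param region_length number of residues in the construct.
#' @param mutable_positions inclusive integer range of mutagenised positions.
#' @param barcodes_per_variant_dist list: `name` (`"nbinom"`), `size`, `mu`,
#'   `min` (lower truncation). Defaults give median 19 barcodes per variant.
#' @param n_wt_barcodes number of wild-type barcodes.
#' @param n_synonymous number of synonymous pseudo-variants.
#' @param timepoints_h sampling times in hours, strictly increasing; the
#'   first must be the selection start (t = 0).
#' @param depth_per_timepoint sequencing reads per timepoint.
#' @param baseline_growth_rate baseline log-growth per normalized time unit
#'   shared by all cells (cancels in log-ratios).
#' @param s_null selection coefficient of a null (non-binding) variant per
#'   normalized time unit; every nonsense variant gets exactly this value.
#' @param effect_distribution mixture over missense selection coefficients:
#'   list of components, each `list(weight, dist, ...params)` with `dist`
#'   `"normal"` or `"uniform"`.
#' @param anticorrelation slope linking the two arms (negative).
#' @param s_minus_noise_sd residual sd of the no-antibiotic coefficient.
#' @param label_link list with `k` (steepness) and `s0` (midpoint) of the
#'   logistic link from |s_plus| to pathogenicity propensity.
#' @param barcode_length barcode length in nt.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(region_length = 150L,
                       mutable_positions = c(2L, 150L),
                       barcodes_per_variant_dist = list(name = "nbinom",
                                                        size = 3, mu = 21,
                                                        min = 1),
                       n_wt_barcodes = 8655L,
                       n_synonymous = 227L,
                       timepoints_h = c(0, 12, 24, 36),
                       depth_per_timepoint = 1e6,
                       baseline_growth_rate = 1.0,
                       s_null = -2.5,
                       effect_distribution = list(
                         list(weight = 0.45, dist = "normal", mean = 0,    sd = 0.08),
                         list(weight = 0.20, dist = "uniform", min = -2.0, max = -0.4),
                         list(weight = 0.22, dist = "normal", mean = -2.5, sd = 0.15),
                         list(weight = 0.08, dist = "normal", mean = 0.8,  sd = 0.25),
                         list(weight = 0.05, dist = "normal", mean = -3.6, sd = 0.25)),
                       anticorrelation = -0.6,
                       s_minus_noise_sd = 0.15,
                       label_link = list(k = 6, s0 = 1.0),
                       barcode_length = 30L,
                       seed = 1L) {
  cfg <- list(region_length = as.integer(region_length),
              mutable_positions = as.integer(mutable_positions),
              barcodes_per_variant_dist = barcodes_per_variant_dist,
              n_wt_barcodes = as.integer(n_wt_barcodes),
              n_synonymous = as.integer(n_synonymous),
              timepoints_h = as.numeric(timepoints_h),
              depth_per_timepoint = depth_per_timepoint,
              baseline_growth_rate = baseline_growth_rate,
              s_null = s_null,
              effect_distribution = effect_distribution,
              anticorrelation = anticorrelation,
              s_minus_noise_sd = s_minus_noise_sd,
              label_link = label_link,
              barcode_length = as.integer(barcode_length),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$region_length >= 1, "region_length must be >= 1")
  assert_that(length(cfg$mutable_positions) == 2 &&
                cfg$mutable_positions[1] <= cfg$mutable_positions[2],
              "mutable_positions must be an inclusive range")
  assert_that(cfg$mutable_positions[1] >= 1 &&
                cfg$mutable_positions[2] <= cfg$region_length,
              "mutable range must lie within [1, region_length]")
  assert_that(all(diff(cfg$timepoints_h) > 0),
              "timepoints must be strictly increasing")
  assert_that(cfg$depth_per_timepoint > 0, "depth must be > 0")
  w <- vapply(cfg$effect_distribution, function(co) co$weight, numeric(1))
  assert_that(all(is.finite(w)) && all(w >= 0) && sum(w) > 0,
              "mixture weights must be finite and non-negative")
  pars <- unlist(lapply(cfg$effect_distribution,
                        function(co) co[setdiff(names(co), "dist")]))
  assert_that(all(is.finite(as.numeric(pars))),
              "every distribution parameter must be finite")
  assert_that(is.finite(cfg$anticorrelation), "anticorrelation must be finite")
  invisible(cfg)
}

# Draw n values from the configured mixture of selection coefficients.
draw_effects <- function(n, mixture) {
  w <- vapply(mixture, function(co) co$weight, numeric(1))
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  s <- numeric(n)
  for (j in seq_along(mixture)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    co <- mixture[[j]]
    s[idx] <- switch(co$dist,
      normal  = stats::rnorm(length(idx), co$mean, co$sd),
      uniform = stats::runif(length(idx), co$min, co$max),
      stop_y1h(sprintf("unknown mixture component '%s'", co$dist)))
  }
  s
}
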