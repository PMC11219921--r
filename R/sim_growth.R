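#' Simulate competitive growth and barcode sequencing
#'
#' Each barcode `b` carrying variant `v` grows exponentially from a random
#' starting abundance: `n_b(t) = n_b(0) * exp((r0 + s_v) * t / t_max)`,
#' with time normalized to the final sampling point so selection
#' coefficients and downstream fitness scores share one scale. At every
#' timepoint, `depth` reads are drawn multinomially from the current
#' abundance frequencies (sequencing noise); with `sampling = "expected"`
#' the noiseless expected read counts `depth * frequency` are returned
#' instead (the infinite-depth limit used by scoring oracles).
#'
#' @param map barcode-variant map from [gen_library()].
#' @param effects true-effect table from [gen_library()].
#' @param config a [sim_config()].
#' @param condition `"plus_antibiotic"` (uses `s_plus`) or
#'   `"minus_antibiotic"` (uses `s_minus`).
#' @param lineage lineage identifier; different lineages get independent
#'   starting abundances and sampling noise under the same true effects.
#' @param depth reads per timepoint (default from config).
#' @param sampling `"multinomial"` or `"expected"`.
#' @return A barcode-level [count_table()].
#' @export
simulate_growth <- function(map, effects, config,
                            condition = c("plus_antibiotic",
                                          "minus_antibiotic"),
                            lineage = 1L,
                            depth = config$depth_per_timepoint,
                            sampling = c("multinomial", "expected")) {
  condition <- match.arg(condition)
  sampling <- match.arg(sampling)
  validate_barcode_map(map)
  assert_that(all(map$variant %in% effects$variant),
              "every mapped variant needs a true-effect entry")
  assert_that(depth > 0, "depth must be > 0")

  s_col <- if (condition == "plus_antibiotic") "s_plus" else "s_minus"
  s <- effects[[s_col]][match(map$variant, effects$variant)]
  times <- config$timepoints_h
  x <- times / max(times)

  with_seed(derive_seed(config$seed,
                        paste("growth", condition, lineage, sep = ":")), {
    n0 <- stats::rlnorm(nrow(map), meanlog = log(100), sdlog = 0.5)
    counts <- matrix(0, nrow(map), length(times))
    for (j in seq_along(times)) {
      abund <- n0 * exp((config$baseline_growth_rate + s) * x[j])
      tot <- sum(abund)
      if (!is.finite(tot) || tot <= 0) stop_y1h("zero total abundance")
      freq <- abund / tot
      counts[, j] <- if (sampling == "multinomial") {
        stats::rmultinom(1, size = depth, prob = freq)[, 1]
      } else {
        depth * freq
      }
    }
    count_table(counts, map$barcode, times, level = "barcode",
                condition = list(bait = "synthetic",
                                 antibiotic = if (condition ==
                                                  "plus_antibiotic") "plus"
                                              else "minus"),
                lineage = lineage)
  })
}

#' Generate clinical labels from true effects
#'
#' Produces a synthetic pathogenic/benign label set whose relationship to
#' the true selection coefficients is controlled. Pathogenicity tracks the
#' absolute antibiotic-arm coefficient, reflecting that deviation from
#' wild-type binding in either direction can be pathogenic.
#'
#' Two modes:
#' \describe{
#'   \item{`rank`}{exactly `round(prior * n)` pathogenic labels.
#'     `overlap = 0` labels the largest-`|s_plus|` variants pathogenic
#'     (perfect separation); `overlap = 1` labels uniformly at random
#'     (labels independent of effect); intermediate values mix the two.}
#'   \item{`logistic`}{each selected variant is labelled pathogenic with
#'     probability `plogis(k * (|s_plus| - s0))` (link from the config);
#'     the class split is then stochastic. This mode has a closed-form
#'     local class ratio used by calibration-recovery checks.}
#' }
#'
#' Pathogenic variants receive a phenotype group: 1 (mild/classical
#' aniridia-like), 2 (atypical, preferentially assigned to larger effects)
#' or 3 (undetermined); benign variants get `"none"`.
#'
#' @param effects true-effect table from [gen_library()].
#' @param config a [sim_config()].
#' @param n number of labelled variants (must not exceed available
#'   missense/nonsense variants).
#' @param prior fraction pathogenic (rank mode only).
#' @param overlap label-vs-effect mixing in `[0, 1]` (rank mode only).
#' @param method `"rank"` or `"logistic"`.
#' @param classes variant classes eligible for labelling.
#' @return data frame: `variant`, `label`, `source`, `phenotype_group`.
#' @export
gen_labels <- function(effects, config, n = 100L, prior = 0.3,
                       overlap = 0, method = c("rank", "logistic"),
                       classes = c("missense", "nonsense")) {
  method <- match.arg(method)
  pool <- effects[effects$variant_class %in% classes, , drop = FALSE]
  assert_that(n <= nrow(pool),
              "requested label count exceeds available variants")
  assert_that(overlap >= 0 && overlap <= 1, "overlap must be in [0,1]")

  with_seed(derive_seed(config$seed, paste0("labels:", n, ":", method)), {
    pick <- pool[sample.int(nrow(pool), n), , drop = FALSE]
    a <- abs(pick$s_plus)
    if (method == "rank") {
      n_path <- round(prior * n)
      n_det <- round((1 - overlap) * n_path)
      ord <- order(-a, pick$variant)       # ties broken by id
      path_idx <- ord[seq_len(n_det)]
      rest <- setdiff(seq_len(n), path_idx)
      path_idx <- c(path_idx, sample(rest, n_path - n_det))
      label <- rep("benign", n)
      label[path_idx] <- "pathogenic"
    } else {
      p <- stats::plogis(config$label_link$k * (a - config$label_link$s0))
      label <- ifelse(stats::runif(n) < p, "pathogenic", "benign")
    }

    group <- rep("none", n)
    is_path <- label == "pathogenic"
    if (any(is_path)) {
      # Atypical (group 2) enriched among larger absolute effects.
      ap <- a[is_path]
      p2 <- stats::plogis(2 * (ap - stats::median(ap)))
      g <- ifelse(stats::runif(sum(is_path)) < 0.2, "3",
                  ifelse(stats::runif(sum(is_path)) < p2, "2", "1"))
      group[is_path] <- g
    }

    data.frame(variant = pick$variant, label = label, source = "synthetic",
               phenotype_group = group, stringsAsFactors = FALSE)
  })
}

#' Read / write clinical label sets as CSV
#'
#' Columns: `variant`, `label` (pathogenic/benign), `source`,
#' `phenotype_group` (1/2/3/none).
#'
#' @param labels label data frame.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  labels <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("variant", "label")
  assert_that(all(need %in% names(labels)),
              "labels need at least columns variant, label")
  assert_that(all(labels$label %in% c("pathogenic", "benign")),
              "labels must be pathogenic or benign")
  assert_that(!anyDuplicated(labels$variant), "one label per variant")
  if (is.null(labels$source)) labels$source <- NA_character_
  if (is.null(labels$phenotype_group)) labels$phenotype_group <- "none"
  labels
}
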