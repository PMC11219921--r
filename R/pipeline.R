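#' End-to-end scoring of one assay condition
#'
#' Chains the standard preprocessing and scoring steps: the 25-read T = 0
#' floor, selection of the first four timepoints, barcode-to-variant
#' aggregation (with the dual wild-type handling), per-lineage weighted
#' log-ratio regression, inverse-variance lineage combination, wild-type
#' centring, dual-null z-tests with BH correction, and functional
#' category assignment.
#'
#' @param barcode_tables a barcode-level [count_table()] or list of them
#'   (one per lineage).
#' @param map barcode-variant map.
#' @param min_reads T = 0 read floor.
#' @param k_timepoints number of leading timepoints scored.
#' @param wt_group_size wild-type pseudo-variant group size.
#' @param alpha FDR threshold for categories.
#' @param seed seed for the wild-type partition.
#' @return score data frame: `variant`, `variant_class`, `score`, `se`,
#'   `n_barcodes`, `n_lineages`, `flagged`, `p_wt`, `q_wt`, `p_nonsense`,
#'   `q_nonsense`, `category`, `category_multi_match`; wild-type
#'   pseudo-variant scores in attribute `wt_scores`, the centring offset
#'   in `wt_offset`, category counts in `category_counts`.
#' @export
score_assay <- function(barcode_tables, map, min_reads = 25,
                        k_timepoints = 4L, wt_group_size = 19L,
                        alpha = 0.05, seed = 1L) {
  if (inherits(barcode_tables, "count_table")) {
    barcode_tables <- list(barcode_tables)
  }
  aggs <- lapply(barcode_tables, function(tab) {
    tab <- filter_min_t0(tab, min_reads)
    if (nrow(tab) == 0) stop_y1h("no barcodes pass the T = 0 floor")
    tab <- select_timepoints(tab, k_timepoints)
    aggregate_to_variants(tab, map, wt_group_size = wt_group_size,
                          seed = seed)
  })

  assert_that(!any(vapply(aggs, function(a) is.null(a$wt_groups),
                          logical(1))),
              "wild-type barcodes are required for centring")
  raw <- score_condition(lapply(aggs, `[[`, "variants"),
                         lapply(aggs, `[[`, "wt_series"))
  wt_raw <- score_condition(lapply(aggs, `[[`, "wt_groups"),
                            lapply(aggs, `[[`, "wt_series"))

  scored <- normalize_to_wt(raw, wt_raw$score)
  wt_scores <- wt_raw$score - attr(scored, "wt_offset")

  scored$variant_class <- map$variant_class[match(scored$variant,
                                                  map$variant)]
  nbc <- Reduce(`+`, lapply(aggs, function(a) {
    out <- stats::setNames(integer(length(scored$variant)), scored$variant)
    out[names(a$n_barcodes)] <- a$n_barcodes
    out
  }))
  scored$n_barcodes <- as.integer(nbc[scored$variant])

  # Wild-type null: the centred WT pseudo-variant distribution.
  wt_ref <- list(score = mean(wt_scores),
                 se = stats::sd(wt_scores) / sqrt(length(wt_scores)))
  ns <- scored[scored$variant_class == "nonsense", , drop = FALSE]
  assert_that(nrow(ns) >= 2, "need nonsense variants for the second null")
  nonsense_ref <- list(score = mean(ns$score),
                       se = stats::sd(ns$score) / sqrt(nrow(ns)))

  scored$p_wt <- null_pvalue(scored$score, scored$se,
                             wt_ref$score, wt_ref$se)
  scored$q_wt <- bh_fdr(scored$p_wt)
  scored$p_nonsense <- null_pvalue(scored$score, scored$se,
                                   nonsense_ref$score, nonsense_ref$se)
  scored$q_nonsense <- bh_fdr(scored$p_nonsense)

  scored <- assign_categories(scored,
                              category_rules(alpha = alpha,
                                             mean_nonsense =
                                               nonsense_ref$score))
  attr(scored, "wt_scores") <- wt_scores
  attr(scored, "nonsense_ref") <- nonsense_ref
  scored
}

#' Write / read variant score tables as CSV
#'
#' Column layout: `variant`, `score`, `se`, `n_barcodes`, `p_wt`, `q_wt`,
#' `p_nonsense`, `q_nonsense`, `category`, plus whatever else the table
#' carries. `read_scores` also accepts MaveDB-style score CSVs (comment
#' header lines starting with `#`, `hgvs_pro` identifier column), mapping
#' `hgvs_pro` to `variant`.
#'
#' @param table score data frame.
#' @param path file path.
#' @export
write_scores <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"variant" %in% names(df) && "hgvs_pro" %in% names(df)) {
    names(df)[names(df) == "hgvs_pro"] <- "variant"
  }
  assert_that(all(c("variant", "score") %in% names(df)),
              "score table needs variant and score columns")
  df
}

#' Full evidence calibration from scores and labels
#'
#' Convenience wrapper: takes a (typically absolute) score table and a
#' clinical label set, runs both oddsPath sweeps, derives tier score
#' thresholds and applies them to the full table.
#'
#' @param table score data frame (`variant`, `score`).
#' @param labels label data frame (`variant`, `label`).
#' @param min_window,min_minority window constraints.
#' @param boundaries tier boundary table.
#' @param rule threshold rule (see [evidence_thresholds()]).
#' @return list: `calib_path`, `calib_benign`, `thresholds`, `evidence`
#'   (the table with tiers), `tier_counts`.
#' @export
calibrate_evidence <- function(table, labels, min_window = 20L,
                               min_minority = 2L,
                               boundaries = acmg_tier_boundaries(),
                               rule = "sustained") {
  idx <- match(labels$variant, table$variant)
  keep <- !is.na(idx) & !is.na(table$score[idx])
  assert_that(sum(keep) >= min_window, "too few labelled, scored variants")
  sc <- table$score[idx[keep]]
  lb <- labels$label[keep]
  vv <- labels$variant[keep]

  calib_path <- oddspath_windows(sc, lb, vv, min_window, min_minority,
                                 direction = "pathogenic")
  calib_benign <- oddspath_windows(sc, lb, vv, min_window, min_minority,
                                   direction = "benign")
  thresholds <- evidence_thresholds(calib_path, calib_benign, boundaries,
                                    rule = rule)
  evidence <- apply_evidence(table, thresholds)
  list(calib_path = calib_path, calib_benign = calib_benign,
       thresholds = thresholds, evidence = evidence,
       tier_counts = attr(evidence, "tier_counts"))
}
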