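#' Log-ratios of variant to wild-type counts
#'
#' Per-timepoint log enrichment of a variant relative to the wild-type
#' reference, with 0.5 pseudocounts, and the corresponding approximate
#' variance used as the regression weight:
#' \deqn{L_t = \ln\frac{c_t + 0.5}{w_t + 0.5}, \qquad
#'       V_t = \frac{1}{c_t + 0.5} + \frac{1}{w_t + 0.5}.}
#'
#' @param variant_counts non-negative counts per timepoint.
#' @param wt_counts wild-type reference counts, same length.
#' @return list with numeric vectors `L` and `V`.
#' @export
log_ratios <- function(variant_counts, wt_counts) {
  assert_that(length(variant_counts) == length(wt_counts),
              "count series must have equal length")
  assert_that(all(variant_counts >= 0) && all(wt_counts >= 0),
              "counts must be non-negative")
  L <- log((variant_counts + 0.5) / (wt_counts + 0.5))
  V <- 1 / (variant_counts + 0.5) + 1 / (wt_counts + 0.5)
  list(L = L, V = V)
}

#' Weighted least-squares slope of a log-ratio series
#'
#' Fits `L ~ a + b x` by weighted least squares with weights `1/V`; the
#' slope `b` is the fitness score on the normalized time axis. The slope
#' standard error uses the residual variance on `n - 2` degrees of
#' freedom, so it is invariant to rescaling all weights; when residuals
#' vanish (an exact line) the se is reported at a small positive floor so
#' downstream z-tests stay finite.
#'
#' @param L log-ratio series.
#' @param V variance series (weights are `1/V`).
#' @param x normalized times, same length (default equally spaced on
#'   `[0, 1]`).
#' @param se_floor minimum reported standard error.
#' @return list: `slope`, `se`, `intercept`.
#' @export
wls_slope <- function(L, V, x = seq(0, 1, length.out = length(L)),
                      se_floor = 1e-8) {
  n <- length(L)
  assert_that(n >= 3, "need at least 3 timepoints")
  assert_that(length(V) == n && length(x) == n, "series length mismatch")
  w <- 1 / V
  assert_that(all(is.finite(w)) && all(w > 0),
              "weights must be finite and positive")
  assert_that(stats::var(x) > 0, "all x identical")
  fit <- wls_slope_matrix(matrix(L, 1), matrix(V, 1), x, se_floor)
  list(slope = fit$slope[1], se = fit$se[1], intercept = fit$intercept[1])
}

# Vectorised weighted regression: one row per variant. Closed-form
# weighted least squares, se floored at se_floor.
wls_slope_matrix <- function(Lmat, Vmat, x, se_floor = 1e-8) {
  n <- ncol(Lmat)
  W <- 1 / Vmat
  sw <- rowSums(W)
  xbar <- as.vector(W %*% x) / sw
  ybar <- rowSums(W * Lmat) / sw
  xc <- matrix(x, nrow(Lmat), n, byrow = TRUE) - xbar
  Sxx <- rowSums(W * xc^2)
  Sxy <- rowSums(W * xc * (Lmat - ybar))
  slope <- Sxy / Sxx
  intercept <- ybar - slope * xbar
  resid <- Lmat - intercept - slope %o% x
  rss <- rowSums(W * resid^2)
  sigma2 <- rss / (n - 2)
  se <- pmax(sqrt(sigma2 / Sxx), se_floor)
  list(slope = slope, se = se, intercept = intercept)
}

#' Score every variant of a condition
#'
#' Computes one (score, se) per variant and lineage from its count series
#' against the summed wild-type reference series — log-ratios followed by
#' the weighted slope — then combines lineages by inverse-variance
#' (fixed-effect) averaging:
#' \deqn{\hat s = \frac{\sum_i s_i / \sigma_i^2}{\sum_i 1/\sigma_i^2},
#'   \qquad \mathrm{se}(\hat s) = \Big(\sum_i 1/\sigma_i^2\Big)^{-1/2}.}
#' Variants scored in fewer lineages than supplied are carried with
#' `flagged = TRUE`.
#'
#' @param variant_tables a variant-level [count_table()] or a list of them
#'   (one per lineage).
#' @param wt_series wild-type reference count vector, or list of vectors
#'   matching `variant_tables`.
#' @param times normalized times (default `t / t_max` from the table's
#'   hour labels).
#' @return data frame: `variant`, `score`, `se`, `n_lineages`, `flagged`.
#' @export
score_condition <- function(variant_tables, wt_series, times = NULL) {
  if (inherits(variant_tables, "count_table")) {
    variant_tables <- list(variant_tables)
    wt_series <- list(wt_series)
  }
  assert_that(length(variant_tables) >= 1 &&
                all(vapply(variant_tables, nrow, integer(1)) > 0),
              "empty count table")
  assert_that(length(wt_series) == length(variant_tables),
              "one wild-type series per lineage required")

  per_lineage <- lapply(seq_along(variant_tables), function(i) {
    tab <- variant_tables[[i]]
    wt <- wt_series[[i]]
    tp <- ct_timepoints(tab)
    x <- times %||% (tp / max(tp))
    m <- ct_counts(tab)
    assert_that(length(wt) == ncol(m),
                "wild-type series length must match timepoints")
    Lmat <- log(sweep(m + 0.5, 2, wt + 0.5, "/"))
    Vmat <- sweep(1 / (m + 0.5), 2, 1 / (wt + 0.5), "+")
    fit <- wls_slope_matrix(Lmat, Vmat, x)
    data.frame(variant = tab$id, score = fit$slope, se = fit$se,
               stringsAsFactors = FALSE)
  })

  all_ids <- sort(unique(unlist(lapply(per_lineage, `[[`, "variant"))))
  num <- den <- nlin <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (pl in per_lineage) {
    i <- match(pl$variant, all_ids)
    wv <- 1 / pl$se^2
    num[i] <- num[i] + pl$score * wv
    den[i] <- den[i] + wv
    nlin[i] <- nlin[i] + 1
  }
  data.frame(variant = all_ids,
             score = num / den,
             se = sqrt(1 / den),
             n_lineages = as.integer(nlin),
             flagged = nlin < length(variant_tables),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Centre scores on the wild-type distribution
#'
#' Subtracts the mean wild-type pseudo-variant score from every score so
#' the average wild type sits exactly at 0.
#'
#' @param raw score data frame with a `score` column.
#' @param wt_pseudovariant_scores numeric vector of wild-type
#'   pseudo-variant scores (length >= 1).
#' @return The table with shifted scores; the offset is attached as
#'   attribute `wt_offset`.
#' @export
normalize_to_wt <- function(raw, wt_pseudovariant_scores) {
  assert_that(length(wt_pseudovariant_scores) >= 1,
              "no wild-type pseudo-variant scores")
  offset <- mean(wt_pseudovariant_scores)
  raw$score <- raw$score - offset
  attr(raw, "wt_offset") <- offset
  raw
}

#' Two-sided z-test p-value against a reference score
#'
#' \deqn{z = \frac{s - s_{ref}}{\sqrt{se^2 + se_{ref}^2}}, \qquad
#'       p = 2\,(1 - \Phi(|z|)).}
#'
#' @param score,se variant score and standard error (vectorised).
#' @param ref_score,ref_se reference (null) score and its standard error.
#' @return p-values in `[0, 1]`.
#' @export
null_pvalue <- function(score, se, ref_score, ref_se) {
  assert_that(all(se > 0) && all(ref_se > 0), "standard errors must be > 0")
  z <- (score - ref_score) / sqrt(se^2 + ref_se^2)
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; `NA`/`NaN` entries are
#' excluded from the adjustment and propagated as missing.
#'
#' @param p p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "fdr")
  q
}

#' Split-half barcode reproducibility
#'
#' Randomly halves every variant's barcodes (and the wild-type barcodes),
#' scores each half independently against its own wild-type reference,
#' and reports the Pearson correlation of the two half-scores across
#' variants, overall and stratified by barcode multiplicity and T = 0
#' coverage.
#'
#' @param table filtered, timepoint-selected barcode-level
#'   [count_table()].
#' @param map barcode-variant map.
#' @param seed seed for the halving.
#' @param min_barcodes minimum barcodes per variant to take part.
#' @return list: `r`, `n_variants`, `half_scores` (variant, score1,
#'   score2, n_barcodes, t0_coverage), `by_n_barcodes`, `by_coverage`
#'   (stratified correlations).
#' @export
split_half_reproducibility <- function(table, map, seed = 1L,
                                       min_barcodes = 2L) {
  assert_that(ct_level(table) == "barcode", "barcode-level table required")
  idx <- match(table$id, map$barcode)
  if (anyNA(idx)) stop_y1h("count table contains unmapped barcodes")
  variant <- map$variant[idx]
  is_wt <- map$variant_class[idx] == "wild_type"

  nb <- base::table(variant[!is_wt])
  eligible <- names(nb)[nb >= min_barcodes]
  if (!length(eligible)) stop_y1h("no variant has enough barcodes to split")

  half <- with_seed(derive_seed(seed, "split_half"), {
    h <- integer(nrow(table))
    for (v in c(eligible, "__WT__")) {
      rows <- if (v == "__WT__") which(is_wt) else
        which(variant == v & !is_wt)
      if (length(rows) < 2) next
      h[rows] <- sample(rep_len(1:2, length(rows)))
    }
    h
  })

  m <- ct_counts(table)
  score_half <- function(k) {
    keep <- half == k & !is_wt & variant %in% eligible
    vm <- rowsum(m[keep, , drop = FALSE], variant[keep])
    wt <- colSums(m[half == k & is_wt, , drop = FALSE])
    tab <- ct_rebuild(table, vm, rownames(vm), level = "variant")
    score_condition(tab, wt)
  }
  s1 <- score_half(1)
  s2 <- score_half(2)
  shared <- intersect(s1$variant, s2$variant)
  assert_that(length(shared) >= 3, "too few variants scored in both halves")
  hs <- data.frame(variant = shared,
                   score1 = s1$score[match(shared, s1$variant)],
                   score2 = s2$score[match(shared, s2$variant)],
                   n_barcodes = as.integer(nb[shared]),
                   t0_coverage = rowsum(m[!is_wt, 1, drop = FALSE],
                                        variant[!is_wt])[shared, 1] /
                     as.integer(nb[shared]),
                   stringsAsFactors = FALSE)

  strat <- function(fac) {
    out <- lapply(split(hs, fac), function(d) {
      if (nrow(d) < 3) return(NULL)
      data.frame(stratum = NA_character_, n = nrow(d),
                 r = stats::cor(d$score1, d$score2))
    })
    keep <- !vapply(out, is.null, logical(1))
    res <- do.call(rbind, out[keep])
    if (!is.null(res)) res$stratum <- names(out)[keep]
    res
  }
  bc_bins <- cut(hs$n_barcodes, c(1, 5, 10, 20, Inf),
                 labels = c("2-5", "6-10", "11-20", ">20"))
  cov_bins <- cut(hs$t0_coverage, stats::quantile(hs$t0_coverage,
                                                  c(0, .25, .5, .75, 1)),
                  include.lowest = TRUE)
  list(r = stats::cor(hs$score1, hs$score2),
       n_variants = nrow(hs),
       half_scores = hs,
       by_n_barcodes = strat(bc_bins),
       by_coverage = strat(cov_bins))
}

#' Correlate scores between two conditions
#'
#' @param tableA,tableB score data frames with `variant` and `score`.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: `r`, `n_shared`, `method`.
#' @export
correlate_conditions <- function(tableA, tableB,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(tableA$variant, tableB$variant)
  assert_that(length(shared) >= 3, "need at least 3 shared variants")
  r <- stats::cor(tableA$score[match(shared, tableA$variant)],
                  tableB$score[match(shared, tableB$variant)],
                  method = method)
  list(r = r, n_shared = length(shared), method = method)
}
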