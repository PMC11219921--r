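#' Category rule set for functional classification
#'
#' Holds the FDR threshold and the mean nonsense score that anchor the
#' five functional categories: increased, neutral, hypomorphic, lof
#' (complete loss of function) and toxic.
#'
#' @param alpha FDR threshold on q-values (in `(0, 1)`).
#' @param mean_nonsense mean fitness score of nonsense variants; if `NULL`
#'   it is computed from the scored table at assignment time.
#' @return A `category_rules` list.
#' @export
category_rules <- function(alpha = 0.05, mean_nonsense = NULL) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (!is.null(mean_nonsense)) {
    assert_that(is.finite(mean_nonsense), "mean_nonsense must be finite")
  }
  structure(list(alpha = alpha, mean_nonsense = mean_nonsense),
            class = "category_rules")
}

CATEGORY_LEVELS <- c("increased", "neutral", "hypomorphic", "lof", "toxic")

#' Assign functional categories from dual null hypotheses
#'
#' Each scored variant is tested against two nulls — behaves like wild
#' type (`q_wt`) and behaves like a nonsense variant (`q_nonsense`) — and
#' classified by the first matching rule, in order:
#' \enumerate{
#'   \item increased: score > 0 and `q_wt` < alpha;
#'   \item toxic: score < mean nonsense score and `q_nonsense` < alpha;
#'   \item hypomorphic: 0 > score > mean nonsense score and `q_wt` < alpha
#'     and `q_nonsense` < alpha;
#'   \item neutral: `q_wt` >= alpha;
#'   \item lof: `q_nonsense` >= alpha.
#' }
#' The published conditions are not mutually exclusive; evaluating
#' evidence-bearing rules before the two fail-to-reject rules (neutral
#' preferred over lof when both nulls stand) makes the assignment total
#' and deterministic. Rows matched by more than one rule are flagged in
#' `category_multi_match`.
#'
#' @param table score data frame with `score`, `q_wt`, `q_nonsense` and
#'   (if `rules$mean_nonsense` is NULL) a `variant_class` column
#'   containing nonsense variants.
#' @param rules a [category_rules()].
#' @return `table` with `category` and `category_multi_match` columns;
#'   per-category counts in attribute `category_counts`.
#' @export
assign_categories <- function(table, rules = category_rules()) {
  assert_that(all(c("score", "q_wt", "q_nonsense") %in% names(table)),
              "score, q_wt and q_nonsense columns required")
  mean_nonsense <- rules$mean_nonsense
  if (is.null(mean_nonsense)) {
    assert_that("variant_class" %in% names(table),
                "variant_class needed to compute the nonsense mean")
    ns <- table$score[table$variant_class == "nonsense"]
    assert_that(length(ns) >= 1, "no nonsense variants to anchor rules")
    mean_nonsense <- mean(ns)
  }
  a <- rules$alpha
  match_mat <- cbind(
    increased   = table$score > 0 & table$q_wt < a,
    toxic       = table$score < mean_nonsense & table$q_nonsense < a,
    hypomorphic = table$score < 0 & table$score > mean_nonsense &
                  table$q_wt < a & table$q_nonsense < a,
    neutral     = table$q_wt >= a,
    lof         = table$q_nonsense >= a)
  scored <- stats::complete.cases(table[, c("score", "q_wt", "q_nonsense")])
  first <- apply(match_mat, 1, function(r) which(r)[1])
  cat <- colnames(match_mat)[first]
  cat[!scored] <- NA_character_
  table$category <- cat
  table$category_multi_match <- rowSums(match_mat, na.rm = TRUE) > 1 & scored
  counts <- base::table(factor(cat[scored], levels = CATEGORY_LEVELS))
  attr(table, "category_counts") <- counts
  attr(table, "mean_nonsense") <- mean_nonsense
  table
}

#' Pairwise rank-sum comparisons between groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test for every pair of
#' groups, Benjamini-Hochberg adjusted across pairs. The exact null
#' distribution is used when both groups have at most 10 observations and
#' no ties; otherwise the tie-corrected normal approximation.
#'
#' @param values numeric observations.
#' @param groups grouping factor, same length (>= 2 groups of >= 2).
#' @param alternative passed to [stats::wilcox.test()].
#' @return data frame: `group_a`, `group_b`, `n_a`, `n_b`, `median_a`,
#'   `median_b`, `statistic` (Mann-Whitney U of group_a), `p`, `q`.
#' @export
group_compare <- function(values, groups, alternative = "two.sided") {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  lv <- levels(groups)
  assert_that(length(lv) >= 2, "need at least 2 groups")
  sizes <- base::table(groups)
  assert_that(all(sizes >= 2), "every group needs >= 2 observations")

  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    va <- values[groups == ga]; vb <- values[groups == gb]
    exact <- length(va) <= 10 && length(vb) <= 10 &&
      !any(duplicated(c(va, vb)))
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = exact,
                                              correct = FALSE,
                                              alternative = alternative))
    data.frame(group_a = ga, group_b = gb,
               n_a = length(va), n_b = length(vb),
               median_a = stats::median(va), median_b = stats::median(vb),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Compare absolute scores across clinical phenotype groups
#'
#' Pairwise rank-sum tests (BH-adjusted) of absolute fitness scores among
#' mild/classical-aniridia-linked variants (group 1), atypical-phenotype
#' variants (group 2) and nonsense variants; group 3 (undetermined) is
#' excluded.
#'
#' @param abs_scores score data frame with `variant`, `score` (absolute
#'   values) and `variant_class`.
#' @param labels clinical label set with `variant`, `label`,
#'   `phenotype_group`.
#' @return `group_compare` output over groups
#'   `{mild_classical, atypical, nonsense}` with group sizes.
#' @export
phenotype_compare <- function(abs_scores, labels) {
  path <- labels[labels$label == "pathogenic" &
                   labels$phenotype_group %in% c("1", "2"), , drop = FALSE]
  grp <- stats::setNames(ifelse(path$phenotype_group == "1",
                                "mild_classical", "atypical"),
                         path$variant)
  idx <- match(names(grp), abs_scores$variant)
  keep <- !is.na(idx)
  values <- abs_scores$score[idx[keep]]
  groups <- unname(grp[keep])

  ns <- abs_scores$score[abs_scores$variant_class == "nonsense"]
  assert_that(length(ns) >= 2, "nonsense comparator group missing")
  values <- c(values, ns)
  groups <- c(groups, rep("nonsense", length(ns)))
  assert_that(sum(groups == "mild_classical") >= 2 &&
                sum(groups == "atypical") >= 2,
              "phenotype groups 1 and 2 must both be populated")
  group_compare(values, groups)
}
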