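#' Default ACMG/AMP evidence-strength boundaries
#'
#' oddsPath boundaries from the recommended calibration of functional
#' evidence: pathogenic supporting/moderate/strong/very strong at 2.1,
#' 4.3, 18.7 and 350; benign mirrored at 0.48, 0.23, 0.053 and 0.0029.
#'
#' @return data frame: `tier`, `direction`, `boundary` (oddsPath scale).
#' @export
acmg_tier_boundaries <- function() {
  data.frame(
    tier = c("path_supporting", "path_moderate", "path_strong",
             "path_very_strong",
             "benign_supporting", "benign_moderate", "benign_strong",
             "benign_very_strong"),
    direction = rep(c("pathogenic", "benign"), each = 4),
    boundary = c(2.1, 4.3, 18.7, 350, 0.48, 0.23, 0.053, 0.0029),
    stringsAsFactors = FALSE)
}

#' Invert a prediction scale
#'
#' Reverses the orientation of a predictor while preserving its range:
#' `inverted = min(x) - x + max(x)`. Applying it twice is the identity.
#'
#' @param predictions numeric scores (NA allowed, preserved).
#' @return inverted scores.
#' @export
orient_scores <- function(predictions) {
  ok <- is.finite(predictions)
  assert_that(any(ok), "need at least one finite prediction")
  min(predictions[ok]) - predictions + max(predictions[ok])
}

#' Absolute fitness scores
#'
#' Replaces each score by its absolute value (gain and loss of function
#' treated as equally non-wild-type); standard errors are carried
#' unchanged and an `ABS` marker is appended to the condition metadata.
#'
#' @param table score data frame with a `score` column.
#' @return table with `score = |score|`.
#' @export
abs_scores <- function(table) {
  table$score <- abs(table$score)
  cond <- attr(table, "condition")
  if (!is.null(cond) && !grepl("_ABS$", cond)) {
    attr(table, "condition") <- paste0(cond, "_ABS")
  } else if (is.null(cond)) {
    attr(table, "condition") <- "ABS"
  }
  table
}

#' ROC analysis of scores against clinical labels
#'
#' Sweeps thresholds over the score range predicting pathogenic for
#' `score >= threshold`; AUC comes from the tie-corrected rank
#' (Mann-Whitney) statistic with pathogenic as the positive class. The
#' optimal threshold maximises Youden's statistic (tpr - fpr, the point
#' closest to the top-left corner); ties go to the higher (more specific)
#' threshold. Accuracy at the optimum is
#' (true positives + true negatives) / total.
#'
#' @param scores numeric scores, oriented so higher = more pathogenic
#'   (see [orient_scores()]).
#' @param labels `"pathogenic"`/`"benign"` (or 1/0), same length.
#' @param min_class minimum class size below which a warning is issued
#'   (predictor-inclusion rule).
#' @return list: `thresholds`, `tpr`, `fpr`, `auc`, `optimal_threshold`,
#'   `accuracy_at_optimal`, `n_pathogenic`, `n_benign`.
#' @export
roc <- function(scores, labels, min_class = 10L) {
  y <- normalize_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  np <- sum(y == 1); nb <- sum(y == 0)
  assert_that(np >= 1 && nb >= 1, "both classes must be present")
  if (np < min_class || nb < min_class) {
    warning(sprintf("fewer than %d variants in a class (%d pathogenic, %d benign)",
                    min_class, np, nb), call. = FALSE)
  }

  # AUC by mean ranks (handles ties as half-concordance).
  rk <- rank(scores)
  auc <- (sum(rk[y == 1]) - np * (np + 1) / 2) / (np * nb)

  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  youden <- tpr - fpr
  best <- which(youden == max(youden))[1]   # first sweep hit = highest thr
  acc <- (sum(scores[y == 1] >= thr[best]) +
            sum(scores[y == 0] < thr[best])) / length(y)

  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
       optimal_threshold = thr[best], accuracy_at_optimal = acc,
       n_pathogenic = np, n_benign = nb)
}

normalize_labels <- function(labels) {
  if (is.numeric(labels)) {
    assert_that(all(labels %in% c(0, 1)), "numeric labels must be 0/1")
    return(as.integer(labels))
  }
  assert_that(all(labels %in% c("pathogenic", "benign")),
              "labels must be pathogenic/benign or 0/1")
  as.integer(labels == "pathogenic")
}

#' Dynamic-window oddsPath calibration
#'
#' Orders labelled variants along the score axis (descending for the
#' pathogenic sweep, ascending for the benign sweep; ties broken by
#' variant id) and grows a rank-symmetric window around each labelled
#' variant — one variant at a time, alternating sides, truncating at the
#' ends — until it holds at least `min_window` variants including at
#' least `min_minority` members of the (globally) minority class.
#'
#' With `P1` the prior proportion of the direction class and the benign
#' count weighted by `w = ((1 - P1) * n_pathogenic) / (n_benign * P1)`
#' (mirrored for the benign sweep), each window's posterior is
#' `P2 = n_class_win / (n_class_win + w * n_other_win)` and its evidence
#' odds `oddsPath = (P2 * (1 - P1)) / ((1 - P2) * P1)`.
#'
#' @param scores numeric scores of labelled variants (for the usual
#'   absolute-score calibration, pass `abs(score)`).
#' @param labels `"pathogenic"`/`"benign"`, same length.
#' @param variants variant ids (tie-break; default index).
#' @param min_window minimum window size.
#' @param min_minority minimum minority-class members per window.
#' @param direction `"pathogenic"` or `"benign"` sweep.
#' @return `evidence_calibration` list: `windows` (ordered data frame
#'   with per-variant window stats and oddsPath), `P1`, `w`, `direction`,
#'   `n_pathogenic`, `n_benign`, `min_window`, `min_minority`.
#' @export
oddspath_windows <- function(scores, labels, variants = NULL,
                             min_window = 20L, min_minority = 2L,
                             direction = c("pathogenic", "benign")) {
  direction <- match.arg(direction)
  y <- normalize_labels(labels)
  n <- length(scores)
  assert_that(length(y) == n, "scores and labels must match")
  assert_that(n >= min_window,
              "fewer labelled variants than the minimum window size")
  variants <- variants %||% as.character(seq_len(n))
  np <- sum(y == 1); nb <- sum(y == 0)
  assert_that(np >= 1 && nb >= 1, "both classes must be present")
  minority <- if (np <= nb) 1L else 0L

  ord <- if (direction == "pathogenic") order(-scores, variants)
         else order(scores, variants)
  sc <- scores[ord]; yy <- y[ord]; vv <- variants[ord]

  P1 <- if (direction == "pathogenic") np / n else nb / n
  w <- if (direction == "pathogenic") ((1 - P1) * np) / (nb * P1)
       else ((1 - P1) * nb) / (np * P1)

  lo <- hi <- integer(n)
  for (i in seq_len(n)) {
    l <- r <- i
    add_left <- TRUE
    repeat {
      size <- r - l + 1
      nmin <- sum(yy[l:r] == minority)
      if (size >= min_window && nmin >= min_minority) break
      if (l == 1 && r == n) {
        stop_y1h("window constraints unsatisfiable on the full list")
      }
      grew <- FALSE
      for (attempt in 1:2) {
        if (add_left && l > 1) { l <- l - 1; grew <- TRUE }
        else if (!add_left && r < n) { r <- r + 1; grew <- TRUE }
        add_left <- !add_left
        if (grew) break
      }
    }
    lo[i] <- l; hi[i] <- r
  }

  np_w <- vapply(seq_len(n), function(i) sum(yy[lo[i]:hi[i]] == 1L),
                 numeric(1))
  nb_w <- vapply(seq_len(n), function(i) sum(yy[lo[i]:hi[i]] == 0L),
                 numeric(1))
  if (direction == "pathogenic") {
    P2 <- np_w / (np_w + w * nb_w)
  } else {
    P2 <- nb_w / (nb_w + w * np_w)
  }
  oddspath <- oddspath_from_posteriors(P1, P2)

  windows <- data.frame(variant = vv, score = sc,
                        label = ifelse(yy == 1, "pathogenic", "benign"),
                        window_size = hi - lo + 1,
                        n_pathogenic = as.integer(np_w),
                        n_benign = as.integer(nb_w),
                        posterior = P2, oddspath = oddspath,
                        stringsAsFactors = FALSE)
  structure(list(windows = windows, P1 = P1, w = w, direction = direction,
                 n_pathogenic = np, n_benign = nb,
                 min_window = as.integer(min_window),
                 min_minority = as.integer(min_minority)),
            class = "evidence_calibration")
}

#' oddsPath from prior and posterior
#'
#' \deqn{\mathrm{oddsPath} = \frac{P2 (1 - P1)}{(1 - P2) P1}.}
#'
#' @param P1 prior probability of the class.
#' @param P2 posterior probability within a window (vectorised).
#' @return oddsPath values (> 0; `Inf` when P2 = 1).
#' @export
oddspath_from_posteriors <- function(P1, P2) {
  assert_that(all(P1 > 0 & P1 < 1), "P1 must be in (0, 1)")
  (P2 * (1 - P1)) / ((1 - P2) * P1)
}

#' Score thresholds per evidence tier
#'
#' For each tier boundary, walks the sweep from the most extreme labelled
#' variant inward and takes the maximal prefix in which every window's
#' oddsPath meets the boundary (sustained-crossing rule); the threshold
#' is the least-extreme score in that prefix. `rule = "first"` instead
#' takes the least-extreme labelled variant whose own window meets the
#' boundary. Pathogenic tiers come from the pathogenic sweep, benign
#' tiers from the benign sweep; benign boundaries stated on the oddsPath
#' scale (<= 0.48 etc.) are inverted to the benign-odds scale internally.
#'
#' @param calib_path pathogenic-direction [oddspath_windows()] result.
#' @param calib_benign benign-direction result (or `NULL` to skip benign
#'   tiers).
#' @param boundaries tier table as from [acmg_tier_boundaries()].
#' @param rule `"sustained"` or `"first"` crossing.
#' @return data frame: `tier`, `direction`, `boundary`, `threshold`
#'   (NA when never met), `n_labelled_meeting`.
#' @export
evidence_thresholds <- function(calib_path, calib_benign = NULL,
                                boundaries = acmg_tier_boundaries(),
                                rule = c("sustained", "first")) {
  rule <- match.arg(rule)
  one <- function(calib, bnd) {
    odds <- calib$windows$oddspath
    meets <- odds >= bnd
    k <- if (rule == "sustained") {
      if (!length(meets) || !meets[1]) 0L else {
        runs <- rle(meets)
        runs$lengths[1]
      }
    } else {
      if (any(meets)) max(which(meets)) else 0L
    }
    if (k == 0L) {
      return(c(threshold = NA_real_, n = 0))
    }
    c(threshold = calib$windows$score[k], n = k)
  }

  rows <- lapply(seq_len(nrow(boundaries)), function(i) {
    dir <- boundaries$direction[i]
    bnd <- boundaries$boundary[i]
    calib <- if (dir == "pathogenic") calib_path else calib_benign
    if (is.null(calib)) return(NULL)
    assert_that(calib$direction == dir,
                "calibration direction does not match boundary direction")
    eff_bnd <- if (dir == "benign") 1 / bnd else bnd
    r <- one(calib, eff_bnd)
    data.frame(tier = boundaries$tier[i], direction = dir, boundary = bnd,
               threshold = unname(r["threshold"]),
               n_labelled_meeting = as.integer(r["n"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Apply evidence thresholds to a full score table
#'
#' Assigns each scored variant the strongest tier whose threshold it
#' meets: pathogenic tiers for scores at or beyond (>=) the pathogenic
#' threshold, benign tiers for scores at or beyond (<=) the benign
#' threshold; everything else is indeterminate. A variant exactly at a
#' threshold receives the stronger tier.
#'
#' @param table score data frame (`variant`, `score`; scores on the same
#'   scale the calibration used, typically absolute scores).
#' @param thresholds output of [evidence_thresholds()].
#' @return `table` with a `tier` column; counts in attribute
#'   `tier_counts`.
#' @export
apply_evidence <- function(table, thresholds) {
  strength <- c(very_strong = 4, strong = 3, moderate = 2, supporting = 1)
  tier_rank <- function(t) strength[sub("^(path|benign)_", "", t)]

  tier <- rep("indeterminate", nrow(table))
  assign_dir <- function(dir, cmp) {
    th <- thresholds[thresholds$direction == dir &
                       !is.na(thresholds$threshold), , drop = FALSE]
    if (!nrow(th)) return()
    th <- th[order(tier_rank(th$tier)), , drop = FALSE]  # weak -> strong
    for (i in seq_len(nrow(th))) {
      hit <- !is.na(table$score) & cmp(table$score, th$threshold[i])
      tier[hit] <<- th$tier[i]
    }
  }
  assign_dir("benign", `<=`)
  assign_dir("pathogenic", `>=`)

  table$tier <- tier
  lev <- c(thresholds$tier, "indeterminate")
  attr(table, "tier_counts") <- base::table(factor(tier, levels = lev))
  table
}
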