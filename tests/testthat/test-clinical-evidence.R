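test_that("orient_scores applies the min - x + max inversion", {
  expect_equal(orient_scores(c(1, 2, 3)), c(3, 2, 1))
  expect_equal(orient_scores(c(7, 7, 7)), c(7, 7, 7))
  x <- c(0.3, -2, 5, 1.1)
  expect_equal(orient_scores(orient_scores(x)), x)
  expect_equal(order(orient_scores(x)), rev(order(x)))
  expect_error(orient_scores(c(NA_real_, NA_real_)), "finite")
})

test_that("abs_scores takes magnitudes and is idempotent", {
  tab <- data.frame(variant = c("a", "b", "c"), score = c(-2.5, 0, 1.1),
                    se = c(0.1, 0.2, 0.3))
  out <- abs_scores(tab)
  expect_equal(out$score, c(2.5, 0, 1.1))
  expect_equal(out$se, tab$se)
  expect_equal(abs_scores(out)$score, out$score)
})

test_that("roc computes AUC, the Youden threshold and accuracy", {
  perfect <- roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), min_class = 1)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$accuracy_at_optimal, 1.0)
  expect_equal(perfect$optimal_threshold, 0.8)  # pathogenic >= threshold

  mixed <- roc(c(0.9, 0.3, 0.8, 0.1), c(1, 1, 0, 0), min_class = 1)
  expect_equal(mixed$auc, 0.75)

  # AUC invariant under strictly monotone transforms
  set.seed(12)
  sc <- rnorm(60); y <- rbinom(60, 1, plogis(sc))
  expect_equal(roc(sc, y)$auc, roc(exp(sc), y)$auc)

  # tpr/fpr non-decreasing along the sweep
  r <- roc(sc, y)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))

  expect_warning(roc(c(1, 2, 3), c(1, 0, 0)), "fewer than")
  expect_error(roc(c(1, 2), c(1, 1)), "both classes")
})

test_that("roc AUC equals the concordant-pair oracle with ties", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(10:50, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(suppressWarnings(roc(sc, y))$auc, auc_oracle(sc, y))
  }
})

test_that("oddsPath formula fixed points hold", {
  expect_equal(oddspath_from_posteriors(0.25, 0.25), 1)
  expect_equal(oddspath_from_posteriors(0.2, 0.8), 16)
  # strictly increasing in P2 at fixed P1
  p2 <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(oddspath_from_posteriors(0.3, p2)) > 0))
})

test_that("oddspath_windows builds windows meeting both minima", {
  set.seed(5)
  n <- 200
  sc <- c(rnorm(70, 2.2, 0.6), rnorm(130, 0.6, 0.4))
  lb <- rep(c("pathogenic", "benign"), c(70, 130))
  cal <- oddspath_windows(sc, lb, sprintf("v%03d", 1:n))
  w <- cal$windows
  expect_equal(nrow(w), n)
  expect_true(all(w$window_size >= 20))
  minority <- ifelse(cal$n_pathogenic <= cal$n_benign,
                     "n_pathogenic", "n_benign")
  expect_true(all(w[[minority]] >= 2))
  expect_true(all(w$window_size == w$n_pathogenic + w$n_benign))
  expect_true(all(diff(w$score) <= 0))      # descending sweep
  expect_equal(cal$P1, 70 / 200)
  # balanced classes: w = n_pathogenic / n_benign
  cal2 <- oddspath_windows(c(sc, sc), rep(c("pathogenic", "benign"),
                                          each = 200))
  expect_equal(cal2$w, 1)
  expect_error(oddspath_windows(sc[1:10], lb[1:10]), "minimum window")
})

test_that("benign sweep mirrors the pathogenic sweep", {
  set.seed(9)
  sc <- rnorm(120)
  lb <- ifelse(runif(120) < plogis(2 * sc), "pathogenic", "benign")
  cp <- oddspath_windows(sc, lb, sprintf("v%03d", 1:120),
                         direction = "pathogenic")
  cb <- oddspath_windows(sc, lb, sprintf("v%03d", 1:120),
                         direction = "benign")
  expect_equal(cb$P1, 1 - cp$P1)
  expect_true(all(diff(cb$windows$score) >= 0))   # ascending sweep
  # same variant, same window contents -> benign odds = 1 / pathogenic odds
  shared <- merge(cp$windows, cb$windows, by = "variant")
  same_win <- shared[shared$window_size.x == shared$window_size.y &
                       shared$n_pathogenic.x == shared$n_pathogenic.y, ]
  expect_gt(nrow(same_win), 0)
  expect_equal(same_win$oddspath.y, 1 / same_win$oddspath.x)
})

test_that("evidence thresholds separate clean classes and nest", {
  set.seed(31)
  n <- 150
  sc <- c(runif(60, 2, 4), runif(90, 0, 1))   # gap between 1 and 2
  lb <- rep(c("pathogenic", "benign"), c(60, 90))
  tab <- data.frame(variant = sprintf("v%03d", 1:n), score = sc,
                    stringsAsFactors = FALSE)
  labels <- data.frame(variant = tab$variant, label = lb,
                       stringsAsFactors = FALSE)
  res <- calibrate_evidence(tab, labels)
  th <- res$thresholds
  path_mod <- th$threshold[th$tier == "path_moderate"]
  expect_gt(path_mod, 1)                     # sits between the classes
  expect_lt(path_mod, 4)
  ben_mod <- th$threshold[th$tier == "benign_moderate"]
  expect_lt(ben_mod, 2)

  # nesting: moderate threshold at least as extreme as supporting
  expect_gte(path_mod, th$threshold[th$tier == "path_supporting"] - 1e-12)
  expect_lte(ben_mod, th$threshold[th$tier == "benign_supporting"] + 1e-12)

  ev <- res$evidence
  expect_equal(sum(attr(ev, "tier_counts")), nrow(ev))
  # the extremes are never indeterminate under clean separation
  expect_false(any(ev$tier[ev$score > 3] == "indeterminate"))
  expect_false(any(ev$tier[ev$score < 0.5] == "indeterminate"))
})

test_that("labels independent of score leave everything indeterminate", {
  set.seed(4)
  n <- 400
  tab <- data.frame(variant = sprintf("v%04d", 1:n), score = runif(n),
                    stringsAsFactors = FALSE)
  labels <- data.frame(variant = tab$variant,
                       label = sample(rep(c("pathogenic", "benign"), n / 2)),
                       stringsAsFactors = FALSE)
  res <- calibrate_evidence(tab, labels)
  # oddsPath hovers near 1: a short lucky run at an extreme can clear the
  # supporting boundary, but nothing stronger, and nearly everything stays
  # indeterminate
  expect_gt(mean(res$evidence$tier == "indeterminate"), 0.9)
  strong <- c("path_moderate", "path_strong", "path_very_strong",
              "benign_moderate", "benign_strong", "benign_very_strong")
  expect_true(all(is.na(
    res$thresholds$threshold[res$thresholds$tier %in% strong])))
  expect_lt(abs(log(median(res$calib_path$windows$oddspath))), log(1.7))
})

test_that("apply_evidence assigns the stronger tier at an exact threshold", {
  th <- data.frame(tier = c("path_supporting", "path_moderate",
                            "benign_supporting"),
                   direction = c("pathogenic", "pathogenic", "benign"),
                   boundary = c(2.1, 4.3, 0.48),
                   threshold = c(1.0, 2.0, 0.2),
                   stringsAsFactors = FALSE)
  tab <- data.frame(variant = letters[1:5],
                    score = c(2.0, 1.5, 0.5, 0.2, 3.0))
  out <- apply_evidence(tab, th)
  expect_equal(out$tier, c("path_moderate",     # exactly at 2.0 -> stronger
                           "path_supporting", "indeterminate",
                           "benign_supporting", "path_moderate"))
  expect_equal(sum(attr(out, "tier_counts")), 5)
})

test_that("the calibration pipeline recovers a known monotone link", {
  # labels drawn from |s| through a logistic link; at the supporting
  # boundary the local class ratio has a closed form -> true crossing
  lib <- tiny_sim()$lib
  cfg <- tiny_sim()$cfg
  labels <- gen_labels(lib$effects, cfg, n = 450, method = "logistic")
  eff <- lib$effects[match(labels$variant, lib$effects$variant), ]
  tab <- data.frame(variant = labels$variant, score = abs(eff$s_plus),
                    stringsAsFactors = FALSE)
  res <- calibrate_evidence(tab, labels)
  w <- res$calib_path$windows
  expect_true(all(w$window_size >= 20))
  # pathogenic fraction among top-ranked scores exceeds the prior
  top <- w[seq_len(40), ]
  expect_gt(mean(top$label == "pathogenic"), res$calib_path$P1)
})
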