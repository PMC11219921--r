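test_that("log_ratios applies the 0.5 pseudocount formula", {
  lr0 <- log_ratios(0, 0)
  expect_equal(lr0$L, 0)
  expect_equal(lr0$V, 4)

  lr <- log_ratios(c(100, 200, 400, 800), c(100, 100, 100, 100))
  expect_equal(lr$L, log(c(100.5, 200.5, 400.5, 800.5) / 100.5))
  expect_equal(lr$L[2:4], c(0.6907, 1.3832, 2.0757), tolerance = 1e-3)
  expect_equal(lr$V, 1 / c(100.5, 200.5, 400.5, 800.5) + 1 / 100.5)

  same <- log_ratios(c(5, 9, 2), c(5, 9, 2))
  expect_true(all(same$L == 0))
  expect_error(log_ratios(1:3, 1:4), "length")
})

test_that("wls_slope matches closed forms and is weight-scale invariant", {
  x <- c(0, 1/3, 2/3, 1)
  exact <- wls_slope(c(0, 1, 2, 3) * 1, rep(1, 4), x)
  expect_equal(exact$slope, 3)
  expect_equal(exact$se, 1e-8)  # residuals vanish -> floor

  fit <- wls_slope(c(0, 1, 1, 2), rep(1, 4), x)
  expect_equal(fit$slope, 1.8)
  # independent oracle: ordinary least squares via lm
  olm <- lm(c(0, 1, 1, 2) ~ x)
  expect_equal(fit$slope, unname(coef(olm)[2]))
  expect_equal(fit$se, unname(sqrt(diag(vcov(olm)))[2]))

  # doubling all weights (halving V) changes neither slope nor se
  V <- c(0.2, 0.5, 0.3, 0.9)
  f1 <- wls_slope(c(0, 1, 1, 2), V, x)
  f2 <- wls_slope(c(0, 1, 1, 2), V / 2, x)
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$se, f2$se)

  expect_error(wls_slope(c(0, 1), c(1, 1), c(0, 1)), "3 timepoints")
  expect_error(wls_slope(c(0, 1, 2), c(1, 1, 1), c(1, 1, 1)), "identical")

  # weighted fit against lm's weighted least squares on random cases
  for (seed in 1:20) {
    set.seed(seed)
    L <- rnorm(5); V <- runif(5, 0.1, 2); xs <- sort(runif(5))
    fit <- wls_slope(L, V, xs)
    ref <- lm(L ~ xs, weights = 1 / V)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-10)
  }
})

test_that("score_condition scores variants against WT and combines lineages", {
  # equal variant and WT series -> exactly 0
  tab <- count_table(rbind(c(50, 80, 120, 200)), "v1", c(0, 12, 24, 36))
  s <- score_condition(tab, c(50, 80, 120, 200))
  expect_equal(s$score, 0)

  # single lineage: combination is the identity
  two <- count_table(rbind(c(100, 150, 210, 300), c(90, 60, 40, 25)),
                     c("a", "b"), c(0, 12, 24, 36))
  wt <- c(100, 100, 100, 100)
  solo <- score_condition(two, wt)
  both <- score_condition(list(two, two), list(wt, wt))
  expect_equal(both$score, solo$score)
  expect_equal(both$se, solo$se / sqrt(2))

  # two lineages with equal se -> combined score is the simple mean
  tabA <- count_table(rbind(c(100, 200, 400, 800)), "v", c(0, 12, 24, 36))
  tabB <- count_table(rbind(c(800, 400, 200, 100)), "v", c(0, 12, 24, 36))
  sA <- score_condition(tabA, wt); sB <- score_condition(tabB, wt)
  comb <- score_condition(list(tabA, tabB), list(wt, wt))
  wts <- 1 / c(sA$se, sB$se)^2
  expect_equal(comb$score, sum(c(sA$score, sB$score) * wts) / sum(wts))

  # with residual-estimated variance the slope se is invariant to a common
  # rescaling of the weights, so doubling all counts at fixed frequencies
  # can move the se only through the 0.5 pseudocount (order 1e-4): it must
  # never increase materially
  for (seed in 1:10) {
    set.seed(seed)
    v <- rpois(4, 200); w <- rpois(4, 500)
    s1 <- score_condition(count_table(rbind(v), "v", c(0, 12, 24, 36)), w)
    s2 <- score_condition(count_table(rbind(2 * v), "v", c(0, 12, 24, 36)),
                          2 * w)
    expect_lte(s2$se, s1$se * (1 + 5e-3) + 1e-6)
  }
})

test_that("normalize_to_wt centres the wild-type distribution at zero", {
  raw <- data.frame(variant = c("a", "b"), score = c(1.2, -0.3))
  # symmetric WT scores: offset 0, table unchanged
  out0 <- normalize_to_wt(raw, c(0.1, -0.1))
  expect_equal(out0$score, raw$score)

  out <- normalize_to_wt(raw, c(0.4, 0.6))
  expect_equal(out$score, raw$score - 0.5)
  expect_equal(attr(out, "wt_offset"), 0.5)

  # shift invariance: shifting everything by c changes nothing after centring
  shifted <- raw; shifted$score <- raw$score + 2
  out2 <- normalize_to_wt(shifted, c(0.4, 0.6) + 2)
  expect_equal(out2$score, out$score)
  expect_error(normalize_to_wt(raw, numeric(0)), "wild-type")
})

test_that("null_pvalue is a two-sided z-test", {
  expect_equal(null_pvalue(1.5, 0.2, 1.5, 0.3), 1)
  # z = 1.959964 -> p ~ 0.05
  se <- sqrt(0.5)
  expect_equal(null_pvalue(1.959964, se, 0, se), 0.05, tolerance = 1e-6)
  expect_equal(null_pvalue(2, 0.3, 1, 0.4), null_pvalue(1, 0.4, 2, 0.3))
  expect_error(null_pvalue(1, 0, 0, 1), "> 0")
})

test_that("bh_fdr matches the step-up oracle and propagates NA", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.5)))
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(2:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("scores track true selection coefficients on synthetic data", {
  fl <- flat_library(200, 10, 500, seed = 31, depth_per_timepoint = 1e6)
  tab <- simulate_growth(fl$map, fl$effects, fl$cfg, "plus_antibiotic")
  sc <- score_assay(tab, fl$map, seed = 2)
  m <- merge(sc, fl$effects, by = "variant")
  expect_gt(cor(m$score, m$s_plus), 0.95)
  expect_gt(cor(m$score, m$s_plus, method = "spearman"), 0.9)
  # wild-type pseudo-variants centred exactly at 0
  expect_lt(abs(mean(attr(sc, "wt_scores"))), 1e-9)
})

test_that("split-half reproducibility behaves like sampling noise", {
  fl <- flat_library(150, 8, 300, seed = 17, depth_per_timepoint = 2e5)
  tab <- simulate_growth(fl$map, fl$effects, fl$cfg, "plus_antibiotic")
  sh <- split_half_reproducibility(tab, fl$map, seed = 5)
  expect_gt(sh$r, 0.9)
  expect_equal(sh$n_variants, 170)   # 150 missense + 20 nonsense
  expect_true(all(c("score1", "score2") %in% names(sh$half_scores)))

  # near-noiseless counts -> r -> 1
  tab_inf <- simulate_growth(fl$map, fl$effects, fl$cfg, "plus_antibiotic",
                             depth = 1e10, sampling = "expected")
  sh_inf <- split_half_reproducibility(tab_inf, fl$map, seed = 5)
  expect_gt(sh_inf$r, 0.999)

  # permuting one half's variant identities destroys the correlation
  hs <- sh$half_scores
  set.seed(1)
  r_perm <- cor(hs$score1, sample(hs$score2))
  expect_lt(abs(r_perm), 0.25)
})

test_that("correlate_conditions works on the shared-variant intersection", {
  a <- data.frame(variant = c("x", "y", "z", "w"), score = c(1, 2, 3, 4))
  b <- data.frame(variant = c("y", "z", "w", "q"), score = c(-2, -3, -4, 9))
  expect_equal(correlate_conditions(a, a)$r, 1)
  neg <- a; neg$score <- -a$score
  expect_equal(correlate_conditions(a, neg)$r, -1)
  res <- correlate_conditions(a, b)
  expect_equal(res$n_shared, 3)
  expect_equal(res$r, -1)
  # spearman is invariant under a monotone transform of either table
  bmono <- b; bmono$score <- exp(b$score)
  expect_equal(correlate_conditions(a, b, "spearman")$r,
               correlate_conditions(a, bmono, "spearman")$r)
  expect_error(correlate_conditions(a, data.frame(variant = "x", score = 1)),
               "3 shared")
})
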