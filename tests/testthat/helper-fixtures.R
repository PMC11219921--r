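# Shared fixtures and independent oracles. Everything is generated in code;
# expensive shared objects are built once per run and cached in .fx.

.fx <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  sim_config(region_length = 25, mutable_positions = c(2, 25),
             n_wt_barcodes = 300, n_synonymous = 15,
             depth_per_timepoint = 1e5, seed = 42, ...)
}

# A small but complete simulated experiment: 480 single-substitution
# variants, two lineages, multinomial sampling at depth 1e5.
tiny_sim <- function() {
  if (is.null(.fx$tiny)) {
    cfg <- tiny_config()
    lib <- gen_library(cfg)
    tabs <- lapply(1:2, function(L) {
      simulate_growth(lib$map, lib$effects, cfg, "plus_antibiotic",
                      lineage = L)
    })
    scored <- score_assay(tabs, lib$map, min_reads = 5, seed = 3)
    .fx$tiny <- list(cfg = cfg, lib = lib, tabs = tabs, scored = scored)
  }
  .fx$tiny
}

# A library with a fixed number of barcodes per variant and chosen true
# effects, bypassing the negative-binomial multiplicity draw.
flat_library <- function(n_variants, n_per, n_wt, s_plus = NULL,
                         seed = 1L, n_nonsense = 20L, s_null = -2.5, ...) {
  cfg <- sim_config(seed = seed, ...)
  variants <- c(sprintf("v%04d", seq_len(n_variants)),
                sprintf("x%04d", seq_len(n_nonsense)))
  classes <- rep(c("missense", "nonsense"), c(n_variants, n_nonsense))
  if (is.null(s_plus)) {
    s_plus <- y1hscan:::with_seed(seed, y1hscan:::draw_effects(
      n_variants, cfg$effect_distribution))
  }
  s_all <- c(s_plus, rep(s_null, n_nonsense))
  n_mut <- length(variants)
  n_bc <- n_mut * n_per + n_wt
  barcodes <- paste0("BC", formatC(seq_len(n_bc),
                                   width = cfg$barcode_length - 2,
                                   flag = "0"))
  map <- data.frame(
    barcode = barcodes,
    variant = c(rep(variants, each = n_per), rep("WT", n_wt)),
    variant_class = c(rep(classes, each = n_per), rep("wild_type", n_wt)),
    n_mutations = c(rep(1L, n_mut * n_per), rep(0L, n_wt)),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    variant = c(variants, "WT"),
    variant_class = c(classes, "wild_type"),
    s_plus = c(s_all, 0), s_minus = 0, label_propensity = 0,
    stringsAsFactors = FALSE)
  list(cfg = cfg, map = map, effects = effects)
}

# ---- independent oracles ----

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  q <- numeric(n)
  q[o] <- pmin(adj, 1)
  q
}

# AUC as the fraction of concordant (pathogenic, benign) pairs, ties 0.5.
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# All-pairs minimum distance per residue, scalar double loop.
min_dist_oracle <- function(prot, dna) {
  out <- numeric(0)
  for (rid in unique(prot$resid)) {
    best <- Inf
    pr <- prot[prot$resid == rid, , drop = FALSE]
    for (i in seq_len(nrow(pr))) for (j in seq_len(nrow(dna))) {
      d <- sqrt((pr$x[i] - dna$x[j])^2 + (pr$y[i] - dna$y[j])^2 +
                  (pr$z[i] - dna$z[j])^2)
      if (d < best) best <- d
    }
    out[as.character(rid)] <- best
  }
  out
}

# Mann-Whitney U of group a by pair counting.
u_oracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Exact two-sided rank-sum p-value by enumerating group assignments.
ranksum_exact_oracle <- function(a, b) {
  n <- length(a) + length(b)
  vals <- c(a, b)
  u_obs <- u_oracle(a, b)
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, function(idx) u_oracle(vals[idx], vals[-idx]))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-corrected normal-approximation rank-sum p-value, from the textbook
# formulas (no continuity correction).
ranksum_approx_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- u_oracle(a, b)
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

# First-match functional category straight from the published rule list.
category_oracle <- function(score, q_wt, q_nonsense, mean_nonsense,
                            alpha = 0.05) {
  if (score > 0 && q_wt < alpha) return("increased")
  if (score < mean_nonsense && q_nonsense < alpha) return("toxic")
  if (score < 0 && score > mean_nonsense && q_wt < alpha &&
        q_nonsense < alpha) return("hypomorphic")
  if (q_wt >= alpha) return("neutral")
  if (q_nonsense >= alpha) return("lof")
  NA_character_
}
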