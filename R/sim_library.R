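#' Generate a barcoded saturation-mutagenesis library
#'
#' Enumerates every single amino-acid substitution over the mutable range
#' (19 missense + 1 nonsense per position), adds synonymous pseudo-variants
#' and wild-type barcodes, assigns each variant a negative-binomial number
#' of unique 30-nt barcodes, and draws true selection coefficients for both
#' assay arms. With the default 150-residue construct and mutable positions
#' 2-150 the design space holds 2831 missense and 149 nonsense variants.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{map}{barcode-variant map: `barcode`, `variant`,
#'       `variant_class`, `n_mutations`.}
#'     \item{effects}{true effects: `variant`, `variant_class`, `s_plus`,
#'       `s_minus`, `label_propensity` (wild type and synonymous variants
#'       have `s_plus = s_minus = 0` exactly; nonsense variants have
#'       `s_plus = config$s_null`).}
#'     \item{wt_sequence}{simulated wild-type amino-acid sequence.}
#'   }
#' @export
gen_library <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "library"), {
    positions <- seq(config$mutable_positions[1], config$mutable_positions[2])
    wt_seq <- c("M", sample(AA_ALPHABET, config$region_length - 1L,
                            replace = TRUE))

    wt_at <- wt_seq[positions]
    missense <- unlist(lapply(seq_along(positions), function(i) {
      alts <- setdiff(AA_ALPHABET, wt_at[i])
      paste0(wt_at[i], positions[i], alts)
    }))
    nonsense <- paste0(wt_at, positions, "*")

    syn_pos <- sample(positions, config$n_synonymous, replace = TRUE)
    syn_idx <- stats::ave(seq_along(syn_pos), syn_pos, FUN = seq_along)
    synonymous <- paste0(wt_seq[syn_pos], syn_pos, wt_seq[syn_pos], "_", syn_idx)

    variants <- data.frame(
      variant = c(missense, nonsense, synonymous),
      variant_class = rep(c("missense", "nonsense", "synonymous"),
                          c(length(missense), length(nonsense),
                            length(synonymous))),
      stringsAsFactors = FALSE)

    # Barcode multiplicity: truncated negative binomial, median ~19.
    bdist <- config$barcodes_per_variant_dist
    assert_that(identical(bdist$name, "nbinom"),
                "only nbinom barcode multiplicity is implemented")
    n_bc <- pmax(stats::rnbinom(nrow(variants), size = bdist$size,
                                mu = bdist$mu),
                 bdist$min %||% 1)

    map <- data.frame(
      variant = c(rep(variants$variant, n_bc),
                  rep("WT", config$n_wt_barcodes)),
      variant_class = c(rep(variants$variant_class, n_bc),
                        rep("wild_type", config$n_wt_barcodes)),
      stringsAsFactors = FALSE)
    map$n_mutations <- ifelse(map$variant_class == "wild_type", 0L, 1L)
    map <- cbind(barcode = random_barcodes(nrow(map), config$barcode_length),
                 map, stringsAsFactors = FALSE)

    # True effects per variant.
    s_plus <- numeric(nrow(variants))
    mis <- variants$variant_class == "missense"
    s_plus[mis] <- draw_effects(sum(mis), config$effect_distribution)
    s_plus[variants$variant_class == "nonsense"] <- config$s_null
    s_plus[variants$variant_class == "synonymous"] <- 0

    effects <- data.frame(
      variant = c(variants$variant, "WT"),
      variant_class = c(variants$variant_class, "wild_type"),
      s_plus = c(s_plus, 0),
      stringsAsFactors = FALSE)
    noise <- stats::rnorm(nrow(effects), 0, config$s_minus_noise_sd)
    effects$s_minus <- config$anticorrelation * effects$s_plus + noise
    effects$s_minus[effects$variant == "WT"] <- 0
    effects$s_minus[effects$variant_class == "synonymous"] <- 0
    effects$label_propensity <- stats::plogis(
      config$label_link$k * (abs(effects$s_plus) - config$label_link$s0))

    list(map = map, effects = effects, wt_sequence = wt_seq)
  })
}

# Unique random fixed-length DNA barcodes; duplicate draws are regenerated
# (up to 100 rounds) before failing hard. 4^30 space makes retries cosmetic.
random_barcodes <- function(n, length = 30L, max_retry = 100L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  bc <- draw(n)
  for (i in seq_len(max_retry)) {
    dup <- duplicated(bc)
    if (!any(dup)) return(bc)
    bc[dup] <- draw(sum(dup))
  }
  stop_y1h("barcode collision not resolved within retry budget")
}

#' Write / read a barcode-variant map as TSV
#'
#' Columns: `barcode`, `variant`, `variant_class`, `n_mutations`.
#'
#' @param map barcode-variant map data frame.
#' @param path file path.
#' @export
write_barcode_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_map
#' @export
read_barcode_map <- function(path) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_barcode_map(map)
  map
}

validate_barcode_map <- function(map) {
  need <- c("barcode", "variant", "variant_class", "n_mutations")
  assert_that(all(need %in% names(map)),
              paste("barcode map must have columns:",
                    paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(map$barcode), "barcodes must be unique")
  assert_that(all(map$variant_class %in%
                    c("wild_type", "synonymous", "missense", "nonsense",
                      "multi")),
              "unknown variant_class")
  assert_that(all((map$variant_class == "wild_type") == (map$n_mutations == 0)),
              "wild_type entries must have 0 mutations and vice versa")
  invisible(map)
}
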