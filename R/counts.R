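#' Extract barcodes from a FASTQ file
#'
#' The sequencing primer anneals so the read starts at the first barcode
#' nucleotide: the barcode is the first `barcode_length` nt of each read,
#' taken verbatim with no error correction. Reads shorter than the barcode
#' and reads with any `N` inside the barcode window are tallied as
#' unmatched. A structurally malformed record (missing header/plus line,
#' sequence/quality length mismatch, truncated record) aborts with the
#' offending record index.
#'
#' @param fastq_path path to an uncompressed FASTQ file.
#' @param barcode_length barcode length in nt.
#' @return list: `counts` (named integer vector, barcode -> occurrences),
#'   `unmatched` (number of rejected reads), `n_reads` (total records).
#' @export
extract_barcodes <- function(fastq_path, barcode_length = 30L) {
  assert_that(file.exists(fastq_path),
              sprintf("no such file: %s", fastq_path))
  lines <- readLines(fastq_path)
  if (length(lines) == 0) {
    return(list(counts = integer(0), unmatched = 0L, n_reads = 0L))
  }
  if (length(lines) %% 4 != 0) {
    stop_y1h(sprintf("malformed FASTQ: truncated record %d in %s",
                     length(lines) %/% 4 + 1, fastq_path))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]

  bad <- !startsWith(hdr, "@") | !startsWith(plus, "+") |
    nchar(seqs) != nchar(qual)
  if (any(bad)) {
    stop_y1h(sprintf("malformed FASTQ record %d in %s", which(bad)[1],
                     fastq_path))
  }

  ok <- nchar(seqs) >= barcode_length
  bc <- substr(seqs[ok], 1L, barcode_length)
  has_n <- grepl("N", bc, fixed = TRUE)
  unmatched <- sum(!ok) + sum(has_n)
  bc <- bc[!has_n]
  counts <- if (length(bc)) table(bc) else integer(0)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, unmatched = as.integer(unmatched), n_reads = n)
}

#' Count mapped barcodes across timepoints
#'
#' Builds a barcode-level count table restricted to barcodes present in
#' the map; every mapped barcode gets a row (0 where unseen), and unmapped
#' barcodes are tallied separately per timepoint.
#'
#' @param multisets list (one per timepoint, in time order) of named
#'   integer vectors as produced by [extract_barcodes()]`$counts`.
#' @param map barcode-variant map.
#' @param timepoints_h hours for each multiset.
#' @param condition,lineage metadata attached to the table.
#' @return list: `table` (barcode-level [count_table()]), `unmapped`
#'   (integer vector of unmapped read counts per timepoint).
#' @export
count_barcodes <- function(multisets, map, timepoints_h,
                           condition = NULL, lineage = NA) {
  validate_barcode_map(map)
  assert_that(length(multisets) == length(timepoints_h),
              "one multiset per timepoint required")
  m <- matrix(0, nrow(map), length(multisets))
  unmapped <- integer(length(multisets))
  for (j in seq_along(multisets)) {
    ms <- multisets[[j]]
    if (!length(ms)) next
    hit <- match(names(ms), map$barcode)
    unmapped[j] <- sum(ms[is.na(hit)])
    keep <- !is.na(hit)
    m[hit[keep], j] <- m[hit[keep], j] + as.numeric(ms[keep])
  }
  list(table = count_table(m, map$barcode, timepoints_h, level = "barcode",
                           condition = condition, lineage = lineage),
       unmapped = unmapped)
}

#' Filter barcodes on the selection-start count
#'
#' Drops every barcode whose count at the first timepoint (T = 0, when
#' antibiotic is added) falls below `min_reads`; the default 25-read floor
#' suppresses barcodes too shallow to yield a stable log-ratio series.
#'
#' @param table barcode-level [count_table()] whose first timepoint is
#'   T = 0.
#' @param min_reads minimum T = 0 count to retain a barcode.
#' @return Filtered [count_table()] with attribute `n_removed`.
#' @export
filter_min_t0 <- function(table, min_reads = 25) {
  assert_that(ct_level(table) == "barcode", "filtering is barcode-level")
  tp <- ct_timepoints(table)
  assert_that(length(tp) >= 1 && tp[1] == 0, "T = 0 column required")
  m <- ct_counts(table)
  keep <- m[, 1] >= min_reads
  out <- ct_rebuild(table, m[keep, , drop = FALSE], table$id[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep the first k timepoints
#'
#' @param table a [count_table()].
#' @param k number of leading timepoints to retain.
#' @return Trimmed [count_table()].
#' @export
select_timepoints <- function(table, k = 4L) {
  tp <- ct_timepoints(table)
  assert_that(length(tp) >= k, sprintf("need >= %d timepoints", k))
  m <- ct_counts(table)[, seq_len(k), drop = FALSE]
  ct_rebuild(table, m, table$id, timepoints_h = tp[seq_len(k)])
}

#' Aggregate barcode counts to variants
#'
#' Sums counts over all barcodes of each variant. Wild-type barcodes are
#' handled two ways at once: (a) summed into a single `WT` reference
#' series (the denominator of the scoring log-ratio), and (b) partitioned
#' at random (seeded) into pseudo-variant groups of `wt_group_size`
#' barcodes, scored like ordinary variants to give an empirical wild-type
#' score distribution. Per-timepoint totals are conserved: variant totals
#' plus WT total equal the barcode-level totals.
#'
#' @param table filtered, timepoint-selected barcode-level table.
#' @param map barcode-variant map.
#' @param wt_group_size barcodes per wild-type pseudo-variant group
#'   (default 19, the library's median barcode multiplicity).
#' @param seed seed for the wild-type partition.
#' @return list: `variants` (variant-level [count_table()], wild type
#'   excluded), `wt_series` (named numeric vector, summed WT counts per
#'   timepoint), `wt_groups` (variant-level [count_table()] of WT
#'   pseudo-variants, ids `WT_grp<k>`), `n_barcodes` (named vector,
#'   barcodes per variant after filtering).
#' @export
aggregate_to_variants <- function(table, map, wt_group_size = 19L,
                                  seed = 1L) {
  assert_that(ct_level(table) == "barcode", "aggregation is barcode-level")
  idx <- match(table$id, map$barcode)
  if (anyNA(idx)) stop_y1h("count table contains unmapped barcodes")
  variant <- map$variant[idx]
  is_wt <- map$variant_class[idx] == "wild_type"
  m <- ct_counts(table)

  agg <- function(mm, by) {
    if (!nrow(mm)) {
      return(matrix(0, 0, ncol(mm)))
    }
    rowsum(mm, group = by, reorder = TRUE)
  }

  vm <- agg(m[!is_wt, , drop = FALSE], variant[!is_wt])
  variants <- ct_rebuild(table, vm, rownames(vm), level = "variant")

  wt_m <- m[is_wt, , drop = FALSE]
  wt_series <- colSums(wt_m)
  names(wt_series) <- paste0("t", ct_timepoints(table))

  wt_groups <- NULL
  if (nrow(wt_m) >= 1) {
    ng <- max(1L, nrow(wt_m) %/% wt_group_size)
    grp <- with_seed(derive_seed(seed, "wt_partition"), {
      sample(rep_len(seq_len(ng), nrow(wt_m)))
    })
    gm <- agg(wt_m, paste0("WT_grp", formatC(grp, width = 4, flag = "0")))
    wt_groups <- ct_rebuild(table, gm, rownames(gm), level = "variant")
  }

  nb <- base::table(variant[!is_wt])
  list(variants = variants, wt_series = wt_series, wt_groups = wt_groups,
       n_barcodes = stats::setNames(as.integer(nb), names(nb)))
}
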