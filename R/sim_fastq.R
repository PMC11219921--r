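#' Write fixture FASTQ files from a barcode count table
#'
#' One FASTQ per timepoint; each record's first `barcode_length` nt are the
#' barcode (the read layout produced by a sequencing primer annealing
#' directly upstream of the barcode), padded to `read_length` with a fixed
#' filler base and constant Phred+33 qualities. A table with count `k` for
#' barcode `b` at timepoint `t` yields exactly `k` records starting with
#' `b` in that timepoint's file, so extraction round-trips the table.
#'
#' @param counts barcode-level [count_table()] with integer counts.
#' @param map barcode-variant map (used only to sanity-check membership).
#' @param out_dir output directory (created if absent).
#' @param prefix file-name prefix; files are `<prefix>_t<hours>.fastq`.
#' @param read_length total read length (>= barcode length).
#' @param shuffle_seed if non-NULL, records within each file are shuffled
#'   with this seed (realistic read order; counts are unaffected).
#' @return character vector of written file paths, named by timepoint.
#' @export
write_fixture_fastq <- function(counts, map = NULL, out_dir,
                                prefix = "sim", read_length = 75L,
                                shuffle_seed = NULL) {
  assert_that(ct_level(counts) == "barcode", "counts must be barcode-level")
  m <- ct_counts(counts)
  assert_that(all(m == round(m)), "FASTQ fixtures need integer counts")
  if (!is.null(map)) {
    assert_that(all(counts$id %in% map$barcode),
                "count table contains unmapped barcodes")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bl <- unique(nchar(counts$id))
  assert_that(length(bl) <= 1, "barcodes must share one length")
  pad <- if (length(bl) && read_length > bl) {
    strrep("A", read_length - bl)
  } else ""

  hours <- ct_timepoints(counts)
  paths <- file.path(out_dir, sprintf("%s_t%g.fastq", prefix, hours))
  names(paths) <- paste0("t", hours)
  qual <- strrep("I", read_length)
  for (j in seq_along(hours)) {
    reps <- m[, j]
    bcs <- rep(counts$id, reps)
    if (!is.null(shuffle_seed) && length(bcs) > 1) {
      bcs <- with_seed(derive_seed(shuffle_seed, paste0("fq", j)),
                       sample(bcs))
    }
    if (length(bcs)) {
      recs <- as.vector(rbind(sprintf("@read%d_t%g", seq_along(bcs),
                                      hours[j]),
                              paste0(bcs, pad), "+", qual))
      writeLines(recs, paths[j])
    } else {
      file.create(paths[j])  # empty, header-less
    }
  }
  invisible(paths)
}
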