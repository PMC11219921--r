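#' Per-timepoint count tables
#'
#' A `count_table` is a data frame whose first column (`id`) holds barcode
#' sequences or variant identifiers and whose remaining columns hold counts
#' at successive timepoints, labelled `t<hours>` (e.g. `t0`, `t12`).
#' Timepoint hours, the table level (`"barcode"` or `"variant"`), and assay
#' metadata (bait, antibiotic arm, lineage) travel as attributes.
#'
#' Counts are non-negative; they are integers for sampled data but may be
#' fractional for noiseless expected-count tables produced by
#' [simulate_growth()] with `sampling = "expected"`.
#'
#' @param counts numeric matrix or data frame, one row per id, one column
#'   per timepoint.
#' @param ids character vector of row identifiers (barcodes or variants).
#' @param timepoints_h strictly increasing numeric vector of hours.
#' @param level `"barcode"` or `"variant"`.
#' @param condition list with elements `bait` and `antibiotic` (or `NULL`).
#' @param lineage lineage identifier (or `NA`).
#' @return A `count_table` data frame.
#' @export
count_table <- function(counts, ids, timepoints_h,
                        level = c("barcode", "variant"),
                        condition = NULL, lineage = NA) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  assert_that(length(ids) == nrow(counts), "ids must match count rows")
  assert_that(length(timepoints_h) == ncol(counts),
              "timepoints_h must match count columns")
  assert_that(all(diff(timepoints_h) > 0), "timepoints must be strictly increasing")
  assert_that(all(counts >= 0), "counts must be non-negative")
  df <- data.frame(id = as.character(ids), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("t", timepoints_h))
  rownames(df) <- NULL
  structure(df,
            timepoints_h = as.numeric(timepoints_h),
            level = level,
            condition = condition,
            lineage = lineage,
            class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> level=%s, %d rows, timepoints (h): %s\n",
              ct_level(x), nrow(x), paste(ct_timepoints(x), collapse = ", ")))
  cond <- attr(x, "condition")
  if (!is.null(cond)) {
    cat(sprintf("  condition: bait=%s antibiotic=%s lineage=%s\n",
                cond$bait %||% "?", cond$antibiotic %||% "?",
                as.character(attr(x, "lineage"))))
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

ct_timepoints <- function(x) attr(x, "timepoints_h")
ct_level <- function(x) attr(x, "level")

# Count matrix (rows = ids) without the id column.
ct_counts <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$id
  m
}

# Rebuild a count_table with new rows/columns, keeping metadata.
ct_rebuild <- function(template, counts, ids, timepoints_h = NULL,
                       level = NULL) {
  count_table(counts, ids,
              timepoints_h %||% ct_timepoints(template),
              level = level %||% ct_level(template),
              condition = attr(template, "condition"),
              lineage = attr(template, "lineage"))
}

#' Write / read count tables as TSV
#'
#' Plain tab-separated serialisation: `id` column, one `t<hours>` column per
#' timepoint, plus `level`, `bait`, `antibiotic` and `lineage` metadata
#' columns so a table round-trips through disk.
#'
#' @param x a `count_table`.
#' @param path file path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns a `count_table`.
#' @export
write_count_table <- function(x, path) {
  cond <- attr(x, "condition") %||% list(bait = NA, antibiotic = NA)
  df <- as.data.frame(x)
  df$level <- ct_level(x)
  df$bait <- cond$bait %||% NA
  df$antibiotic <- cond$antibiotic %||% NA
  df$lineage <- attr(x, "lineage")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tp_cols <- grep("^t[0-9.]+$", names(df), value = TRUE)
  assert_that(length(tp_cols) >= 1, "no timepoint columns found")
  hours <- as.numeric(sub("^t", "", tp_cols))
  count_table(df[, tp_cols, drop = FALSE], df$id, hours,
              level = df$level[1],
              condition = list(bait = df$bait[1], antibiotic = df$antibiotic[1]),
              lineage = df$lineage[1])
}
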