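#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state: seeds the generator, restores the caller's
# .Random.seed afterwards so library-level determinism never leaks out.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_y1h <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_y1h(msg)
  invisible(TRUE)
}

# The 20 standard amino acids, one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Parse protein-level variant ids of the form <wt><pos><alt>, e.g. "K12E",
# nonsense "K12*", synonymous "K12K_1". Returns NA position for ids that do
# not carry one (e.g. "WT").
variant_position <- function(variant) {
  pos <- rep(NA_integer_, length(variant))
  has <- grepl("^[A-Z]\\d+", variant)
  pos[has] <- as.integer(sub("^[A-Z](\\d+).*$", "\\1", variant[has]))
  pos
}
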