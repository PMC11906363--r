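#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages take an explicit integer seed. Multi-stage drivers
#' (the cohort simulator, the pipeline) derive one child seed per stage from
#' a single master seed so that any stage can be re-run standalone and still
#' reproduce its output byte-for-byte.
#'
#' @param seed Master seed (single integer).
#' @param stage Stage label (character) or integer offset.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  x <- (as.numeric(seed) %% m) + 1
  a <- 48271
  x <- (a * x + as.numeric(stage) * 69621) %% m
  x <- (a * x) %% m
  as.integer(ifelse(x == 0, 1, x))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
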