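#' Round half away from zero
#'
#' Fixed-precision rounding with the "round half up" tie rule used for all
#' reported percentages (base R's `round()` rounds half to even, which would
#' print 45.09 where the cohort tables print 45.10).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(46 / 102 * 100) # 45.10
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half up to two decimals
#' @param k Numerator count.
#' @param n Denominator count.
#' @return `k / n * 100` rounded to 2 decimals; `NA` when `n == 0`.
#' @export
percent_of <- function(k, n) {
  if (length(n) == 1L && n == 0) return(rep(NA_real_, length(k)))
  round_half_up(k / n * 100, 2)
}

# internal: stop with a consistent prefix
abort <- function(...) stop(sprintf(...), call. = FALSE)

# internal: read a TSV with required columns, "." as missing
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]  # leading comment lines only;
                                           # '#' inside fields is data
  df <- utils::read.delim(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c(".", "NA", ""),
                          check.names = FALSE, comment.char = "", quote = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort("%s: missing required column(s): %s", basename(path),
          paste(missing_cols, collapse = ", "))
  df
}

# internal: write a TSV with "." for missing
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata` directory; with no
#'   arguments, lists the available fixtures.
#' @return Absolute path to the fixture (or a character vector of names).
#' @export
eoad_fixture_path <- function(name = NULL) {
  base <- system.file("extdata", package = "eoadtriage")
  if (is.null(name)) return(dir(base))
  path <- file.path(base, name)
  if (!file.exists(path)) abort("no packaged fixture named '%s'", name)
  path
}
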