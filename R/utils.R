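#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when printing percentages in
#' descriptive tables of spontaneous-report studies. Base R's `round()` uses
#' banker's rounding (half-to-even), which prints 50.215 as 50.22 or 50.21
#' depending on the binary representation; half-up is deterministic.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(238 / 474 * 100) # 50.21
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage of a count against a denominator, rounded half-up
#'
#' @param count numerator count(s).
#' @param denom denominator.
#' @param digits decimal places (default 2).
#' @return percentage on the 0-100 scale.
#' @export
#' @examples
#' pct(174, 1714) # 10.15
pct <- function(count, denom, digits = 2) {
  round_half_up(100 * count / denom, digits)
}

# collapse internal whitespace and trim; used for drug names and PTs
squish <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

# uppercase + squish: the normalized key for name matching
norm_key <- function(x) {
  toupper(squish(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty strings (and "NA" placeholders are NOT touched: FAERS uses blanks)
blank_to_na <- function(x) {
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

# yyyymmdd string -> integer; invalid/unparseable -> NA
parse_fda_dt <- function(x) {
  out <- suppressWarnings(as.integer(x))
  bad <- !is.na(out) & !valid_yyyymmdd(out)
  out[bad] <- NA_integer_
  out
}

valid_yyyymmdd <- function(d) {
  y <- d %/% 10000L
  m <- (d %/% 100L) %% 100L
  dd <- d %% 100L
  y >= 1900L & y <= 2100L & m >= 1L & m <= 12L & dd >= 1L & dd <= 31L
}

# run an expression with a private RNG stream, restoring global state after
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
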