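#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages and
#' consensus scores use the conventional half-away-from-zero rule instead
#' (so `round_half_up(0.835, 2)` is 0.84, matching how published tables are
#' formatted).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 1.7915, 0.5833), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small relative fudge so values that are exactly representable halves
  # (from integer ratios) are not pushed down by binary float error
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Canonical variant identifier
#'
#' @param chrom chromosome (with or without "chr" prefix).
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @return character vector `"chr:pos:ref:alt"` with normalised chromosome.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(normalise_chrom(chrom), pos, ref, alt, sep = ":")
}

#' Normalise chromosome names to "chr"-prefixed form
#'
#' @param chrom character vector of contig names ("16", "chr16", "MT", ...).
#' @return character vector with "chr" prefix; "MT" becomes "chrM".
#' @export
normalise_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  chrom[chrom %in% c("MT", "chrMT")] <- "chrM"
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}

# is x a whole non-negative number (vectorised)
is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# "." and "" are the missing markers of the annotation dialect
dot_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "." | x == "")] <- NA_character_
  x
}

na_to_dot <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "."
  x
}

# parse numeric annotation cells; unparseable cells become missing
numeric_or_na <- function(x) {
  suppressWarnings(as.numeric(dot_to_na(as.character(x))))
}
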