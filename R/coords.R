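# Single source of off-by-one truth.
#
# External conventions: VCF positions are 1-based; all interval logic inside
# the package is 0-based half-open [start0, end0) (BED convention).  IRanges
# is 1-based closed, so a half-open interval [s0, e0) maps to IRanges(s0 + 1,
# e0), and a 1-based point position maps to the 0-based base pos1 - 1.

#' Convert 1-based positions to 0-based
#'
#' VCF `POS` is 1-based; interval logic in this package is 0-based half-open.
#' All conversions go through this pair of helpers.
#'
#' @param pos1 integer vector of 1-based positions.
#' @return 0-based positions (`pos1 - 1`).
#' @export
pos1_to_pos0 <- function(pos1) {
  stopifnot(all(pos1 >= 1, na.rm = TRUE))
  pos1 - 1L
}

#' @rdname pos1_to_pos0
#' @param pos0 integer vector of 0-based positions.
#' @export
pos0_to_pos1 <- function(pos0) pos0 + 1L

# 0-based half-open intervals -> IRanges (1-based closed)
intervals_to_iranges <- function(start0, end0) {
  stopifnot(all(start0 < end0))
  IRanges::IRanges(start = start0 + 1L, end = end0)
}

# IRanges -> 0-based half-open
iranges_to_intervals <- function(ir) {
  data.frame(start0 = BiocGenerics::start(ir) - 1L,
             end0 = BiocGenerics::end(ir))
}

# point membership: is 0-based position p0 inside [start0, end0)?
point_in_interval <- function(p0, start0, end0) {
  p0 >= start0 & p0 < end0
}

AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

is_autosome <- function(chrom) as.character(chrom) %in% AUTOSOMES

variant_key <- function(chrom, pos1, ref, alt) {
  paste(chrom, pos1, ref, alt, sep = ":")
}
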