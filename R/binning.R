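#' Distance binning for cis fragment pairs
#'
#' Tiles the genomic-distance axis \eqn{(0, \mathrm{upper}]} with half-open
#' intervals \eqn{(l, u]} of equal width. All per-bin diagnostics (distance
#' function estimation, KS goodness of fit, observed interaction priors)
#' share one binning. Defaults give 75 bins of 20 kb up to 1.5 Mb, the
#' range over which the Brownian background dominates technical noise.
#'
#' @param width_bp Bin width in bp (default 20000).
#' @param upper_bp Upper distance limit in bp (default 1500000); must be a
#'   multiple of `width_bp`.
#' @return A tibble of class `chic_binning` with columns `bin` (index),
#'   `lower`, `upper`, `center` (bp) and a `label` like `"(0,2e+04]"`.
#' @examples
#' distance_bins()
#' @export
distance_bins <- function(width_bp = 20000, upper_bp = 1500000) {
  stopifnot(width_bp > 0, upper_bp > 0)
  n <- upper_bp / width_bp
  if (abs(n - round(n)) > 1e-9) {
    stop("`upper_bp` must be an integer multiple of `width_bp`", call. = FALSE)
  }
  n <- round(n)
  lower <- (seq_len(n) - 1) * width_bp
  upper <- seq_len(n) * width_bp
  out <- tibble::tibble(
    bin = seq_len(n),
    lower = lower,
    upper = upper,
    center = (lower + upper) / 2,
    label = sprintf("(%s,%s]", format(lower, trim = TRUE, scientific = NA),
                    format(upper, trim = TRUE, scientific = NA))
  )
  attr(out, "width_bp") <- width_bp
  attr(out, "upper_bp") <- upper_bp
  class(out) <- c("chic_binning", class(out))
  out
}

#' Map distances to distance bins
#'
#' @param distance_bp Numeric vector of cis distances in bp.
#' @param binning A [distance_bins()] tibble.
#' @return Integer bin indices; `NA` for distances outside
#'   `(0, upper_bp]` (including trans pairs coded as `NA`).
#' @export
assign_bins <- function(distance_bp, binning) {
  w <- attr(binning, "width_bp")
  up <- attr(binning, "upper_bp")
  idx <- ceiling(distance_bp / w)
  idx[!is.na(distance_bp) & (distance_bp <= 0 | distance_bp > up)] <- NA_integer_
  as.integer(idx)
}
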