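#' Inverse hyperbolic sine transformation with a normalization cofactor
#'
#' Transforms fluorescence intensities \code{z} to
#' \code{asinh(z/c) = ln(z/c + sqrt((z/c)^2 + 1))}. The cofactor \code{c}
#' controls the transition between the near-linear regime (\code{|z| << c},
#' where the transform is approximately \code{z/c}) and the logarithmic
#' regime (\code{z >> c}, approximately \code{ln(2 z / c)}). The scale and
#' shift constants of the general three-parameter form are fixed at 1 and 0:
#' a post-transformation scaling does not affect downstream analysis and a
#' pre-transformation shift would displace cell populations.
#'
#' The transform is defined on all reals, so compensated (possibly negative)
#' fluorescence values pass through without clipping.
#'
#' @param x numeric vector of raw intensities (finite; negatives allowed).
#' @param cofactor positive finite scalar, in the same units as \code{x}.
#' @return numeric vector of transformed values, same length as \code{x}.
#' @examples
#' asinh_transform(c(-5, 0, 1, 100), cofactor = 5)
#' @export
asinh_transform <- function(x, cofactor) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L ||
      !is.finite(cofactor) || cofactor <= 0) {
    stop("'cofactor' must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  asinh(x / cofactor)
}

#' Rescale a vector to the unit interval
#'
#' Maps \code{x} linearly so its minimum becomes 0 and its maximum 1:
#' \code{(x - min(x)) / (max(x) - min(x))}. Used to put channels transformed
#' by different methods on a common scale before comparing the spread of
#' their density peaks.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return numeric vector in \code{[0, 1]}, same order as \code{x}.
#' @examples
#' rescale_unit(c(2, 4, 6))
#' @export
rescale_unit <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  r <- range(x, na.rm = FALSE)
  if (!all(is.finite(r))) stop("'x' must be finite", call. = FALSE)
  if (r[1] == r[2]) {
    stop("cannot rescale a constant vector to [0, 1]", call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}
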