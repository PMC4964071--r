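#' Kernel density estimate of one transformed channel
#'
#' Gaussian-kernel KDE on a 512-point equally spaced grid extending three
#' bandwidths beyond the data range, with the Silverman rule-of-thumb
#' default bandwidth \code{0.9 * min(sd, IQR/1.34) * n^(-1/5)} (the
#' \code{"nrd0"} rule of \code{stats::density}, whose defaults this
#' deliberately mirrors).
#'
#' @param x numeric vector of at least 10 finite values with positive spread.
#' @param bandwidth optional positive kernel bandwidth; default is the
#'   rule-of-thumb above.
#' @return a \code{density_curve}: list with \code{grid} (strictly
#'   increasing), \code{density} (non-negative, integrates to ~1) and
#'   \code{bandwidth}.
#' @export
estimate_density <- function(x, bandwidth = NULL) {
  x <- as.numeric(x)
  if (length(x) < 10L || any(!is.finite(x))) {
    stop("need at least 10 finite values for density estimation",
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("values have zero spread; density is degenerate", call. = FALSE)
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  if (!is.numeric(bw) || length(bw) != 1L || !is.finite(bw) || bw <= 0) {
    stop("'bandwidth' must be a single positive number", call. = FALSE)
  }
  d <- stats::density(x, bw = bw, kernel = "gaussian", n = 512L, cut = 3)
  structure(list(grid = d$x, density = d$y, bandwidth = d$bw),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat("density_curve: ", length(x$grid), " grid points on [",
      format(x$grid[1], digits = 4), ", ",
      format(x$grid[length(x$grid)], digits = 4), "], bandwidth ",
      format(x$bandwidth, digits = 4), "\n", sep = "")
  invisible(x)
}

# Indices of local maxima of y: strictly above the previous point and at
# least as high as the next (leftmost point of a plateau wins).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  which(y > left & y >= right)
}

# Topographic prominence of each candidate maximum: height above the higher
# of the two key saddles, where each side's saddle is the minimum density
# between the peak and the nearest strictly higher point (or the grid edge).
peak_prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      lmin <- min(lmin, y[j])
    }
    if (j == 1L && y[1L] <= h) lmin <- min(lmin, y[1L])
    rmin <- h
    j <- i
    n <- length(y)
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      rmin <- min(rmin, y[j])
    }
    if (j == n && y[n] <= h) rmin <- min(rmin, y[n])
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect 1-D density peaks and their boundaries
#'
#' Finds local maxima of the estimated density that stand out as regions of
#' high local density and significant curvature, operationalized as two
#' thresholds relative to the global density maximum: a minimum height and a
#' minimum topographic prominence. Retained adjacent peaks are separated at
#' the lowest-density grid point between their modes (leftmost point on
#' ties); the outermost boundaries sit at the grid ends, so the peak regions
#' partition the grid span. A unimodal curve yields a single peak spanning
#' the whole grid.
#'
#' @param curve a \code{density_curve} from \code{\link{estimate_density}}.
#' @param min_height_frac peaks below this fraction of the maximum density
#'   are discarded (default 0.01).
#' @param min_prominence_frac peaks whose prominence is below this fraction
#'   of the maximum density are discarded (default 0.05).
#' @return data frame with one row per peak: \code{mode}, \code{lo},
#'   \code{hi} on the transformed-intensity scale, ordered by mode.
#' @export
detect_peaks <- function(curve, min_height_frac = 0.01,
                         min_prominence_frac = 0.05) {
  stopifnot(inherits(curve, "density_curve"))
  if (!(min_height_frac > 0 && min_height_frac < 1) ||
      !(min_prominence_frac > 0 && min_prominence_frac < 1)) {
    stop("threshold fractions must lie in (0, 1)", call. = FALSE)
  }
  y <- curve$density
  g <- curve$grid
  ymax <- max(y)
  cand <- local_maxima(y)
  if (length(cand) == 0L) cand <- which.max(y)
  keep <- y[cand] >= min_height_frac * ymax
  cand <- cand[keep]
  prom <- peak_prominence(y, cand)
  # the tallest peak always survives (its prominence equals its height)
  cand <- cand[prom >= min_prominence_frac * ymax | y[cand] == ymax]
  cand <- sort(cand)
  k <- length(cand)
  lo <- numeric(k)
  hi <- numeric(k)
  lo[1] <- g[1]
  hi[k] <- g[length(g)]
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      span <- cand[i]:cand[i + 1L]
      cut_idx <- span[which.min(y[span])]  # leftmost minimum on ties
      hi[i] <- g[cut_idx]
      lo[i + 1L] <- g[cut_idx]
    }
  }
  data.frame(mode = g[cand], lo = lo, hi = hi)
}

#' Collect density peaks across samples at one cofactor
#'
#' Runs the per-sample pipeline for a channel at a candidate cofactor:
#' transform with \code{\link{asinh_transform}}, estimate the density,
#' detect peaks, assign the sample's transformed events to peak regions by
#' the inter-peak boundaries (\code{lo <= t < hi}), and summarize each peak
#' by its event count, mean, and unbiased variance. Peaks with fewer than
#' \code{min_events} events or with near-zero variance are dropped with a
#' warning (tiny or degenerate peaks destabilize the log-variance terms of
#' Bartlett's statistic). Surviving peaks from all samples are pooled into
#' one set; the pooled variance is \code{sum((n_i-1) var_i) / (n - m)}.
#'
#' @param samples list of \code{\link{fc_sample}} objects.
#' @param channel channel name, present in every sample.
#' @param cofactor positive asinh cofactor.
#' @param min_events minimum events per retained peak (default 50).
#' @param min_height_frac,min_prominence_frac passed to
#'   \code{\link{detect_peaks}}.
#' @param bandwidth optional fixed KDE bandwidth (default: per-sample
#'   rule-of-thumb).
#' @return a \code{peak_set}: list with \code{channel}, \code{cofactor},
#'   \code{peaks} (data frame: \code{sample_id}, \code{mode}, \code{lo},
#'   \code{hi}, \code{n}, \code{mu}, \code{var}), \code{m}, \code{n},
#'   \code{pooled_var}, and \code{valid} (FALSE when no peak survived).
#' @export
collect_peaks <- function(samples, channel, cofactor, min_events = 50L,
                          min_height_frac = 0.01, min_prominence_frac = 0.05,
                          bandwidth = NULL) {
  if (inherits(samples, "fc_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  rows <- vector("list", length(samples))
  dropped <- 0L
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    t <- asinh_transform(channel_values(s, channel), cofactor)
    curve <- estimate_density(t, bandwidth = bandwidth)
    reg <- detect_peaks(curve, min_height_frac, min_prominence_frac)
    stat <- lapply(seq_len(nrow(reg)), function(i) {
      inside <- t >= reg$lo[i] & t < reg$hi[i]
      v <- t[inside]
      data.frame(sample_id = s$sample_id, mode = reg$mode[i],
                 lo = reg$lo[i], hi = reg$hi[i], n = length(v),
                 mu = if (length(v)) mean(v) else NA_real_,
                 var = if (length(v) >= 2L) stats::var(v) else NA_real_)
    })
    stat <- do.call(rbind, stat)
    ok <- stat$n >= min_events & !is.na(stat$var) & stat$var >= 1e-12
    dropped <- dropped + sum(!ok)
    rows[[j]] <- stat[ok, , drop = FALSE]
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  if (dropped > 0L) {
    warning(dropped, " peak(s) dropped (below ", min_events,
            " events or near-zero variance)", call. = FALSE)
  }
  m <- nrow(peaks)
  n <- sum(peaks$n)
  structure(list(channel = channel, cofactor = cofactor, peaks = peaks,
                 m = m, n = n,
                 pooled_var = if (m >= 1L && n > m)
                   sum((peaks$n - 1) * peaks$var) / (n - m) else NA_real_,
                 valid = m >= 1L),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set: channel '", x$channel, "' at cofactor ",
      format(x$cofactor, digits = 6), " -- ", x$m, " peak(s), ",
      x$n, " events", if (!x$valid) " [invalid]", "\n", sep = "")
  if (x$m > 0L) print(x$peaks, ...)
  invisible(x)
}
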