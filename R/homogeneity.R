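#' Bartlett's homogeneity-of-variance statistic from group summaries
#'
#' Computes the likelihood-ratio statistic
#' \deqn{B = \frac{(n-m)\ln\sigma_p^2 - \sum_i (n_i-1)\ln\sigma_i^2}
#'            {1 + \frac{1}{3(m-1)}\left(\sum_i \frac{1}{n_i-1} -
#'             \frac{1}{n-m}\right)}}
#' where \eqn{m} is the number of groups, \eqn{n = \sum n_i}, and
#' \eqn{\sigma_p^2 = \sum (n_i-1)\sigma_i^2 / (n-m)} is the pooled variance.
#' Only group summaries (sizes and unbiased variances) are needed, which is
#' what makes the statistic cheap enough to serve as the objective of a
#' cofactor search: it is recomputed from density-peak summaries at every
#' candidate cofactor. \code{B} is used here as a homogeneity score, not as
#' a hypothesis test; no p-value is reported.
#'
#' @param x either a \code{peak_set} (see \code{\link{collect_peaks}}) or a
#'   numeric vector of group sizes \code{n_i} (each >= 2).
#' @param var numeric vector of unbiased group variances (each > 0);
#'   ignored when \code{x} is a \code{peak_set}.
#' @return the non-negative statistic \code{B} (0 when all variances are
#'   equal).
#' @examples
#' bartlett_statistic(c(11, 11), c(4, 1))  # ~4.2504
#' @export
bartlett_statistic <- function(x, var = NULL) {
  if (inherits(x, "peak_set")) {
    n <- x$peaks$n
    v <- x$peaks$var
  } else {
    n <- as.numeric(x)
    v <- as.numeric(var)
  }
  m <- length(n)
  if (m < 2L) {
    stop("Bartlett's statistic is undefined for fewer than 2 groups",
         call. = FALSE)
  }
  if (length(v) != m) stop("'var' must match the group sizes in length",
                           call. = FALSE)
  if (any(n < 2)) stop("every group needs n_i >= 2", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("every group variance must be finite and positive", call. = FALSE)
  }
  ntot <- sum(n)
  pooled <- sum((n - 1) * v) / (ntot - m)
  num <- (ntot - m) * log(pooled) - sum((n - 1) * log(v))
  corr <- 1 + (sum(1 / (n - 1)) - 1 / (ntot - m)) / (3 * (m - 1))
  # tiny negative values can arise from floating-point cancellation at B ~ 0
  max(num / corr, 0)
}

#' Levene / Brown-Forsythe homogeneity statistic from raw group values
#'
#' The classical one-way ANOVA F statistic computed on absolute deviations
#' of each observation from its group center. With \code{center = "mean"}
#' this is Levene's statistic; with \code{center = "median"} it is the
#' Brown-Forsythe variant, which is more robust to heavy tails. Unlike
#' \code{\link{bartlett_statistic}} this requires the raw event values of
#' each group, not summaries. Offered as a drop-in alternative objective for
#' data whose 1-D clusters depart visibly from normality; Bartlett remains
#' the default because it discriminates variance heterogeneity more sharply
#' on approximately normal clusters.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 finite values).
#' @param center \code{"mean"} (Levene) or \code{"median"} (Brown-Forsythe).
#' @return non-negative F statistic (0 for identical groups).
#' @export
levene_statistic <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of at least 2 numeric vectors",
         call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  dev <- lapply(groups, function(g) abs(g - cfun(g)))
  y <- unlist(dev, use.names = FALSE)
  g <- factor(rep.int(seq_along(dev), lengths(dev)))
  if (stats::var(y) == 0) return(0)
  unname(stats::oneway.test(y ~ g, var.equal = TRUE)$statistic)
}

#' Between- to within-cluster variance ratio of a metacluster
#'
#' Effect-size measure of the homogeneity of a metacluster (a set of
#' clusters from different samples asserted to represent the same
#' immunophenotype):
#' \deqn{\sigma_b^2/\sigma_w^2 = \frac{\sum_i (n_i-1)(\mu_i-\mu)^2}
#'       {\sum_i (n_i-1)\sigma_i^2}}
#' with \eqn{\mu} the event-weighted combined mean (the common
#' \eqn{1/(N-k)} factors cancel). Unlike an F-test it does not grow with the
#' number of cells, so it compares metaclusters rather than testing them:
#' the more homogeneous the metacluster, the smaller the ratio. It is
#' invariant to a common affine change of scale applied to all clusters.
#'
#' @param n integer vector of cluster sizes (each >= 2).
#' @param mu numeric vector of cluster means.
#' @param var numeric vector of unbiased cluster variances.
#' @return the non-negative ratio (0 when all cluster means are equal).
#' @examples
#' between_within_ratio(c(101, 101), c(0, 2), c(1, 1))  # 1
#' @export
between_within_ratio <- function(n, mu, var) {
  k <- length(n)
  if (k < 2L) stop("a metacluster needs at least 2 clusters", call. = FALSE)
  if (length(mu) != k || length(var) != k) {
    stop("'n', 'mu' and 'var' must have equal length", call. = FALSE)
  }
  if (any(n < 2)) stop("every cluster needs n_i >= 2", call. = FALSE)
  if (any(!is.finite(var)) || any(var < 0)) {
    stop("cluster variances must be finite and non-negative", call. = FALSE)
  }
  denom <- sum((n - 1) * var)
  if (denom <= 0) stop("all cluster variances are zero", call. = FALSE)
  grand <- sum(n * mu) / sum(n)
  sum((n - 1) * (mu - grand)^2) / denom
}
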