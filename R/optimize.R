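#' Homogeneity objective for one channel at one cofactor
#'
#' Collects density peaks across all samples at the candidate cofactor and
#' scores their variance homogeneity. With the default Bartlett objective
#' the score comes from the peak summaries alone; the Levene and
#' Brown-Forsythe alternatives re-extract the raw transformed events of each
#' peak and are more robust to heavy-tailed clusters at extra cost. Returns
#' \code{Inf} when fewer than two peaks survive (the statistic is undefined
#' there), so an interval search can continue past degenerate cofactors.
#'
#' @param samples list of \code{\link{fc_sample}} objects.
#' @param channel channel name.
#' @param cofactor positive candidate cofactor.
#' @param objective \code{"bartlett"} (default), \code{"levene"} or
#'   \code{"brown_forsythe"}.
#' @param ... peak-collection settings passed to \code{\link{collect_peaks}}
#'   (\code{min_events}, \code{min_height_frac}, \code{min_prominence_frac},
#'   \code{bandwidth}).
#' @return non-negative score, or \code{Inf} when undefined.
#' @export
vs_objective <- function(samples, channel, cofactor,
                         objective = c("bartlett", "levene",
                                       "brown_forsythe"), ...) {
  objective <- match.arg(objective)
  ps <- suppressWarnings(collect_peaks(samples, channel, cofactor, ...))
  if (ps$m < 2L) return(Inf)
  if (objective == "bartlett") return(bartlett_statistic(ps))
  # robust objectives need raw per-peak values, re-extracted per sample
  groups <- list()
  for (s in samples) {
    t <- asinh_transform(channel_values(s, channel), cofactor)
    pk <- ps$peaks[ps$peaks$sample_id == s$sample_id, , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      groups[[length(groups) + 1L]] <- t[t >= pk$lo[i] & t < pk$hi[i]]
    }
  }
  levene_statistic(groups,
                   center = if (objective == "levene") "mean" else "median")
}

#' Minimize a 1-D black-box objective on an interval
#'
#' Bounded derivative-free minimization by golden-section search with
#' successive parabolic interpolation (\code{stats::optimize}). Because the
#' homogeneity objective is discontinuous wherever the detected peak count
#' changes with the cofactor, the interval endpoints are also evaluated and
#' the best of the three candidates is returned; the search treats the
#' objective strictly as a black box.
#'
#' @param f function of one positive real.
#' @param lower,upper interval bounds, \code{0 < lower < upper}.
#' @param tol relative tolerance on the argument (default 1e-4).
#' @return list with \code{minimum} (the argument), \code{value}
#'   (\code{f(minimum)}) and \code{evaluations}.
#' @export
minimize_interval <- function(f, lower, upper, tol = 1e-4) {
  stopifnot(is.function(f), lower > 0, lower < upper)
  nev <- 0L
  fw <- function(x) {
    nev <<- nev + 1L
    f(x)
  }
  # the +Inf sentinel for undefined statistics is by design; optimize()
  # replaces it with .Machine$double.xmax and warns, which is noise here
  opt <- withCallingHandlers(
    stats::optimize(fw, lower = lower, upper = upper, tol = tol * lower),
    warning = function(w) {
      if (grepl("NA/Inf replaced", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cand_x <- c(opt$minimum, lower, upper)
  cand_y <- c(opt$objective, fw(lower), fw(upper))
  best <- which.min(cand_y)  # which.min takes the first (smallest x wins ties
                             # only among the recorded candidate order)
  list(minimum = cand_x[best], value = cand_y[best], evaluations = nev)
}

#' Select the variance-stabilizing cofactor for one channel
#'
#' Piecewise minimization of the homogeneity score \code{B(c)} over
#' cofactors. The search domain \code{[exp(c_low), exp(c_high)]} (defaults
#' \code{c_low = -2}, \code{c_high = 10}, i.e. cofactors from ~0.135 to
#' ~22026) is split into \code{c_high - c_low} unit-width intervals on the
#' natural-log scale; within each interval
#' \code{[exp(c_i), exp(c_i + 1)]} a bounded derivative-free search finds a
#' local minimizer, and the global optimum is the best interval optimum.
#' Splitting the domain keeps each interval unlikely to hold more than one
#' local optimum of the non-differentiable objective. Ties across intervals
#' go to the smallest cofactor. The full evaluation trace is recorded.
#'
#' @param samples list of \code{\link{fc_sample}} objects.
#' @param channel channel name present in every sample.
#' @param c_low,c_high search bounds on the natural-log scale; non-integer
#'   spans end in a final partial interval.
#' @param tol relative tolerance of the inner search.
#' @param objective,... passed to \code{\link{vs_objective}}.
#' @return a \code{cofactor_scan}: list with \code{channel}, \code{c_low},
#'   \code{c_high}, \code{interval_optima} (data frame: \code{lo},
#'   \code{hi}, \code{c_opt}, \code{B}, \code{evaluations}), \code{c_star},
#'   \code{B_star}, and \code{trace} (data frame of every
#'   \code{(cofactor, B)} evaluated).
#' @export
optimize_cofactor <- function(samples, channel, c_low = -2, c_high = 10,
                              tol = 1e-4,
                              objective = c("bartlett", "levene",
                                            "brown_forsythe"), ...) {
  objective <- match.arg(objective)
  if (!(c_low < c_high)) stop("need c_low < c_high", call. = FALSE)
  breaks <- seq(c_low, c_high, by = 1)
  if (breaks[length(breaks)] < c_high) breaks <- c(breaks, c_high)
  k <- length(breaks) - 1L
  trace_c <- numeric(0)
  trace_B <- numeric(0)
  f <- function(cof) {
    b <- vs_objective(samples, channel, cof, objective = objective, ...)
    trace_c <<- c(trace_c, cof)
    trace_B <<- c(trace_B, b)
    b
  }
  opt <- data.frame(lo = exp(breaks[-length(breaks)]), hi = exp(breaks[-1]),
                    c_opt = NA_real_, B = NA_real_, evaluations = 0L)
  for (i in seq_len(k)) {
    res <- minimize_interval(f, opt$lo[i], opt$hi[i], tol = tol)
    opt$c_opt[i] <- res$minimum
    opt$B[i] <- res$value
    opt$evaluations[i] <- res$evaluations
  }
  if (all(!is.finite(opt$B))) {
    stop("optimization failed for channel '", channel,
         "': no cofactor yielded >= 2 density peaks ",
         "(too few samples or populations?)", call. = FALSE)
  }
  best_B <- min(opt$B)
  cand <- which(opt$B == best_B)
  best <- cand[which.min(opt$c_opt[cand])]  # smallest cofactor on ties
  structure(list(channel = channel, c_low = c_low, c_high = c_high, k = k,
                 objective = objective, interval_optima = opt,
                 c_star = opt$c_opt[best], B_star = opt$B[best],
                 trace = data.frame(cofactor = trace_c, B = trace_B)),
            class = "cofactor_scan")
}

#' @export
print.cofactor_scan <- function(x, ...) {
  cat("cofactor_scan: channel '", x$channel, "', ", x$k,
      " log-interval(s) on [", format(exp(x$c_low), digits = 4), ", ",
      format(exp(x$c_high), digits = 6), "]\n", sep = "")
  cat("  objective: ", x$objective, "; evaluations: ", nrow(x$trace),
      "\n", sep = "")
  cat("  c* = ", format(x$c_star, digits = 6), "  (ln c* = ",
      format(log(x$c_star), digits = 4), "),  B(c*) = ",
      format(x$B_star, digits = 6), "\n", sep = "")
  invisible(x)
}

is_scatter_channel <- function(channel) {
  grepl("^(FSC|SSC)", channel, ignore.case = TRUE) |
    grepl("(FORWARD|SIDE)[ ._-]?SCATTER", channel, ignore.case = TRUE)
}

#' Variance-stabilize selected channels of a dataset
#'
#' Runs \code{\link{optimize_cofactor}} independently for each requested
#' fluorescence channel (channels are treated as independent; joint
#' multi-channel stabilization is out of scope), then transforms that
#' channel in every sample with the single selected cofactor
#' \code{asinh(z / c*)}. Using one cofactor per channel across all samples
#' keeps populations comparable between samples. Scatter channels
#' (FSC*/SSC*) are skipped with a warning: transforming light scatter
#' brings little benefit. A channel whose optimization fails is reported
#' and skipped; the remaining channels are still processed.
#'
#' @param samples list of \code{\link{fc_sample}} objects.
#' @param channels character vector of channel names to stabilize.
#' @param c_low,c_high,tol,objective,... passed to
#'   \code{\link{optimize_cofactor}}.
#' @return a \code{vs_result}: list with \code{cofactors} (named list of
#'   \code{cofactor_scan} per channel), \code{summary} (data frame:
#'   \code{channel}, \code{cofactor}, \code{B}), \code{transformed} (the
#'   samples with stabilized channels replaced), and \code{failed} (named
#'   character vector of per-channel error messages, possibly empty).
#' @export
stabilize_dataset <- function(samples, channels, c_low = -2, c_high = 10,
                              tol = 1e-4, objective = "bartlett", ...) {
  if (inherits(samples, "fc_sample")) samples <- list(samples)
  scatter <- is_scatter_channel(channels)
  if (any(scatter)) {
    warning("skipping scatter channel(s): ",
            paste(channels[scatter], collapse = ", "), call. = FALSE)
    channels <- channels[!scatter]
  }
  scans <- list()
  failed <- character(0)
  for (ch in channels) {
    res <- tryCatch(
      optimize_cofactor(samples, ch, c_low = c_low, c_high = c_high,
                        tol = tol, objective = objective, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[ch] <- conditionMessage(res)
      warning("channel '", ch, "' failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      scans[[ch]] <- res
    }
  }
  transformed <- lapply(samples, function(s) {
    for (ch in names(scans)) {
      s$exprs[, ch] <- asinh_transform(s$exprs[, ch], scans[[ch]]$c_star)
    }
    s
  })
  summary <- data.frame(
    channel = names(scans),
    cofactor = vapply(scans, function(z) z$c_star, 1),
    B = vapply(scans, function(z) z$B_star, 1),
    row.names = NULL)
  structure(list(cofactors = scans, summary = summary,
                 transformed = transformed, failed = failed),
            class = "vs_result")
}

#' @export
print.vs_result <- function(x, ...) {
  cat("vs_result over", length(x$transformed), "sample(s)\n")
  print(x$summary, ...)
  if (length(x$failed)) {
    cat("failed channels:", paste(names(x$failed), collapse = ", "), "\n")
  }
  invisible(x)
}
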