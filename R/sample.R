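#' Construct a flow-cytometry sample
#'
#' Container for one list-mode sample: an events-by-channels matrix of
#' (compensated) fluorescence intensities together with channel names and
#' acquisition keywords. Negative values are legitimate after compensation
#' and are kept as-is.
#'
#' @param exprs numeric matrix, rows = events, columns = channels.
#' @param channels character vector of unique channel names (the FCS $PnN
#'   short names); defaults to \code{colnames(exprs)}.
#' @param sample_id single string identifying the sample.
#' @param metadata named character list of acquisition keywords.
#' @return an object of class \code{fc_sample} with elements \code{exprs},
#'   \code{channels}, \code{sample_id}, \code{metadata}.
#' @export
fc_sample <- function(exprs, channels = colnames(exprs),
                      sample_id = "sample", metadata = list()) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(channels)) {
    stop("channel names are required (supply 'channels' or column names)",
         call. = FALSE)
  }
  channels <- as.character(channels)
  if (ncol(exprs) != length(channels)) {
    stop("number of columns must equal the number of channel names",
         call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("duplicate channel name(s): ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(exprs) >= 1L && any(!is.finite(exprs))) {
    stop("event values must be finite", call. = FALSE)
  }
  colnames(exprs) <- channels
  structure(list(exprs = exprs, channels = channels,
                 sample_id = as.character(sample_id)[1],
                 metadata = metadata),
            class = "fc_sample")
}

#' @export
print.fc_sample <- function(x, ...) {
  cat("fc_sample '", x$sample_id, "': ", nrow(x$exprs), " events x ",
      length(x$channels), " channels\n", sep = "")
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fc_sample <- function(x) dim(x$exprs)

channel_values <- function(sample, channel) {
  if (!channel %in% sample$channels) {
    stop("channel '", channel, "' not found in sample '",
         sample$sample_id, "'", call. = FALSE)
  }
  sample$exprs[, channel]
}

#' Gate specifications
#'
#' \code{rectangle_gate} selects events with
#' \code{x_min <= x <= x_max} and \code{y_min <= y <= y_max} (inclusive);
#' \code{ellipse_gate} selects events whose Mahalanobis distance to
#' \code{center} under \code{shape} is at most \code{threshold}. Chained,
#' these express the usual two-step lymphocyte gate: a rectangle in the low
#' scatter corner followed by a dense ellipse within it. Gate placement is
#' dataset-specific and supplied by the user.
#'
#' @param channel_x,channel_y names of the two gating channels.
#' @param x_min,x_max,y_min,y_max rectangle bounds (\code{x_min < x_max},
#'   \code{y_min < y_max}).
#' @param center numeric length-2 ellipse center.
#' @param shape 2x2 symmetric positive-definite matrix (covariance-like).
#' @param threshold positive Mahalanobis-distance cutoff.
#' @return a \code{gate_spec} object for \code{\link{apply_gate}}.
#' @export
rectangle_gate <- function(channel_x, channel_y, x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop("rectangle bounds must satisfy x_min < x_max and y_min < y_max",
         call. = FALSE)
  }
  structure(list(kind = "rectangle", channel_x = channel_x,
                 channel_y = channel_y,
                 bounds = c(x_min = x_min, x_max = x_max,
                            y_min = y_min, y_max = y_max)),
            class = "gate_spec")
}

#' @rdname rectangle_gate
#' @export
ellipse_gate <- function(channel_x, channel_y, center, shape, threshold) {
  center <- as.numeric(center)
  shape <- as.matrix(shape)
  if (length(center) != 2L || !all(dim(shape) == c(2L, 2L))) {
    stop("'center' must have length 2 and 'shape' must be 2x2",
         call. = FALSE)
  }
  if (max(abs(shape - t(shape))) > 1e-8 * max(abs(shape), 1) ||
      any(eigen(shape, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("'shape' must be symmetric positive definite", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("'threshold' must be positive", call. = FALSE)
  }
  structure(list(kind = "ellipse", channel_x = channel_x,
                 channel_y = channel_y, center = center, shape = shape,
                 threshold = threshold),
            class = "gate_spec")
}

#' Apply a gate to a sample
#'
#' Returns a new sample containing exactly the events inside the gate, in
#' their original order. Rectangle bounds are inclusive; the ellipse keeps
#' events with Mahalanobis distance to the center at most the threshold.
#'
#' @param sample an \code{\link{fc_sample}}.
#' @param gate a \code{gate_spec} from \code{\link{rectangle_gate}} or
#'   \code{\link{ellipse_gate}}.
#' @return gated \code{fc_sample}; a warning is raised if no event passes.
#' @export
apply_gate <- function(sample, gate) {
  stopifnot(inherits(sample, "fc_sample"), inherits(gate, "gate_spec"))
  x <- channel_values(sample, gate$channel_x)
  y <- channel_values(sample, gate$channel_y)
  keep <- if (gate$kind == "rectangle") {
    b <- gate$bounds
    x >= b["x_min"] & x <= b["x_max"] & y >= b["y_min"] & y <= b["y_max"]
  } else {
    d <- cbind(x - gate$center[1], y - gate$center[2])
    md2 <- rowSums((d %*% solve(gate$shape)) * d)
    md2 <= gate$threshold^2
  }
  if (!any(keep)) warning("gate retained no events", call. = FALSE)
  out <- sample
  out$exprs <- sample$exprs[keep, , drop = FALSE]
  out
}
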