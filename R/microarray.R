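#' Construct an expression matrix
#'
#' Genes-by-samples container for microarray mode. Each gene's expressions
#' across the samples form one variance group, so the same Bartlett
#' machinery used on density peaks applies with groups given by genes
#' instead of detected peaks. Rows containing any non-finite value are
#' dropped (with a warning): a gene with missing intensities cannot
#' contribute a variance.
#'
#' @param values numeric matrix, rows = genes, columns = samples (>= 2).
#' @param gene_ids unique gene identifiers; default rownames or g1..gm.
#' @param sample_ids sample identifiers; default colnames or s1..sN.
#' @return an \code{expression_matrix} object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique", call. = FALSE)
  bad <- !apply(is.finite(values), 1L, all)
  if (any(bad)) {
    warning(sum(bad), " gene row(s) with non-finite values dropped",
            call. = FALSE)
    values <- values[!bad, , drop = FALSE]
    gene_ids <- gene_ids[!bad]
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  invisible(x)
}

#' Read / write a delimited expression matrix
#'
#' Plain-text layout: first column gene ids, header row of sample ids,
#' tab- (or other-) separated numeric values.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return \code{read_expression_matrix}: an
#'   \code{\link{expression_matrix}}; \code{write_expression_matrix}:
#'   \code{path}, invisibly.
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 3L) {
    stop("malformed matrix file '", path,
         "': need a gene-id column plus >= 2 sample columns", call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))[1] + 1L
    stop("malformed matrix file '", path, "': column ", bad,
         " is not numeric", call. = FALSE)
  }
  expression_matrix(vals, gene_ids = as.character(df[[1]]),
                    sample_ids = colnames(df)[-1])
}

#' @rdname read_expression_matrix
#' @param mat an \code{\link{expression_matrix}}.
#' @export
write_expression_matrix <- function(mat, path, sep = "\t") {
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(gene_id = mat$gene_ids, mat$values,
                   check.names = FALSE, row.names = NULL)
  colnames(df) <- c("gene_id", mat$sample_ids)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene variance groups at a candidate cofactor
#'
#' Transforms the whole matrix by \code{asinh(x / c)} and summarizes each
#' gene as one group of size \code{N} (samples) with its mean and unbiased
#' variance across samples. Genes with near-zero variance on the
#' transformed scale are dropped with a warning. The result is packaged as
#' a \code{peak_set} so \code{\link{bartlett_statistic}} applies unchanged;
#' with equal group sizes the correction term of the statistic is exact and
#' cheap.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param cofactor positive asinh cofactor.
#' @return a \code{peak_set} whose "peaks" are genes (\code{sample_id}
#'   holds the gene id; \code{mode}, \code{lo}, \code{hi} are \code{NA}).
#' @export
gene_groups <- function(mat, cofactor) {
  stopifnot(inherits(mat, "expression_matrix"))
  tv <- asinh_transform(mat$values, cofactor)
  mu <- rowMeans(tv)
  v <- apply(tv, 1L, stats::var)
  ok <- v >= 1e-12
  if (!all(ok)) {
    warning(sum(!ok), " gene(s) with near-zero variance dropped",
            call. = FALSE)
  }
  nsamp <- ncol(mat$values)
  peaks <- data.frame(sample_id = mat$gene_ids[ok],
                      mode = rep(NA_real_, sum(ok)),
                      lo = rep(NA_real_, sum(ok)),
                      hi = rep(NA_real_, sum(ok)),
                      n = rep.int(nsamp, sum(ok)), mu = mu[ok], var = v[ok])
  rownames(peaks) <- NULL
  m <- nrow(peaks)
  n <- m * nsamp
  structure(list(channel = "expression", cofactor = cofactor,
                 peaks = peaks, m = m, n = n,
                 pooled_var = if (m >= 1L)
                   sum((peaks$n - 1) * peaks$var) / (n - m) else NA_real_,
                 valid = m >= 1L),
            class = "peak_set")
}

#' Select one cofactor stabilizing per-gene variances
#'
#' Microarray counterpart of \code{\link{optimize_cofactor}}: the same
#' unit-log-interval piecewise search, but the objective at cofactor c is
#' Bartlett's statistic over the per-gene groups of
#' \code{\link{gene_groups}}. A single cofactor is selected for all genes.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param c_low,c_high,tol as in \code{\link{optimize_cofactor}}.
#' @return a \code{cofactor_scan}.
#' @export
optimize_cofactor_microarray <- function(mat, c_low = -2, c_high = 10,
                                         tol = 1e-4) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (!(c_low < c_high)) stop("need c_low < c_high", call. = FALSE)
  breaks <- seq(c_low, c_high, by = 1)
  if (breaks[length(breaks)] < c_high) breaks <- c(breaks, c_high)
  k <- length(breaks) - 1L
  trace_c <- numeric(0)
  trace_B <- numeric(0)
  f <- function(cof) {
    gg <- suppressWarnings(gene_groups(mat, cof))
    b <- if (gg$m < 2L) Inf else bartlett_statistic(gg)
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
    stop("optimization failed: no cofactor yielded >= 2 gene groups",
         call. = FALSE)
  }
  best_B <- min(opt$B)
  cand <- which(opt$B == best_B)
  best <- cand[which.min(opt$c_opt[cand])]
  structure(list(channel = "expression", c_low = c_low, c_high = c_high,
                 k = k, objective = "bartlett", interval_optima = opt,
                 c_star = opt$c_opt[best], B_star = opt$B[best],
                 trace = data.frame(cofactor = trace_c, B = trace_B)),
            class = "cofactor_scan")
}

#' Mean-sd profile of an expression matrix
#'
#' Diagnostic behind mean-versus-variance plots: per-gene mean and standard
#' deviation (optionally after an asinh transformation), the rank of each
#' gene's mean (ties broken by gene order), and a running median of the sd
#' over a sliding window along the mean ranks. A flat running-median curve
#' indicates stabilized variance; a rising one indicates the usual
#' mean-variance dependence of raw fluorescence intensities.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param cofactor optional positive cofactor; when supplied the profile is
#'   computed on \code{asinh(x / cofactor)}.
#' @param window odd window width for the running median; default
#'   \code{max(51, m/20)} rounded up to odd, capped at the gene count.
#' @return data frame (one row per gene, ordered by rank):
#'   \code{gene_id}, \code{mean}, \code{sd}, \code{rank_of_mean},
#'   \code{running_median_sd}.
#' @export
mean_sd_profile <- function(mat, cofactor = NULL, window = NULL) {
  stopifnot(inherits(mat, "expression_matrix"))
  v <- if (is.null(cofactor)) mat$values
       else asinh_transform(mat$values, cofactor)
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  m <- length(mu)
  rk <- rank(mu, ties.method = "first")
  if (is.null(window)) window <- max(51, ceiling(m / 20))
  window <- min(as.integer(window), m)
  if (window %% 2L == 0L) window <- window + 1L
  ord <- order(rk)
  rm_sd <- numeric(m)
  # endrule "constant" repeats the first/last full-window median at the
  # edges; shrinking edge windows would be far noisier than the interior
  rm_sd[ord] <- stats::runmed(sd[ord], k = min(window, m - (m + 1) %% 2),
                              endrule = "constant")
  out <- data.frame(gene_id = mat$gene_ids, mean = mu, sd = sd,
                    rank_of_mean = rk, running_median_sd = rm_sd)
  out[ord, , drop = FALSE]
}
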