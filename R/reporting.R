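#' Export a peak set or scan trace as delimited text
#'
#' \code{write_peak_table} writes one row per peak (sample_id, mode, lo,
#' hi, n, mu, var); \code{write_scan_trace} writes every (cofactor,
#' objective value) evaluation of a scan, the data behind
#' objective-versus-cofactor curves.
#'
#' @param ps a \code{peak_set}.
#' @param scan a \code{cofactor_scan}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_peak_table <- function(ps, path) {
  stopifnot(inherits(ps, "peak_set"))
  df <- cbind(channel = ps$channel, cofactor = ps$cofactor, ps$peaks)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
write_scan_trace <- function(scan, path) {
  stopifnot(inherits(scan, "cofactor_scan"))
  tr <- scan$trace
  names(tr) <- c("cofactor", scan$objective)
  utils::write.table(tr[order(tr$cofactor), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stabilize a set of FCS files end to end
#'
#' Workflow driver: read FCS files, optionally apply a gate chain, select a
#' variance-stabilizing cofactor per channel, transform, and write all
#' artifacts to \code{out_dir}: per-channel scan traces
#' (\code{scan_<channel>.tsv}), per-channel peak tables at the selected
#' cofactor (\code{peaks_<channel>.tsv}), a cofactor summary table
#' (\code{cofactors.tsv}), a JSON summary with settings
#' (\code{summary.json}), and the transformed samples as FCS
#' (\code{vs_<input name>.fcs}).
#'
#' @param paths character vector of FCS file paths (>= 1).
#' @param channels channels to stabilize.
#' @param out_dir output directory (created if needed).
#' @param gates optional list of \code{gate_spec} objects applied in order
#'   to every sample before stabilization.
#' @param c_low,c_high,tol,objective,... passed to
#'   \code{\link{stabilize_dataset}}.
#' @return the \code{vs_result}, invisibly.
#' @export
run_stabilize <- function(paths, channels, out_dir, gates = NULL,
                          c_low = -2, c_high = 10, tol = 1e-4,
                          objective = "bartlett", ...) {
  stopifnot(length(paths) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- lapply(paths, read_fcs)
  if (!is.null(gates)) {
    for (g in gates) samples <- lapply(samples, apply_gate, gate = g)
  }
  res <- stabilize_dataset(samples, channels, c_low = c_low,
                           c_high = c_high, tol = tol,
                           objective = objective, ...)
  if (length(res$cofactors) == 0L) {
    stop("all requested channels failed; no output written", call. = FALSE)
  }
  for (ch in names(res$cofactors)) {
    scan <- res$cofactors[[ch]]
    write_scan_trace(scan, file.path(out_dir, paste0("scan_", ch, ".tsv")))
    ps <- suppressWarnings(collect_peaks(samples, ch, scan$c_star, ...))
    write_peak_table(ps, file.path(out_dir, paste0("peaks_", ch, ".tsv")))
  }
  utils::write.table(res$summary, file.path(out_dir, "cofactors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(objective = objective, c_low = c_low, c_high = c_high, tol = tol,
         cofactors = stats::setNames(as.list(res$summary$cofactor),
                                     res$summary$channel),
         B = stats::setNames(as.list(res$summary$B), res$summary$channel),
         failed = as.list(res$failed)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  for (i in seq_along(res$transformed)) {
    out <- file.path(out_dir, paste0(
      "vs_", sub("\\.[^.]*$", "", basename(paths[i])), ".fcs"))
    write_fcs(res$transformed[[i]], out)
  }
  invisible(res)
}

#' Stabilize an expression matrix end to end
#'
#' Reads a delimited genes-by-samples matrix, selects the single
#' variance-stabilizing cofactor, and writes: the scan trace
#' (\code{scan_expression.tsv}), the transformed matrix
#' (\code{transformed_matrix.tsv}), mean-sd profiles before and after
#' transformation (\code{profile_raw.tsv}, \code{profile_vs.tsv}), and a
#' JSON summary (\code{summary.json}).
#'
#' @param path delimited matrix file (see
#'   \code{\link{read_expression_matrix}}).
#' @param out_dir output directory.
#' @param c_low,c_high,tol passed to
#'   \code{\link{optimize_cofactor_microarray}}.
#' @param sep field separator of the input file.
#' @return the \code{cofactor_scan}, invisibly.
#' @export
run_microarray <- function(path, out_dir, c_low = -2, c_high = 10,
                           tol = 1e-4, sep = "\t") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression_matrix(path, sep = sep)
  scan <- optimize_cofactor_microarray(mat, c_low = c_low, c_high = c_high,
                                       tol = tol)
  write_scan_trace(scan, file.path(out_dir, "scan_expression.tsv"))
  tmat <- mat
  tmat$values <- asinh_transform(mat$values, scan$c_star)
  write_expression_matrix(tmat,
                          file.path(out_dir, "transformed_matrix.tsv"))
  utils::write.table(mean_sd_profile(mat),
                     file.path(out_dir, "profile_raw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mean_sd_profile(mat, cofactor = scan$c_star),
                     file.path(out_dir, "profile_vs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(c_low = c_low, c_high = c_high, tol = tol,
         cofactor = scan$c_star, B = scan$B_star,
         genes = nrow(mat$values), samples = ncol(mat$values)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(scan)
}

#' Between/within ratios for metaclusters in a peak table
#'
#' Reads cluster summaries (columns \code{n}, \code{mu}, \code{var} plus a
#' grouping column naming the metacluster each cluster belongs to) and
#' computes the between- to within-cluster variance ratio per metacluster
#' with \code{\link{between_within_ratio}}. Metaclusters with fewer than
#' two clusters are skipped with a warning.
#'
#' @param peaks data frame of cluster summaries, or path to a TSV with the
#'   same columns.
#' @param group name of the grouping column (default "metacluster").
#' @return data frame with columns \code{metacluster}, \code{k} (cluster
#'   count) and \code{ratio}, one row per scored metacluster.
#' @export
metacluster_ratio_table <- function(peaks, group = "metacluster") {
  if (is.character(peaks) && length(peaks) == 1L) {
    peaks <- utils::read.table(peaks, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  need <- c("n", "mu", "var", group)
  if (!all(need %in% names(peaks))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(peaks, peaks[[group]]), function(g) {
    if (nrow(g) < 2L) {
      warning("metacluster '", g[[group]][1],
              "' has fewer than 2 clusters; skipped", call. = FALSE)
      return(NULL)
    }
    data.frame(metacluster = g[[group]][1], k = nrow(g),
               ratio = between_within_ratio(g$n, g$mu, g$var))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(metacluster = character(0), k = integer(0),
                      ratio = numeric(0))
  }
  rownames(out) <- NULL
  out
}
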