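#' Simulate a multi-sample flow-cytometry dataset with a known cofactor
#'
#' Generates the structure the stabilization algorithm assumes: each
#' channel value arises from a cell population that is Gaussian on the
#' transformed scale. For every event a population is drawn by weight, a
#' transformed-scale value \code{t ~ N(mu_t + sample_shift, sigma_t)} is
#' drawn, and the raw intensity is \code{z = true_cofactor * sinh(t)} -- the
#' exact inverse of the asinh transform, so \code{asinh(z/true_cofactor) =
#' t} by construction and the population variances are homogeneous exactly
#' at the true cofactor. Because \code{sinh} is convex and increasing on
#' positive values, raw-scale peak variance grows with raw-scale MFI when
#' the \code{sigma_t} are equal, reproducing the mean-variance dependence
#' characteristic of untransformed fluorescence data.
#'
#' Per-sample shifts (sd \code{mfi_jitter}) displace the population MFIs,
#' emulating between-subject variation; they never touch \code{sigma_t},
#' since stabilization targets variances while MFI differences can carry
#' biological signal.
#'
#' @param n_samples number of samples.
#' @param populations data frame with columns \code{weight} (summing to 1),
#'   \code{mu_t}, \code{sigma_t} -- population mixture on the transformed
#'   scale. Default: two populations (negative at 1.0, positive at 4.0) of
#'   equal weight with common \code{sigma_t = 0.35}.
#' @param true_cofactor ground-truth cofactor (raw intensity units).
#' @param events_per_sample events per sample.
#' @param mfi_jitter sd of the per-sample shift added to every
#'   \code{mu_t} (transformed-scale units; default 0.2).
#' @param channel name given to the simulated channel (default "FL1").
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @return list of \code{\link{fc_sample}} objects, one channel each.
#' @export
simulate_fc_dataset <- function(n_samples = 3L,
                                populations = data.frame(
                                  weight = c(0.5, 0.5),
                                  mu_t = c(1.0, 4.0),
                                  sigma_t = c(0.35, 0.35)),
                                true_cofactor = exp(4),
                                events_per_sample = 10000L,
                                mfi_jitter = 0.2,
                                channel = "FL1",
                                seed = 1L) {
  stopifnot(n_samples >= 1L, events_per_sample >= 1L,
            true_cofactor > 0, mfi_jitter >= 0)
  w <- populations$weight
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8) {
    stop("population weights must be positive and sum to 1", call. = FALSE)
  }
  if (any(populations$sigma_t <= 0)) {
    stop("population sigma_t must be positive", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_samples), function(j) {
    shift <- stats::rnorm(1L, 0, mfi_jitter)
    lab <- sample.int(nrow(populations), events_per_sample, replace = TRUE,
                      prob = w)
    t <- stats::rnorm(events_per_sample,
                      mean = populations$mu_t[lab] + shift,
                      sd = populations$sigma_t[lab])
    z <- matrix(true_cofactor * sinh(t), ncol = 1L)
    fc_sample(z, channels = channel,
              sample_id = sprintf("sim%02d", j),
              metadata = list(true_cofactor = as.character(true_cofactor)))
  })
}

#' Simulate an expression matrix with a known cofactor
#'
#' Gene i receives transformed-scale values \code{t_ij ~ N(mu_i, sigma_t)}
#' with the gene means \code{mu_i} spread evenly over \code{mean_range};
#' raw intensities are \code{x_ij = true_cofactor * sinh(t_ij)}. Per-gene
#' variance is homogeneous on the \code{asinh(x/true_cofactor)} scale by
#' construction, while on the raw scale per-gene sd grows with per-gene
#' mean (the untransformed microarray mean-variance shape).
#'
#' @param m_genes number of genes (>= 10).
#' @param n_samples number of samples (>= 2).
#' @param true_cofactor ground-truth cofactor.
#' @param sigma_t transformed-scale per-gene sd (default 0.2).
#' @param mean_range length-2 range over which gene means are spread
#'   (transformed scale; default \code{c(0.5, 5)}).
#' @param seed integer seed.
#' @return an \code{\link{expression_matrix}}.
#' @export
simulate_expression_matrix <- function(m_genes = 2000L, n_samples = 6L,
                                       true_cofactor = exp(6),
                                       sigma_t = 0.2,
                                       mean_range = c(0.5, 5),
                                       seed = 1L) {
  stopifnot(m_genes >= 10L, n_samples >= 2L, true_cofactor > 0,
            sigma_t > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- seq(mean_range[1], mean_range[2], length.out = m_genes)
  t <- matrix(stats::rnorm(m_genes * n_samples, mean = mu, sd = sigma_t),
              nrow = m_genes, ncol = n_samples)
  expression_matrix(true_cofactor * sinh(t),
                    gene_ids = sprintf("g%05d", seq_len(m_genes)),
                    sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

# Save/restore the global RNG state so simulators are pure functions of
# their seed without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
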