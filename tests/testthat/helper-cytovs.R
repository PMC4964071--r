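# Shared fixtures, built in code at test time.

# Two-channel dataset: channel FL1 with true cofactor c1, FL2 with c2.
make_two_channel_dataset <- function(c1, c2, n_samples = 3L,
                                     events = 5000L, seed = 1L) {
  d1 <- simulate_fc_dataset(n_samples = n_samples, true_cofactor = c1,
                            events_per_sample = events, seed = seed)
  d2 <- simulate_fc_dataset(n_samples = n_samples, true_cofactor = c2,
                            events_per_sample = events, seed = seed + 1000L)
  lapply(seq_len(n_samples), function(j) {
    fc_sample(cbind(d1[[j]]$exprs, d2[[j]]$exprs),
              channels = c("FL1", "FL2"),
              sample_id = d1[[j]]$sample_id)
  })
}

# Raw-scale summaries of the peak regions found at a given cofactor:
# events are assigned on the transformed scale, statistics taken on the
# raw values, giving the pre-transformation mean/variance of each peak.
raw_peak_stats <- function(samples, channel, cofactor, ...) {
  ps <- suppressWarnings(collect_peaks(samples, channel, cofactor, ...))
  rows <- lapply(seq_len(nrow(ps$peaks)), function(i) {
    p <- ps$peaks[i, ]
    s <- samples[[which(vapply(samples, function(x) x$sample_id, "") ==
                          p$sample_id)]]
    z <- s$exprs[, channel]
    t <- asinh_transform(z, cofactor)
    zin <- z[t >= p$lo & t < p$hi]
    data.frame(raw_mu = mean(zin), raw_var = stats::var(zin))
  })
  cbind(ps$peaks, do.call(rbind, rows))
}

# Hand-rolled FCS 3.0 integer-mode writer used as an independent oracle for
# the reader: the byte layout is constructed explicitly in the test.
write_fcs_int16 <- function(path, values, channels, pnr = 1024L) {
  npar <- ncol(values)
  ntot <- nrow(values)
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$MODE", "L", "$DATATYPE", "I", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0", "$PAR", as.character(npar),
          "$TOT", as.character(ntot))
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dB", i), "16",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), channels[i],
            sprintf("$P%dR", i), as.character(pnr))
  }
  build <- function(db, de) {
    paste0(delim, paste0(c(kw, "$BEGINDATA", db, "$ENDDATA", de),
                         delim, collapse = ""))
  }
  db <- 58L; de <- 58L
  for (it in 1:5) {
    text <- build(db, de)
    nb <- 58L + nchar(text)
    ne <- nb + 2L * npar * ntot - 1L
    if (nb == db && ne == de) break
    db <- nb; de <- ne
  }
  text <- build(db, de)
  fmt8 <- function(x) formatC(x, width = 8L, format = "d")
  header <- paste0("FCS3.0    ", fmt8(58L), fmt8(58L + nchar(text) - 1L),
                   fmt8(db), fmt8(de), fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.integer(t(values)), con, size = 2L, endian = "little")
  invisible(path)
}
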