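#' Read an FCS 3.0/3.1 list-mode file
#'
#' Minimal but standard-conforming reader for list-mode FCS 3.0 and 3.1
#' files with float (\code{$DATATYPE F}), double (\code{D}) or unsigned
#' integer (\code{I}) storage, little- or big-endian byte order. All
#' parameters are returned as channels; values are neither transformed nor
#' truncated (compensated negative values pass through). Integer parameters
#' are masked to the number of bits implied by their stated range
#' \code{$PnR}, as list-mode acquisition hardware leaves undefined high
#' bits. Channel names come from the \code{$PnN} short names; the optional
#' \code{$PnS} stain names and all other TEXT keywords are preserved in
#' \code{metadata}.
#'
#' @param path path to an FCS file.
#' @return an \code{\link{fc_sample}}; its \code{sample_id} is the file's
#'   base name without extension.
#' @seealso \code{\link{write_fcs}}
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 58L) stop("FCS header truncated in ", path, call. = FALSE)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' (need FCS3.0/FCS3.1)",
         call. = FALSE)
  }
  hdr_num <- function(a, b) {
    s <- trimws(rawToChar(raw[a:b]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  txt_beg <- hdr_num(11, 18); txt_end <- hdr_num(19, 26)
  dat_beg <- hdr_num(27, 34); dat_end <- hdr_num(35, 42)
  if (is.na(txt_beg) || is.na(txt_end) || txt_beg < 58 || txt_end <= txt_beg) {
    stop("corrupt HEADER segment: bad TEXT offsets", call. = FALSE)
  }
  # offsets are 0-based byte positions of first/last byte, inclusive
  text <- rawToChar(raw[(txt_beg + 1L):(txt_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substr(text, 2L, nchar(text)), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1L, length(parts), 2L)])
  vals <- trimws(parts[seq(2L, length(parts), 2L)])
  std <- startsWith(keys, "$")
  keys[std] <- toupper(keys[std])
  kw <- stats::setNames(as.list(vals), keys)
  need <- function(k) {
    if (is.null(kw[[k]])) stop("required keyword ", k, " missing from TEXT",
                               call. = FALSE)
    kw[[k]]
  }
  if (toupper(need("$MODE")) != "L") {
    stop("only list mode ($MODE L) is supported; got $MODE ",
         kw[["$MODE"]], call. = FALSE)
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- gsub("[^0-9,]", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop("unsupported $BYTEORD '", kw[["$BYTEORD"]], "'",
                      call. = FALSE)
  if (dat_beg == 0 || dat_end == 0) {
    dat_beg <- as.numeric(need("$BEGINDATA"))
    dat_end <- as.numeric(need("$ENDDATA"))
  }
  if (dat_end <= dat_beg || dat_end + 1 > length(raw)) {
    stop("corrupt DATA segment offsets ($BEGINDATA/$ENDDATA)",
         call. = FALSE)
  }
  ch_names <- vapply(seq_len(npar),
                     function(i) need(sprintf("$P%dN", i)), "")
  if (anyDuplicated(ch_names)) {
    stop("duplicate $PnN channel name(s): ",
         paste(unique(ch_names[duplicated(ch_names)]), collapse = ", "),
         call. = FALSE)
  }
  bits <- vapply(seq_len(npar),
                 function(i) as.integer(need(sprintf("$P%dB", i))), 1L)
  databytes <- raw[(dat_beg + 1L):(dat_end + 1L)]
  nvals <- npar * ntot
  if (dtype == "F") {
    if (any(bits != 32L)) stop("$DATATYPE F requires $PnB 32", call. = FALSE)
    mat <- readBin(databytes, "double", n = nvals, size = 4L,
                   endian = endian)
  } else if (dtype == "D") {
    if (any(bits != 64L)) stop("$DATATYPE D requires $PnB 64", call. = FALSE)
    mat <- readBin(databytes, "double", n = nvals, size = 8L,
                   endian = endian)
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(8L, 16L, 32L)) {
      stop("$DATATYPE I supported for uniform $PnB of 8, 16 or 32 only",
           call. = FALSE)
    }
    size <- bits[1] %/% 8L
    if (size < 4L) {
      mat <- as.numeric(readBin(databytes, "integer", n = nvals,
                                size = size, signed = FALSE,
                                endian = endian))
    } else {
      v <- as.numeric(readBin(databytes, "integer", n = nvals, size = 4L,
                              endian = endian))
      v[v < 0] <- v[v < 0] + 2^32
      mat <- v
    }
    rng <- vapply(seq_len(npar), function(i) {
      r <- kw[[sprintf("$P%dR", i)]]
      if (is.null(r)) 2^bits[i] else as.numeric(r)
    }, 1)
    mask_bits <- pmin(bits, pmax(1L, as.integer(ceiling(log2(pmax(rng, 2))))))
    mat <- matrix(mat, nrow = ntot, ncol = npar, byrow = TRUE)
    for (i in seq_len(npar)) {
      if (mask_bits[i] < bits[i]) {
        mat[, i] <- mat[, i] %% 2^mask_bits[i]
      }
    }
    return(fc_sample(mat, ch_names,
                     sample_id = sub("\\.[^.]*$", "", basename(path)),
                     metadata = kw))
  } else {
    stop("unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  }
  if (length(mat) != nvals) {
    stop("DATA segment holds ", length(mat), " values; expected ",
         nvals, " ($PAR x $TOT)", call. = FALSE)
  }
  fc_sample(matrix(mat, nrow = ntot, ncol = npar, byrow = TRUE), ch_names,
            sample_id = sub("\\.[^.]*$", "", basename(path)),
            metadata = kw)
}

#' Write a sample as an FCS 3.1 file
#'
#' Writes list-mode FCS 3.1 with 32-bit float storage, little-endian.
#' Round-tripping through \code{\link{read_fcs}} reproduces event values to
#' 32-bit float precision. Stain names stored in metadata under
#' \code{$PnS} keywords are carried along.
#'
#' @param sample an \code{\link{fc_sample}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "fc_sample"))
  ex <- sample$exprs
  npar <- ncol(ex)
  ntot <- nrow(ex)
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$NEXTDATA", "0",
          "$PAR", as.character(npar), "$TOT", as.character(ntot))
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), sample$channels[i],
            sprintf("$P%dR", i),
            format(max(262144, 2^ceiling(log2(max(abs(ex[, i]), 1) + 1))),
                   scientific = FALSE))
    stain <- sample$metadata[[sprintf("$P%dS", i)]]
    if (!is.null(stain)) kw <- c(kw, sprintf("$P%dS", i), stain)
  }
  if (any(grepl(delim, kw, fixed = TRUE))) {
    stop("keyword values may not contain the TEXT delimiter '", delim, "'",
         call. = FALSE)
  }
  txt_beg <- 58L
  ndata <- 4L * npar * ntot
  # data offsets appear inside TEXT, so fix the segment length iteratively
  build_text <- function(db, de) {
    paste0(delim,
           paste0(c(kw, "$BEGINDATA", format(db, scientific = FALSE),
                    "$ENDDATA", format(de, scientific = FALSE)),
                  delim, collapse = ""))
  }
  db <- txt_beg; de <- txt_beg
  for (it in 1:5) {
    text <- build_text(db, de)
    db_new <- txt_beg + nchar(text)
    de_new <- db_new + ndata - 1L
    if (db_new == db && de_new == de) break
    db <- db_new; de <- de_new
  }
  text <- build_text(db, de)
  txt_end <- txt_beg + nchar(text) - 1L
  fmt8 <- function(x) formatC(x, width = 8L, format = "d")
  header <- paste0("FCS3.1    ", fmt8(txt_beg), fmt8(txt_end),
                   if (de <= 99999999) paste0(fmt8(db), fmt8(de))
                   else paste0(fmt8(0), fmt8(0)),
                   fmt8(0), fmt8(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(ex)), con, size = 4L, endian = "little")
  invisible(path)
}
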