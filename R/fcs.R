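#' Read an FCS 3.0/3.1 event matrix
#'
#' Minimal list-mode reader covering the part of the FCS standard that mass
#' cytometry exports use: a single data set (`$NEXTDATA 0`), `$MODE L`,
#' `$DATATYPE F` (float32) or `D` (float64) with uniform `$PnB`, and byte
#' order `1,2,3,4` (little-endian) or `4,3,2,1` (big-endian). Integer data
#' types, bit-packed widths, escaped TEXT delimiters and multi-segment files
#' are not supported. Marker names are taken from `$PnS` when present and
#' non-blank, else `$PnN`.
#'
#' @param path FCS file.
#' @return numeric matrix (events x markers) with marker column names.
#' @seealso [read_profile()] for the user-facing entry point.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(header) < 58L || substr(header, 1L, 4L) != "FCS3") {
    stop("not an FCS 3.x file: ", path, call. = FALSE)
  }
  off <- function(i) {
    s <- substr(header, 10L + (i - 1L) * 8L + 1L, 10L + i * 8L)
    suppressWarnings(as.numeric(trimws(s)))
  }
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)
  if (anyNA(c(text_start, text_end)) || text_end <= text_start) {
    stop("malformed FCS header in ", path, call. = FALSE)
  }
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1L, useBytes = TRUE)
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- c(parts, "")
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- trimws(parts[seq(2L, length(parts), by = 2L)])
  kw <- as.list(stats::setNames(vals, keys))
  get_kw <- function(k, required = TRUE) {
    if (!k %in% names(kw)) {
      if (required) {
        stop("FCS keyword ", k, " missing in ", path, call. = FALSE)
      }
      return(NULL)
    }
    kw[[k]]
  }
  if (!is.na(data_start) && data_start == 0) data_start <- NA
  if (is.na(data_start)) data_start <- as.numeric(get_kw("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) {
    data_end <- as.numeric(get_kw("$ENDDATA"))
  }
  mode <- get_kw("$MODE")
  if (!identical(mode, "L")) {
    stop("unsupported FCS $MODE '", mode, "' (only list mode)", call. = FALSE)
  }
  dtype <- get_kw("$DATATYPE")
  size <- switch(dtype, F = 4L, D = 8L,
                 stop("unsupported FCS $DATATYPE '", dtype, "'", call. = FALSE))
  endian <- switch(get_kw("$BYTEORD"),
                   "1,2,3,4" = "little", "4,3,2,1" = "big",
                   stop("unsupported FCS $BYTEORD", call. = FALSE))
  par <- as.integer(get_kw("$PAR"))
  tot <- as.integer(get_kw("$TOT"))
  nm <- character(par)
  for (j in seq_len(par)) {
    bits <- get_kw(sprintf("$P%dB", j))
    if (as.integer(bits) != size * 8L) {
      stop("FCS $P", j, "B = ", bits, " inconsistent with $DATATYPE ", dtype,
           call. = FALSE)
    }
    s <- get_kw(sprintf("$P%dS", j), required = FALSE)
    n <- get_kw(sprintf("$P%dN", j))
    nm[j] <- if (!is.null(s) && nzchar(s)) s else n
  }
  expected <- as.numeric(tot) * par * size
  if (!is.na(data_end) && data_end - data_start + 1 < expected) {
    stop("FCS data segment shorter than $TOT x $PAR in ", path, call. = FALSE)
  }
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = tot * par, size = size, endian = endian)
  if (length(vals) < tot * par) {
    stop("truncated FCS data segment in ", path, call. = FALSE)
  }
  matrix(vals, nrow = tot, ncol = par, byrow = TRUE,
         dimnames = list(NULL, nm))
}

#' Write an event matrix as FCS 3.1
#'
#' Emits a single list-mode data set with little-endian float32 values,
#' marker names in `$PnN`, and offsets recorded both in the 58-byte header
#' and in `$BEGINDATA`/`$ENDDATA`. Values round-trip through [read_fcs()]
#' at single precision.
#'
#' @param exprs numeric matrix (events x markers) with marker column names.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(exprs, path) {
  exprs <- as.matrix(exprs)
  nm <- colnames(exprs)
  if (is.null(nm)) stop("exprs must have marker column names", call. = FALSE)
  if (any(grepl("/", nm, fixed = TRUE))) {
    stop("marker names may not contain the FCS delimiter '/'", call. = FALSE)
  }
  n <- nrow(exprs); p <- ncol(exprs)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0", "$NEXTDATA" = "0",
          "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
          "$TOT" = as.character(n), "$PAR" = as.character(p),
          # fixed-width placeholders so the TEXT length is offset-independent
          "$BEGINDATA" = sprintf("%010d", 0), "$ENDDATA" = sprintf("%010d", 0))
  for (j in seq_len(p)) {
    kw[sprintf("$P%dN", j)] <- nm[j]
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
  }
  build_text <- function(kw) {
    paste0("/", paste(names(kw), kw, sep = "/", collapse = "/"), "/")
  }
  text <- build_text(kw)
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_start)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kw)
  fmt8 <- function(x) if (x <= 99999999) sprintf("%8d", x) else sprintf("%8d", 0)
  header <- paste0("FCS3.1    ", fmt8(text_start), fmt8(text_end),
                   fmt8(data_start), fmt8(data_end), fmt8(0L), fmt8(0L))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write: ", path, call. = FALSE))
  on.exit(close(con))
  writeChar(paste0(header, text), con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(exprs)), con, size = 4L, endian = "little")
  invisible(path)
}
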