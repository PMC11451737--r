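#' Read a 2D spectrum from disk
#'
#' Two dialects are supported. `"plain"` is a dependency-free text format: a
#' tab-separated intensity matrix at `path` (rows = indirect dimension) plus a
#' JSON sidecar at `<path>.json` holding `axis_direct`, `axis_indirect`,
#' `nucleus_direct`, `nucleus_indirect` and optionally `noise_rms`. `"nmrpipe"`
#' reads a single-file NMRPipe 2D spectrum (512-word float32 header followed by
#' real intensity planes); ppm axes are reconstructed from the header's sweep
#' width, observe frequency and origin fields. Axes are normalised to ascending
#' order on load.
#'
#' @param path Path to the spectrum file.
#' @param dialect `"plain"` or `"nmrpipe"`.
#' @return A [spectrum2d()].
#' @seealso [write_spectrum()], [write_nmrpipe()]
#' @export
load_spectrum <- function(path, dialect = c("plain", "nmrpipe")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
         plain = load_spectrum_plain(path),
         nmrpipe = read_nmrpipe(path))
}

#' Write a 2D spectrum in the plain text dialect
#'
#' Writes the intensity matrix as tab-separated `%.17g` values (bit-exact
#' round trip for doubles) and a JSON sidecar `<path>.json` with the axes and
#' nucleus labels.
#'
#' @param spec A [spectrum2d()].
#' @param path Output path for the matrix file.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum2d"))
  lines <- apply(spec$intensity, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  meta <- list(axis_direct = spec$axis_direct,
               axis_indirect = spec$axis_indirect,
               nucleus_direct = spec$nucleus_direct,
               nucleus_indirect = spec$nucleus_indirect)
  if (!is.null(spec$noise_rms)) meta$noise_rms <- spec$noise_rms
  # digits = 17 round-trips doubles bit-exactly; digits = NA does not
  jsonlite::write_json(meta, paste0(path, ".json"), digits = 17, auto_unbox = TRUE)
  invisible(path)
}

load_spectrum_plain <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("plain dialect sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("axis_direct", "axis_indirect")) {
    if (is.null(meta[[field]])) {
      stop("plain dialect sidecar is missing field `", field, "`", call. = FALSE)
    }
  }
  rows <- readLines(path)
  rows <- rows[nzchar(rows)]
  mat <- suppressWarnings(
    do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric)))
  if (anyNA(mat)) stop("non-numeric values in intensity matrix: ", path, call. = FALSE)
  if (ncol(mat) != length(meta$axis_direct)) {
    stop("field `axis_direct` has length ", length(meta$axis_direct),
         " but the matrix has ", ncol(mat), " columns", call. = FALSE)
  }
  if (nrow(mat) != length(meta$axis_indirect)) {
    stop("field `axis_indirect` has length ", length(meta$axis_indirect),
         " but the matrix has ", nrow(mat), " rows", call. = FALSE)
  }
  spectrum2d(mat, meta$axis_direct, meta$axis_indirect,
             nucleus_direct = meta$nucleus_direct %||% "13C",
             nucleus_indirect = meta$nucleus_indirect %||% "13C",
             noise_rms = meta$noise_rms)
}

# NMRPipe header word indices (0-based, per fdatap.h)
.fd <- list(MAGIC = 0L, FLTFORMAT = 2L, FLTORDER = 3L, DIMCOUNT = 9L,
            SIZE = 99L, SPECNUM = 219L, QUADFLAG = 106L, TRANSPOSED = 221L,
            F2SW = 100L, F2OBS = 119L, F2ORIG = 101L, F2FTFLAG = 220L,
            F1SW = 229L, F1OBS = 218L, F1ORIG = 249L, F1FTFLAG = 222L,
            F2LABEL = 16L, F1LABEL = 18L)
.fd_fltformat <- 4008636160

#' Read a single-file NMRPipe 2D spectrum
#'
#' Parses the 512-word float32 header, detects byte order from the
#' float-format magic word, and reconstructs ppm axes as
#' `ppm_i = (orig + sw * (n - 1 - i) / n) / obs` for grid index
#' `i = 0..n-1` in each dimension (the NMRPipe frequency-domain convention:
#' the last point sits at the origin frequency). Only real (singly quadrature)
#' frequency-domain planes are supported.
#'
#' @param path Path to a `.ft2`-style NMRPipe file.
#' @return A [spectrum2d()].
#' @export
read_nmrpipe <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr <- readBin(con, "numeric", n = 512, size = 4, endian = endian)
  if (!isTRUE(abs(hdr[.fd$FLTFORMAT + 1L] - .fd_fltformat) < 1)) {
    seek(con, 0)
    endian <- "big"
    hdr <- readBin(con, "numeric", n = 512, size = 4, endian = endian)
    if (!isTRUE(abs(hdr[.fd$FLTFORMAT + 1L] - .fd_fltformat) < 1)) {
      stop("not an NMRPipe file (float-format magic word mismatch): ", path,
           call. = FALSE)
    }
  }
  h <- function(key) hdr[.fd[[key]] + 1L]
  if (h("DIMCOUNT") < 2) {
    stop("field FDDIMCOUNT = ", h("DIMCOUNT"), "; only 2D files are supported",
         call. = FALSE)
  }
  nx <- as.integer(h("SIZE"))     # direct-dimension points per row
  ny <- as.integer(h("SPECNUM"))  # indirect rows
  if (nx < 1 || ny < 1) {
    stop("invalid FDSIZE/FDSPECNUM (", nx, ", ", ny, ") in ", path, call. = FALSE)
  }
  dat <- readBin(con, "numeric", n = nx * ny, size = 4, endian = endian)
  if (length(dat) != nx * ny) {
    stop("field FDSIZE*FDSPECNUM promises ", nx * ny, " points but file holds ",
         length(dat), call. = FALSE)
  }
  mat <- matrix(dat, nrow = ny, ncol = nx, byrow = TRUE)
  spectrum2d(mat,
             axis_direct = pipe_ppm_axis(nx, h("F2SW"), h("F2OBS"), h("F2ORIG")),
             axis_indirect = pipe_ppm_axis(ny, h("F1SW"), h("F1OBS"), h("F1ORIG")),
             nucleus_direct = pipe_label(path, .fd$F2LABEL, endian),
             nucleus_indirect = pipe_label(path, .fd$F1LABEL, endian))
}

# Frequency-domain ppm axis from header arithmetic; descending in grid order.
pipe_ppm_axis <- function(n, sw, obs, orig) {
  if (!is.finite(obs) || obs == 0) {
    stop("field FDOBS is ", obs, "; cannot convert Hz to ppm", call. = FALSE)
  }
  i <- seq_len(n) - 1
  (orig + sw * (n - 1 - i) / n) / obs
}

pipe_label <- function(path, word, endian) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, word * 4L)
  raw8 <- readBin(con, "raw", n = 8)
  raw8 <- raw8[raw8 != as.raw(0)]
  lbl <- tryCatch(rawToChar(raw8), error = function(e) "")
  trimws(lbl)
}

#' Write a minimal single-file NMRPipe 2D spectrum
#'
#' Produces a real frequency-domain file readable by [read_nmrpipe()] (and by
#' NMRPipe-aware tools): 512-word float32 header with size, sweep width,
#' observe frequency and origin fields, followed by row-major float32 planes.
#' Axes are emitted in NMR display order (descending ppm). Intended for
#' interoperability and for constructing binary fixtures in code; float32
#' storage truncates doubles.
#'
#' @param spec A [spectrum2d()].
#' @param path Output path.
#' @param obs_direct,obs_indirect Spectrometer observe frequencies in MHz used
#'   to convert the ppm axes to Hz.
#' @return `path`, invisibly.
#' @export
write_nmrpipe <- function(spec, path, obs_direct = 150, obs_indirect = 150) {
  stopifnot(inherits(spec, "spectrum2d"))
  hdr <- numeric(512)
  set <- function(key, val) hdr[.fd[[key]] + 1L] <<- val
  set("FLTFORMAT", .fd_fltformat)
  set("FLTORDER", 2.345)
  set("DIMCOUNT", 2)
  set("QUADFLAG", 1)
  set("F2FTFLAG", 1); set("F1FTFLAG", 1)
  nx <- ncol(spec$intensity); ny <- nrow(spec$intensity)
  set("SIZE", nx); set("SPECNUM", ny)
  # invert ppm_i = (orig + sw*(n-1-i)/n)/obs for an evenly spaced ppm axis
  hz_params <- function(axis_ppm, obs) {
    hz <- rev(axis_ppm) * obs            # descending ppm -> grid order
    n <- length(hz)
    step <- if (n > 1) hz[1] - hz[2] else 1
    sw <- step * n
    orig <- hz[n]
    c(sw = sw, orig = orig)
  }
  pd <- hz_params(spec$axis_direct, obs_direct)
  pi_ <- hz_params(spec$axis_indirect, obs_indirect)
  set("F2SW", pd[["sw"]]); set("F2OBS", obs_direct); set("F2ORIG", pd[["orig"]])
  set("F1SW", pi_[["sw"]]); set("F1OBS", obs_indirect); set("F1ORIG", pi_[["orig"]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4, endian = "little")
  write_label <- function(word, lbl) {
    raw8 <- raw(8)
    chars <- charToRaw(substr(lbl, 1, 7))
    raw8[seq_along(chars)] <- chars
    seek(con, word * 4L, rw = "write")
    writeBin(raw8, con)
  }
  write_label(.fd$F2LABEL, spec$nucleus_direct)
  write_label(.fd$F1LABEL, spec$nucleus_indirect)
  seek(con, 512L * 4L, rw = "write")
  # grid order: descending ppm in both dimensions, direct fastest
  mat <- spec$intensity[rev(seq_len(ny)), rev(seq_len(nx)), drop = FALSE]
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
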