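#' Human FUS N-terminal sequence
#'
#' Residues 1-163 of human FUS (UniProt P35637-1), with the initiator Met as
#' residue 1. This low-complexity segment (S/T/Q/Y/G-rich) is the region
#' covered by the molecular-dynamics conformer ensembles that the crosspeak
#' simulations operate on.
#'
#' @param range Optional 1-based inclusive `c(from, to)` to subset.
#' @return A single character string of one-letter codes.
#' @export
fus_sequence <- function(range = NULL) {
  seq163 <- paste0(
    "MASNDYTQQATQSYGAYPTQPGQGYSQQSSQPYGQQSYSGYSQSTDTSGY",
    "GQSSYSSYGQSQNTGYGTQSTPQGYGSTGGYGSSQSSQSSYGQQSSYPGY",
    "GQQPAPSSTSGSYGSSSQSSSYGQLPQSGSYSQQPSYGGQQQSYGQQQSY",
    "NPPQGYGQQNQYN")
  if (is.null(range)) return(seq163)
  stopifnot(length(range) == 2, range[1] >= 1, range[2] <= nchar(seq163),
            range[1] <= range[2])
  substr(seq163, range[1], range[2])
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA3 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
         HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
         PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
         TRP = "W", TYR = "Y")

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x Numeric angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

conformer_cols <- c("frame", "residue_index", "residue_type", "phi", "psi",
                    "chi1", "shift_N", "shift_CA", "shift_CB", "shift_CO")

#' Validate a per-conformer torsion/shift table
#'
#' @param df A data frame with columns `frame`, `residue_index`,
#'   `residue_type` (one-letter codes), `phi`, `psi`, `chi1` (degrees),
#'   `shift_N`, `shift_CA`, `shift_CB`, `shift_CO` (ppm; `shift_CB` is `NA`
#'   for Gly). Angles are wrapped to (-180, 180].
#' @return A validated tibble of class `conformer_table`.
#' @export
conformer_table <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(conformer_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[conformer_cols]
  bad_type <- !df$residue_type %in% AA1
  if (any(bad_type)) {
    stop("invalid residue_type at record(s) ",
         paste(utils::head(which(bad_type), 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[c("frame", "residue_index")])) {
    d <- df[duplicated(df[c("frame", "residue_index")]), c("frame", "residue_index")]
    stop("duplicate (frame, residue) pair, first at frame ", d$frame[1],
         " residue ", d$residue_index[1], call. = FALSE)
  }
  df$phi <- wrap_angle(df$phi)
  df$psi <- wrap_angle(df$psi)
  df$chi1 <- wrap_angle(df$chi1)
  df$shift_CB[df$residue_type == "G"] <- NA_real_
  class(df) <- c("conformer_table", class(df))
  df
}

#' Read a per-conformer torsion/shift table
#'
#' Two dialects. `"tsv"`: a single long tab-separated file with a header row
#' naming the columns of [conformer_table()]. `"spartaplus"`: one
#' whitespace-delimited prediction-style file per frame, with `VARS` /
#' `FORMAT` header lines followed by one row per residue (`RESID RESNAME PHI
#' PSI CHI1 N CA CB CO`); `RESNAME` may be one- or three-letter; the value
#' 9999 marks a missing prediction. Frames are numbered by file order.
#' Records that fail validation (non-finite angles, unknown residue) are
#' dropped, counted, and reported in the `n_invalid` attribute and a message.
#'
#' @param path For `"tsv"` a file; for `"spartaplus"` a character vector of
#'   per-frame files or a directory of them.
#' @param dialect `"tsv"` or `"spartaplus"`.
#' @return A [conformer_table()] tibble, with attributes `n_invalid`.
#' @export
parse_conformer_table <- function(path, dialect = c("tsv", "spartaplus")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    df <- tibble::as_tibble(df)
  } else {
    files <- path
    if (length(path) == 1 && dir.exists(path)) {
      files <- sort(list.files(path, full.names = TRUE))
    }
    if (length(files) == 0) stop("no prediction files found", call. = FALSE)
    df <- dplyr::bind_rows(lapply(seq_along(files), function(k) {
      fr <- read_spartaplus_frame(files[k])
      fr$frame <- k
      fr
    }))
  }
  bad <- !is.finite(df$phi) | !is.finite(df$psi) | !df$residue_type %in% AA1
  n_invalid <- sum(bad)
  if (n_invalid > 0) {
    message(n_invalid, " record(s) failed validation and were dropped")
    df <- df[!bad, , drop = FALSE]
  }
  out <- conformer_table(df)
  attr(out, "n_invalid") <- n_invalid
  out
}

read_spartaplus_frame <- function(file) {
  lines <- readLines(file)
  vars_line <- grep("^\\s*VARS\\b", lines, value = TRUE)
  if (length(vars_line) != 1) {
    stop("missing VARS header line in ", file, call. = FALSE)
  }
  vars <- toupper(strsplit(trimws(vars_line), "\\s+")[[1]][-1])
  data_lines <- lines[!grepl("^\\s*(REMARK|VARS|FORMAT|DATA|#|$)", lines)]
  fields <- strsplit(trimws(data_lines), "\\s+")
  mat <- do.call(rbind, fields)
  colnames(mat) <- vars
  need <- c("RESID", "RESNAME", "PHI", "PSI", "CHI1", "N", "CA", "CB", "CO")
  missing_cols <- setdiff(need, vars)
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s) in ", file, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    x[!is.na(x) & abs(x) >= 9999] <- NA_real_
    x
  }
  resname <- unname(toupper(mat[, "RESNAME"]))
  res1 <- unname(ifelse(nchar(resname) == 3, AA3[resname], resname))
  tibble::tibble(
    frame = NA_integer_,
    residue_index = as.integer(mat[, "RESID"]),
    residue_type = res1,
    phi = num(mat[, "PHI"]), psi = num(mat[, "PSI"]), chi1 = num(mat[, "CHI1"]),
    shift_N = num(mat[, "N"]), shift_CA = num(mat[, "CA"]),
    shift_CB = num(mat[, "CB"]), shift_CO = num(mat[, "CO"])
  )
}

#' Write a conformer table as the long TSV dialect
#'
#' @param table A [conformer_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count residue types in a sequence window
#'
#' @param sequence Amino-acid string of one-letter codes.
#' @param range 1-based inclusive `c(from, to)`; `from > to` gives an empty
#'   window (all counts zero).
#' @return A tibble with columns `residue_type` and `count`, one row per
#'   standard amino acid present in the window (count >= 1), plus zero rows
#'   for an empty window.
#' @export
residue_type_counts <- function(sequence, range = c(1, nchar(sequence))) {
  stopifnot(is.character(sequence), length(sequence) == 1, length(range) == 2)
  letters_all <- strsplit(sequence, "")[[1]]
  bad <- which(!letters_all %in% AA1)
  if (length(bad) > 0) {
    stop("invalid amino-acid letter '", letters_all[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  if (range[1] > range[2]) {
    return(tibble::tibble(residue_type = character(), count = integer()))
  }
  stopifnot(range[1] >= 1, range[2] <= nchar(sequence))
  win <- letters_all[range[1]:range[2]]
  tab <- table(factor(win, levels = AA1))
  tab <- tab[tab > 0]
  tibble::tibble(residue_type = names(tab), count = as.integer(tab))
}

#' Total record count for a residue type
#'
#' The per-type total N_T: the number of conformer records (residues x
#' frames) of the given type, the denominator of the reweighting
#' normalisation.
#'
#' @param table A [conformer_table()].
#' @param residue_type One-letter code.
#' @return An integer count.
#' @export
n_total <- function(table, residue_type) {
  sum(table$residue_type == residue_type)
}

new_histogram2d <- function(counts, x_edges, y_edges, axis_kind, labels) {
  stopifnot(is.matrix(counts),
            nrow(counts) == length(x_edges) - 1,
            ncol(counts) == length(y_edges) - 1,
            all(diff(x_edges) > 0), all(diff(y_edges) > 0))
  structure(list(counts = counts, x_edges = x_edges, y_edges = y_edges,
                 axis_kind = axis_kind, labels = labels,
                 total_weight = sum(counts)),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat("<histogram2d> ", nrow(x$counts), " x ", ncol(x$counts), " bins (",
      x$labels[1], " x ", x$labels[2], ", ", x$axis_kind,
      "), total weight ", format(x$total_weight), "\n", sep = "")
  invisible(x)
}

#' Tidy a 2D histogram into a long tibble of bin centers
#'
#' @param x A `histogram2d`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (bin centers) and `weight`.
#' @method tidy histogram2d
#' @export
tidy.histogram2d <- function(x, ...) {
  cx <- (utils::head(x$x_edges, -1) + utils::tail(x$x_edges, -1)) / 2
  cy <- (utils::head(x$y_edges, -1) + utils::tail(x$y_edges, -1)) / 2
  w <- as.vector(x$counts)
  tibble::tibble(x = rep(cx, times = length(cy)),
                 y = rep(cy, each = length(cx)),
                 weight = w)
}

# bin index with half-open bins [lo, hi), last bin closed; 0 = out of range
bin_index <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  i[!is.na(v) & (v < edges[1] | v > edges[length(edges)])] <- 0L
  i[is.na(v)] <- 0L
  i
}

hist2d <- function(x, y, x_edges, y_edges, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ix <- bin_index(x, x_edges)
  iy <- bin_index(y, y_edges)
  keep <- ix > 0 & iy > 0
  nx <- length(x_edges) - 1
  ny <- length(y_edges) - 1
  counts <- matrix(0, nx, ny)
  if (any(keep)) {
    idx <- (iy[keep] - 1) * nx + ix[keep]
    acc <- rowsum(w[keep], idx)
    counts[as.integer(rownames(acc))] <- acc[, 1]
  }
  list(counts = counts, n_excluded = sum(!keep))
}

#' Ramachandran histogram for one residue type
#'
#' Unweighted 2D histogram of (phi, psi) pairs over `[-180, 180)^2`, with
#' half-open bins; the wrap point 180 is folded onto -180. The total weight
#' equals [n_total()] for the residue type.
#'
#' @param table A [conformer_table()].
#' @param residue_type One-letter code.
#' @param bin_width_deg Bin width in degrees; must divide 360 evenly.
#' @return A `histogram2d` with `axis_kind = "torsion"`.
#' @export
ramachandran_histogram <- function(table, residue_type, bin_width_deg = 10) {
  if (360 %% bin_width_deg != 0) {
    stop("bin_width_deg = ", bin_width_deg, " does not divide 360 evenly",
         call. = FALSE)
  }
  sub <- table[table$residue_type == residue_type, ]
  if (nrow(sub) == 0) {
    stop("no records of residue type '", residue_type, "'", call. = FALSE)
  }
  edges <- seq(-180, 180, by = bin_width_deg)
  fold <- function(a) ifelse(a == 180, -180, a)
  h <- hist2d(fold(sub$phi), fold(sub$psi), edges, edges)
  new_histogram2d(h$counts, edges, edges, axis_kind = "torsion",
                  labels = c("phi (deg)", "psi (deg)"))
}

shift_pair_cols <- function(shift_pair) {
  switch(shift_pair,
         CA_CB = c("shift_CA", "shift_CB"),
         CO_CA = c("shift_CO", "shift_CA"),
         N_CA = c("shift_N", "shift_CA"),
         stop("unknown shift_pair: ", shift_pair, call. = FALSE))
}

# bin edges aligned to multiples of the bin width, covering the data
aligned_edges <- function(v, bw) {
  lo <- floor(min(v) / bw) * bw
  hi <- ceiling(max(v) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  seq(lo, hi, by = bw)
}

#' Chemical-shift crosspeak histogram for one residue type
#'
#' 2D histogram of a predicted chemical-shift pair (Ca/Cb, CO/Ca or N/Ca)
#' across all conformer records of a residue type: the simulated counterpart
#' of an inhomogeneously broadened 2D crosspeak before line broadening.
#' Records with a missing shift are excluded and counted (attribute
#' `n_excluded`), so `total_weight + n_excluded` equals [n_total()] when no
#' explicit `ranges` clip the data.
#'
#' @param table A [conformer_table()].
#' @param residue_type One-letter code; `"G"` with `shift_pair = "CA_CB"` is
#'   an error (Gly has no Cb).
#' @param shift_pair `"CA_CB"`, `"CO_CA"` or `"N_CA"` (x_y order).
#' @param bin_width_ppm Bin width in ppm.
#' @param ranges Optional list with `x` and `y` length-2 ranges; default
#'   covers the data, with edges aligned to multiples of the bin width.
#' @param weights Optional per-record weights (same length as `table` rows);
#'   used by the reweighting machinery.
#' @return A `histogram2d` with `axis_kind = "shift"`.
#' @export
crosspeak_histogram <- function(table, residue_type,
                                shift_pair = c("CA_CB", "CO_CA", "N_CA"),
                                bin_width_ppm = 0.5, ranges = NULL,
                                weights = NULL) {
  shift_pair <- match.arg(shift_pair)
  if (residue_type == "G" && shift_pair == "CA_CB") {
    stop("Gly has no Cb: CA_CB crosspeak is undefined for residue type G",
         call. = FALSE)
  }
  sel <- table$residue_type == residue_type
  sub <- table[sel, ]
  if (nrow(sub) == 0) {
    stop("no records of residue type '", residue_type, "'", call. = FALSE)
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(table))
    w <- weights[sel]
  } else {
    w <- rep(1, nrow(sub))
  }
  cols <- shift_pair_cols(shift_pair)
  xv <- sub[[cols[1]]]
  yv <- sub[[cols[2]]]
  ok <- is.finite(xv) & is.finite(yv)
  n_missing <- sum(!ok)
  xv <- xv[ok]; yv <- yv[ok]; w <- w[ok]
  if (length(xv) == 0) stop("all records have missing shifts", call. = FALSE)
  if (is.null(ranges)) {
    x_edges <- aligned_edges(xv, bin_width_ppm)
    y_edges <- aligned_edges(yv, bin_width_ppm)
  } else {
    x_edges <- seq(ranges$x[1], ranges$x[2], by = bin_width_ppm)
    y_edges <- seq(ranges$y[1], ranges$y[2], by = bin_width_ppm)
  }
  h <- hist2d(xv, yv, x_edges, y_edges, w)
  out <- new_histogram2d(h$counts, x_edges, y_edges, axis_kind = "shift",
                         labels = gsub("shift_", "", cols))
  attr(out, "n_excluded") <- n_missing + h$n_excluded
  out
}
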