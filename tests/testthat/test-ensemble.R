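test_that("fus_sequence has the documented length and composition", {
  s <- fus_sequence()
  expect_equal(nchar(s), 163)
  expect_equal(substr(s, 1, 1), "M")
  expect_equal(fus_sequence(c(1, 5)), "MASND")
  expect_error(fus_sequence(c(0, 10)))
  expect_error(fus_sequence(c(1, 200)))
})

test_that("wrap_angle maps into (-180, 180]", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-190), 170)
  expect_equal(wrap_angle(180), 180)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(360), 0)
  expect_equal(wrap_angle(c(0, 540)), c(0, 180))
})

test_that("conformer_table validates columns, types and duplicates", {
  tb <- two_bin_table()
  expect_s3_class(tb, "conformer_table")
  expect_error(conformer_table(tb[, -4]), "missing mandatory column")
  bad <- tb; bad$residue_type[2] <- "X"
  expect_error(conformer_table(bad), "invalid residue_type at record\\(s\\) 2")
  dup <- rbind(tb, tb[1, ])
  expect_error(conformer_table(dup), "duplicate \\(frame, residue\\)")
})

test_that("conformer_table wraps angles and blanks Gly CB", {
  df <- two_bin_table(4, 1)
  df$phi[1] <- 190 # will be re-wrapped on revalidation
  df$residue_type[4] <- "G"
  df$shift_CB[4] <- 45
  out <- conformer_table(df)
  expect_equal(out$phi[1], -170)
  expect_true(is.na(out$shift_CB[4]))
})

test_that("TSV conformer round trip preserves the table", {
  tb <- small_conformer_table(n_frames = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conformer_table(tb, path)
  back <- parse_conformer_table(path, dialect = "tsv")
  expect_equal(as.data.frame(back), as.data.frame(tb), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "n_invalid"), 0)
})

test_that("spartaplus dialect parses frames, 3-letter names and 9999 sentinels", {
  dir <- withr::local_tempdir()
  frame_lines <- function(rows) c(
    "REMARK synthetic prediction table",
    "VARS RESID RESNAME PHI PSI CHI1 N CA CB CO",
    "FORMAT %4d %4s %8.3f %8.3f %8.3f %8.3f %8.3f %8.3f %8.3f",
    "",
    rows)
  writeLines(frame_lines(c(
    "1 THR -140.0 150.0 60.0 113.6 61.8 69.8 174.7",
    "2 GLY  -75.0 145.0 180.0 108.8 45.1 9999.0 174.9")),
    file.path(dir, "frame_001.pred"))
  writeLines(frame_lines(c(
    "1 T    -63.0 -43.0 -60.0 113.6 61.8 69.8 9999.0")),
    file.path(dir, "frame_002.pred"))
  tb <- parse_conformer_table(dir, dialect = "spartaplus")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$frame, c(1, 1, 2))
  expect_equal(tb$residue_type, c("T", "G", "T"))
  expect_true(is.na(tb$shift_CB[2])) # 9999 sentinel and Gly rule agree
  expect_true(is.na(tb$shift_CO[3]))
  expect_equal(tb$phi[3], -63)
})

test_that("invalid spartaplus records are dropped, counted and reported", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "VARS RESID RESNAME PHI PSI CHI1 N CA CB CO",
    "FORMAT %4d %4s %8.3f %8.3f %8.3f %8.3f %8.3f %8.3f %8.3f",
    "1 THR -140.0 150.0 60.0 113.6 61.8 69.8 174.7",
    "2 XXX -140.0 150.0 60.0 113.6 61.8 69.8 174.7",
    "3 SER 9999.0 150.0 60.0 115.7 58.3 63.8 174.6"),
    file.path(dir, "frame_001.pred"))
  expect_message(tb <- parse_conformer_table(dir, dialect = "spartaplus"),
                 "2 record\\(s\\) failed validation")
  expect_equal(nrow(tb), 1)
  expect_equal(attr(tb, "n_invalid"), 2)
})

test_that("spartaplus dialect requires the mandatory header", {
  f <- withr::local_tempfile()
  writeLines(c("1 THR -140 150 60 113 61 69 174"), f)
  expect_error(parse_conformer_table(f, dialect = "spartaplus"),
               "missing VARS header")
  f2 <- withr::local_tempfile()
  writeLines(c("VARS RESID RESNAME PHI PSI",
               "1 THR -140 150"), f2)
  expect_error(parse_conformer_table(f2, dialect = "spartaplus"),
               "missing mandatory column")
})

test_that("residue_type_counts counts a known window and validates letters", {
  out <- residue_type_counts("MASNDY", c(2, 5))
  expect_equal(out$count[out$residue_type == "A"], 1)
  expect_equal(sum(out$count), 4)
  expect_error(residue_type_counts("MAXND"), "'X' at position 3")
  empty <- residue_type_counts("MASND", c(3, 2))
  expect_equal(nrow(empty), 0)
})

test_that("n_total counts records of one residue type", {
  tb <- two_bin_table(7, 2)
  expect_equal(n_total(tb, "T"), 7)
  expect_equal(n_total(tb, "S"), 0)
})

test_that("ramachandran_histogram conserves weight and folds 180 to -180", {
  tb <- small_conformer_table(n_frames = 10)
  h <- ramachandran_histogram(tb, "S", bin_width_deg = 10)
  expect_s3_class(h, "histogram2d")
  expect_equal(h$total_weight, n_total(tb, "S"))
  expect_equal(range(h$x_edges), c(-180, 180))
  expect_error(ramachandran_histogram(tb, "S", bin_width_deg = 7),
               "does not divide 360")
  expect_error(ramachandran_histogram(tb, "W"), "no records")
  # a record exactly at the wrap point lands in the first bin
  tb2 <- two_bin_table(3, 1)
  tb2$phi[1] <- 180; tb2$psi[1] <- 180
  h2 <- ramachandran_histogram(conformer_table(tb2), "T")
  expect_equal(h2$counts[1, 1], 1)
  expect_equal(h2$total_weight, 3)
})

test_that("crosspeak_histogram conserves weight and counts exclusions", {
  tb <- small_conformer_table(n_frames = 10)
  h <- crosspeak_histogram(tb, "T", "CA_CB")
  expect_equal(h$total_weight + attr(h, "n_excluded"), n_total(tb, "T"))
  expect_equal(attr(h, "n_excluded"), 0)
  # Gly has no CB shift: all CA_CB records would be missing
  expect_error(crosspeak_histogram(tb, "G", "CA_CB"), "Gly has no Cb")
  hg <- crosspeak_histogram(tb, "G", "CO_CA")
  expect_equal(hg$total_weight, n_total(tb, "G"))
  # explicit ranges clip and count
  hr <- crosspeak_histogram(tb, "T", "CA_CB",
                            ranges = list(x = c(0, 1), y = c(0, 1)))
  expect_equal(hr$total_weight, 0)
  expect_equal(attr(hr, "n_excluded"), n_total(tb, "T"))
})

test_that("crosspeak_histogram default edges align to the bin width", {
  tb <- small_conformer_table(n_frames = 5)
  h <- crosspeak_histogram(tb, "T", "CA_CB", bin_width_ppm = 0.5)
  expect_true(all(abs(h$x_edges * 2 - round(h$x_edges * 2)) < 1e-9))
  expect_equal(unique(round(diff(h$x_edges), 9)), 0.5)
})

test_that("crosspeak_histogram applies per-record weights", {
  tb <- two_bin_table(10, 3)
  w <- rep(2, nrow(tb))
  h1 <- crosspeak_histogram(tb, "T", "CA_CB")
  h2 <- crosspeak_histogram(tb, "T", "CA_CB", weights = w)
  expect_equal(h2$counts, 2 * h1$counts)
  expect_error(crosspeak_histogram(tb, "T", "CA_CB", weights = c(1, 2)))
})

test_that("tidy.histogram2d returns bin centers with matching weights", {
  tb <- two_bin_table(10, 3)
  h <- crosspeak_histogram(tb, "T", "CA_CB", bin_width_ppm = 1)
  td <- tidy(h)
  expect_named(td, c("x", "y", "weight"))
  expect_equal(sum(td$weight), h$total_weight)
  # the beta bin holds 3 records at (58.2, 73.2)
  expect_equal(td$weight[td$x == 58.5 & td$y == 73.5], 3)
})
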