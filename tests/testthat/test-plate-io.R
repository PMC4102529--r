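make_small_scan <- function() {
  wl <- 500:520
  mk <- function(w, ex) emission_spectrum(w, ex, wl, seq_along(wl) + ex / 100)
  spectra <- c(lapply(c("A1", "A2", "A3"), mk, ex = 470),
               lapply(c("A1", "A2", "A3"), mk, ex = 530))
  layout <- rbind(
    cbind(data.frame(well_id = "A1"), well_role("donor_only", donor_conc_nM = 100)),
    cbind(data.frame(well_id = "A2"), well_role("acceptor_only", acceptor_conc_nM = 200)),
    cbind(data.frame(well_id = "A3"),
          well_role("mixture_inhibitor", donor_conc_nM = 100,
                    acceptor_conc_nM = 100, inhibitor_id = "lova",
                    inhibitor_conc_uM = 2.5)))
  plate_scan(spectra, layout, list(instrument = "synthetic", gain = 100,
                                   ex_bandwidth_nm = 9, em_bandwidth_nm = 20,
                                   integration_time_us = 20))
}

test_that("plate scans preserve counts and round-trip bit-identically", {
  scan <- make_small_scan()
  expect_equal(length(scan$spectra), 6L)  # 3 wells x 2 excitations

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_plate_scan(scan, p1)
  back <- read_plate_scan(p1)
  expect_equal(length(back$spectra), 6L)
  expect_equal(sort(back$layout$well_id), c("A1", "A2", "A3"))
  s <- get_spectrum(back, "A3", 530)
  expect_equal(s$intensities, get_spectrum(scan, "A3", 530)$intensities)
  expect_equal(back$layout$inhibitor_conc_uM[back$layout$well_id == "A3"], 2.5)

  # write -> read -> write reproduces the file byte for byte
  write_plate_scan(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # and reading again is idempotent at the object level
  again <- read_plate_scan(p2)
  expect_equal(again$layout, back$layout)
  expect_equal(get_spectrum(again, "A1", 470)$intensities,
               get_spectrum(back, "A1", 470)$intensities)
})

test_that("malformed plate files are rejected with named causes", {
  scan <- make_small_scan()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_plate_scan(scan, p)
  lines <- readLines(p)

  bad_hdr <- withr::local_tempfile()
  writeLines(c("#gain", lines[-1L][-1L]), bad_hdr)  # header without '='
  expect_error(read_plate_scan(bad_hdr), class = "fq_format_error")

  # duplicate a data row: duplicated (well, excitation, wavelength)
  dup <- withr::local_tempfile()
  writeLines(c(lines, lines[7L]), dup)
  expect_error(read_plate_scan(dup), class = "fretquant_error")

  # break monotonicity by swapping two wavelength rows
  swp <- withr::local_tempfile()
  swapped <- lines
  swapped[c(7L, 8L)] <- swapped[c(8L, 7L)]
  writeLines(swapped, swp)
  expect_error(read_plate_scan(swp), class = "fq_validation_error")

  # inconsistent role annotation for one well
  inc <- withr::local_tempfile()
  bad <- sub("\tdonor_only\t", "\tmixture\t", lines[7L])
  writeLines(c(lines, sub("^A1\t", "A1\t", bad)), inc)
  expect_error(read_plate_scan(inc), class = "fretquant_error")

  expect_error(read_plate_scan(withr::local_tempfile(), dialect = "tecan"),
               class = "fq_format_error")
  expect_error(read_plate_scan("/nonexistent/plate.tsv"),
               class = "fq_format_error")
})

test_that("layout/spectra consistency is enforced at construction", {
  wl <- 500:520
  s1 <- emission_spectrum("A1", 470, wl, seq_along(wl))
  lay2 <- rbind(cbind(data.frame(well_id = "A1"), well_role("blank")),
                cbind(data.frame(well_id = "B9"), well_role("blank")))
  expect_error(plate_scan(list(s1), lay2), class = "fq_consistency_error")
  lay1 <- cbind(data.frame(well_id = "A1"), well_role("blank"))
  s_dup <- emission_spectrum("A1", 470, wl, seq_along(wl) * 2)
  expect_error(plate_scan(list(s1, s_dup), lay1), class = "fq_consistency_error")
  s_orphan <- emission_spectrum("C3", 470, wl, seq_along(wl))
  expect_error(plate_scan(list(s1, s_orphan), lay1),
               class = "fq_consistency_error")
})

test_that("empty plates and absorbance files survive the round trip", {
  empty <- plate_scan(list(),
                      data.frame(well_id = character(), role = character(),
                                 donor_conc_nM = numeric(),
                                 acceptor_conc_nM = numeric(),
                                 inhibitor_id = character(),
                                 inhibitor_conc_uM = numeric()),
                      list(instrument = "synthetic"))
  p <- withr::local_tempfile()
  write_plate_scan(empty, p)
  back <- read_plate_scan(p)
  expect_equal(length(back$spectra), 0L)

  ab <- list(don = absorbance_spectrum(240:700, runif(461), 1),
             acc = absorbance_spectrum(240:700, runif(461), 1))
  pa <- withr::local_tempfile()
  write_absorbance(ab, pa)
  back <- read_absorbance(pa)
  expect_equal(names(back), c("acc", "don"))
  expect_equal(back$don$absorbance, ab$don$absorbance, tolerance = 1e-8)
})

test_that("well_role validates inhibitor bookkeeping", {
  expect_error(well_role("mixture_inhibitor", 100, 100),
               class = "fq_validation_error")
  expect_error(well_role("mixture", 100, 100, inhibitor_id = "x",
                         inhibitor_conc_uM = 1),
               class = "fq_validation_error")
  expect_error(well_role("donor_only", donor_conc_nM = -1),
               class = "fq_validation_error")
  expect_error(well_role("unknown_role"), class = "fq_validation_error")
})
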