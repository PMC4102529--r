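WELL_ROLES <- c("blank", "donor_only", "acceptor_only", "mixture",
                "mixture_inhibitor")

#' Describe the role of a plate well
#'
#' @param role one of `"blank"`, `"donor_only"`, `"acceptor_only"`,
#'   `"mixture"`, `"mixture_inhibitor"`.
#' @param donor_conc_nM,acceptor_conc_nM protein concentrations in nM
#'   (concentration of the protein in the fluorophore-protein conjugate
#'   solution, not of the dye).
#' @param inhibitor_id,inhibitor_conc_uM inhibitor identity and dose in
#'   µM; required for (and only allowed with) role `"mixture_inhibitor"`.
#' @return a one-row `data.frame` describing the well.
#' @export
well_role <- function(role, donor_conc_nM = 0, acceptor_conc_nM = 0,
                      inhibitor_id = NA_character_,
                      inhibitor_conc_uM = NA_real_) {
  if (!role %in% WELL_ROLES)
    fq_validation_error(sprintf("unknown well role '%s'", role))
  if (donor_conc_nM < 0 || acceptor_conc_nM < 0)
    fq_validation_error("concentrations must be >= 0")
  has_inh <- !is.na(inhibitor_id) || !is.na(inhibitor_conc_uM)
  if (role == "mixture_inhibitor" &&
      (is.na(inhibitor_id) || is.na(inhibitor_conc_uM)))
    fq_validation_error("mixture_inhibitor wells need inhibitor_id and inhibitor_conc_uM")
  if (role != "mixture_inhibitor" && has_inh)
    fq_validation_error("inhibitor fields are only allowed for mixture_inhibitor wells")
  data.frame(role = role, donor_conc_nM = donor_conc_nM,
             acceptor_conc_nM = acceptor_conc_nM,
             inhibitor_id = as.character(inhibitor_id),
             inhibitor_conc_uM = inhibitor_conc_uM,
             stringsAsFactors = FALSE)
}

spec_key <- function(well_id, excitation_nm) {
  sprintf("%s@%s", well_id, format(excitation_nm))
}

#' Assemble a plate scan from spectra and a layout
#'
#' A `plate_scan` holds every emission spectrum of one plate (keyed by well
#' and excitation wavelength), the plate layout (one row per well with its
#' role and concentrations), and the instrument metadata.
#'
#' @param spectra list of [emission_spectrum()] objects.
#' @param layout `data.frame` with columns `well_id`, `role`,
#'   `donor_conc_nM`, `acceptor_conc_nM`, `inhibitor_id`,
#'   `inhibitor_conc_uM`.
#' @param metadata named list of instrument settings.
#' @return an object of class `plate_scan`.
#' @export
plate_scan <- function(spectra, layout, metadata = list()) {
  if (anyDuplicated(layout$well_id))
    fq_consistency_error("duplicated well_id in layout")
  keys <- vapply(spectra, function(s) spec_key(s$well_id, s$excitation_nm), "")
  if (anyDuplicated(keys))
    fq_consistency_error(sprintf(
      "duplicated spectrum for %s", keys[duplicated(keys)][1L]))
  names(spectra) <- keys
  wells_with_spectra <- unique(vapply(spectra, function(s) s$well_id, ""))
  missing <- setdiff(layout$well_id, wells_with_spectra)
  if (length(missing) > 0L)
    fq_consistency_error(sprintf(
      "layout declares wells with no spectra: %s",
      paste(utils::head(missing, 5L), collapse = ", ")))
  orphan <- setdiff(wells_with_spectra, layout$well_id)
  if (length(orphan) > 0L)
    fq_consistency_error(sprintf(
      "spectra present for wells absent from layout: %s",
      paste(utils::head(orphan, 5L), collapse = ", ")))
  structure(list(spectra = spectra, layout = layout, metadata = metadata),
            class = "plate_scan")
}

#' @export
print.plate_scan <- function(x, ...) {
  cat(sprintf("<plate_scan> %d wells, %d spectra\n",
              nrow(x$layout), length(x$spectra)))
  print(table(x$layout$role))
  invisible(x)
}

#' Fetch one spectrum from a plate scan
#'
#' @param scan a [plate_scan()].
#' @param well_id well coordinate.
#' @param excitation_nm excitation wavelength in nm.
#' @return an [emission_spectrum()].
#' @export
get_spectrum <- function(scan, well_id, excitation_nm) {
  s <- scan$spectra[[spec_key(well_id, excitation_nm)]]
  if (is.null(s))
    fq_consistency_error(sprintf("no spectrum for well %s at ex %g nm",
                                 well_id, excitation_nm))
  s
}

PLATE_HEADER_KEYS <- c("instrument", "gain", "ex_bandwidth_nm",
                       "em_bandwidth_nm", "integration_time_us")
PLATE_COLUMNS <- c("well_id", "role", "donor_conc_nM", "acceptor_conc_nM",
                   "inhibitor_id", "inhibitor_conc_uM", "excitation_nm",
                   "wavelength_nm", "intensity")

read_header_block <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  meta <- list(); n <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (!startsWith(line, "#")) break
    n <- n + 1L
    m <- regmatches(line, regexec("^#([A-Za-z0-9_]+)=(.*)$", line))[[1L]]
    if (length(m) != 3L)
      fq_format_error(sprintf("malformed header line %d: '%s'", n, line))
    val <- m[3L]
    meta[[m[2L]]] <- if (grepl("^-?[0-9.eE+]+$", val)) as.numeric(val) else val
    if (n > 100L) fq_format_error("header block exceeds 100 lines")
  }
  list(meta = meta, n = n)
}

#' Read a plate scan file
#'
#' Parses the package's delimited plate-scan format: `#key=value` header
#' lines carrying instrument settings, then a tab-separated table with one
#' row per (well, excitation, wavelength). See the package vignette for
#' the full format definition.
#'
#' @param path file path.
#' @param dialect format name; only `"fretquant"` is currently defined.
#' @return a [plate_scan()].
#' @export
read_plate_scan <- function(path, dialect = "fretquant") {
  if (dialect != "fretquant")
    fq_format_error(sprintf("unknown plate-scan dialect '%s'", dialect))
  if (!file.exists(path)) fq_format_error(sprintf("file not found: %s", path))
  hdr <- read_header_block(path)
  tab <- data.table::fread(path, skip = hdr$n, sep = "\t", header = TRUE,
                           na.strings = "", colClasses = list(
                             character = c("well_id", "role", "inhibitor_id")))
  if (!identical(names(tab), PLATE_COLUMNS))
    fq_format_error(sprintf(
      "unexpected columns: got [%s], expected [%s]",
      paste(names(tab), collapse = ", "),
      paste(PLATE_COLUMNS, collapse = ", ")))
  if (nrow(tab) == 0L)
    return(plate_scan(list(), empty_layout(), hdr$meta))

  # layout: one consistent row per well
  lay <- unique(tab[, c("well_id", "role", "donor_conc_nM", "acceptor_conc_nM",
                        "inhibitor_id", "inhibitor_conc_uM")])
  if (anyDuplicated(lay$well_id))
    fq_consistency_error(sprintf(
      "well %s has inconsistent role/concentration annotations",
      lay$well_id[duplicated(lay$well_id)][1L]))
  bad_role <- setdiff(unique(lay$role), WELL_ROLES)
  if (length(bad_role) > 0L)
    fq_format_error(sprintf("unknown well role '%s'", bad_role[1L]))

  well_id <- excitation_nm <- NULL  # appease R CMD check
  groups <- split(tab, list(tab$well_id, tab$excitation_nm), drop = TRUE)
  spectra <- lapply(groups, function(g) {
    if (anyDuplicated(g$wavelength_nm))
      fq_consistency_error(sprintf(
        "well %s at ex %g nm has duplicated wavelength rows",
        g$well_id[1L], g$excitation_nm[1L]))
    if (any(diff(g$wavelength_nm) <= 0))
      fq_validation_error(sprintf(
        "well %s at ex %g nm: wavelength grid not strictly increasing",
        g$well_id[1L], g$excitation_nm[1L]))
    emission_spectrum(
      well_id = g$well_id[1L], excitation_nm = g$excitation_nm[1L],
      wavelengths = g$wavelength_nm, intensities = g$intensity,
      gain = hdr$meta$gain %||% NA_real_,
      ex_bandwidth_nm = hdr$meta$ex_bandwidth_nm %||% NA_real_,
      em_bandwidth_nm = hdr$meta$em_bandwidth_nm %||% NA_real_,
      integration_time_us = hdr$meta$integration_time_us %||% NA_real_)
  })
  plate_scan(unname(spectra), as.data.frame(lay), hdr$meta)
}

empty_layout <- function() {
  data.frame(well_id = character(), role = character(),
             donor_conc_nM = numeric(), acceptor_conc_nM = numeric(),
             inhibitor_id = character(), inhibitor_conc_uM = numeric(),
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) {
  vapply(x, function(v) if (is.na(v)) "" else sprintf("%.9g", v), "")
}

#' Write a plate scan to the documented delimited format
#'
#' Emits a canonical file: header lines, then rows ordered by well, then
#' excitation, then wavelength, with numbers formatted to 9 significant
#' digits. Reading a written file and writing it again reproduces the file
#' byte for byte.
#'
#' @param scan a [plate_scan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_scan <- function(scan, path) {
  meta <- scan$metadata
  hdr <- vapply(PLATE_HEADER_KEYS, function(k) {
    v <- meta[[k]]
    sprintf("#%s=%s", k, if (is.null(v) || (is.numeric(v) && is.na(v))) ""
            else if (is.numeric(v)) sprintf("%.9g", v)
            else as.character(v))
  }, "")
  lines <- c(hdr, paste(PLATE_COLUMNS, collapse = "\t"))
  if (length(scan$spectra) > 0L) {
    lay <- scan$layout
    rows <- lapply(scan$spectra, function(s) {
      lr <- lay[lay$well_id == s$well_id, , drop = FALSE]
      data.table::data.table(
        well_id = s$well_id, role = lr$role,
        donor_conc_nM = lr$donor_conc_nM,
        acceptor_conc_nM = lr$acceptor_conc_nM,
        inhibitor_id = lr$inhibitor_id,
        inhibitor_conc_uM = lr$inhibitor_conc_uM,
        excitation_nm = s$excitation_nm,
        wavelength_nm = s$wavelengths, intensity = s$intensities)
    })
    tab <- data.table::rbindlist(rows)
    data.table::setorder(tab, well_id, excitation_nm, wavelength_nm)
    body <- do.call(paste, c(list(
      tab$well_id, tab$role, fmt_num(tab$donor_conc_nM),
      fmt_num(tab$acceptor_conc_nM),
      ifelse(is.na(tab$inhibitor_id), "", tab$inhibitor_id),
      fmt_num(tab$inhibitor_conc_uM), fmt_num(tab$excitation_nm),
      fmt_num(tab$wavelength_nm), fmt_num(tab$intensity)), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read absorbance spectra from a delimited file
#'
#' Format: a `#pathlength_cm=` header line, then a tab-separated table
#' with columns `sample_id`, `wavelength_nm`, `absorbance`.
#'
#' @param path file path.
#' @return named list of [absorbance_spectrum()], one per `sample_id`.
#' @export
read_absorbance <- function(path) {
  if (!file.exists(path)) fq_format_error(sprintf("file not found: %s", path))
  hdr <- read_header_block(path)
  pl <- hdr$meta$pathlength_cm %||% 1
  tab <- data.table::fread(path, skip = hdr$n, sep = "\t", header = TRUE,
                           colClasses = list(character = "sample_id"))
  need <- c("sample_id", "wavelength_nm", "absorbance")
  if (!identical(names(tab), need))
    fq_format_error(sprintf("expected columns [%s]",
                            paste(need, collapse = ", ")))
  groups <- split(tab, tab$sample_id)
  lapply(groups, function(g)
    absorbance_spectrum(g$wavelength_nm, g$absorbance, pathlength_cm = pl))
}

#' Write absorbance spectra to the delimited format
#'
#' @param spectra named list of [absorbance_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_absorbance <- function(spectra, path) {
  pl <- spectra[[1L]]$pathlength_cm
  lines <- c(sprintf("#pathlength_cm=%.9g", pl),
             "sample_id\twavelength_nm\tabsorbance")
  for (id in names(spectra)) {
    s <- spectra[[id]]
    lines <- c(lines, paste(id, fmt_num(s$wavelengths), fmt_num(s$absorbance),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
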