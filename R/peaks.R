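#' Construct a peak table
#'
#' A peak table holds per-probe NMR observables for one state of one protein:
#' chemical shifts of the proton and its attached heteronucleus, peak
#' intensity, signal-to-noise, and (optionally) the proton linewidth. Probes
#' are methyl or amide groups identified by residue number, residue name and
#' an atom-group label (e.g. `"CD1"` for an Ile delta-1 methyl, `"N"` for an
#' amide).
#'
#' @param x A data frame with columns `residue` (integer), `resname`
#'   (3-letter code), `atom_group` (character), `nucleus` (`"N15"` or
#'   `"C13"`), `shift_h` and `shift_x` (ppm), `intensity` (arbitrary units),
#'   `snr` (dimensionless) and optionally `linewidth_h` (Hz). Vanished peaks
#'   may carry `NA` intensity/snr.
#' @param protein_id,state_id Identifiers recorded as attributes.
#' @return A tibble of class `peak_table` with a `probe` id column.
#' @export
peak_table <- function(x, protein_id = "protein", state_id = "state") {
  x <- as_tibble(x)
  required <- c("residue", "resname", "atom_group", "nucleus",
                "shift_h", "shift_x", "intensity", "snr")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("peak table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"linewidth_h" %in% names(x)) x$linewidth_h <- NA_real_
  x$linewidth_h <- as.numeric(x$linewidth_h)
  if (!all(x$nucleus %in% c("N15", "C13"))) {
    abort("nucleus must be 'N15' or 'C13'")
  }
  x$probe <- probe_id(x$residue, x$resname, x$atom_group)
  if (anyDuplicated(x$probe)) {
    abort(paste0("duplicate probe identifiers: ",
                 paste(unique(x$probe[duplicated(x$probe)]), collapse = ", ")))
  }
  present <- !is.na(x$intensity)
  stopifnot_named(
    "shifts must be finite" = is.finite(x$shift_h) & is.finite(x$shift_x),
    "S/N must be > 0 where present" = is.na(x$snr) | x$snr > 0,
    "linewidth must be > 0 where present" = is.na(x$linewidth_h) | x$linewidth_h > 0
  )
  x <- x[c("probe", required, "linewidth_h")]
  structure(x, class = c("peak_table", class(x)),
            protein_id = protein_id, state_id = state_id)
}

#' Read / write peak tables as delimited text
#'
#' The on-disk format is a headered CSV or TSV with the columns documented in
#' [peak_table()]; the delimiter is auto-detected from the header line.
#'
#' @param path File path.
#' @param protein_id,state_id Passed to [peak_table()].
#' @return [read_peak_table()] returns a `peak_table`;
#'   [write_peak_table()] returns `path` invisibly.
#' @export
read_peak_table <- function(path, protein_id = "protein", state_id = "state") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$probe <- NULL
  peak_table(df, protein_id = protein_id, state_id = state_id)
}

#' @param x A `peak_table`.
#' @rdname read_peak_table
#' @export
write_peak_table <- function(x, path) {
  df <- as.data.frame(x)[, c("residue", "resname", "atom_group", "nucleus",
                             "shift_h", "shift_x", "intensity", "snr",
                             "linewidth_h")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
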