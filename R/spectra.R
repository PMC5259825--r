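#' Construct an MS/MS spectrum
#'
#' A light container for one scan: a peak table plus precursor metadata.
#' Peaks are stored as a tibble sorted by m/z; intensities are carried along
#' for provenance but are not used by the selection criteria, which operate
#' on m/z only.
#'
#' @param peaks A data frame with columns `mz` and `intensity` (extra columns
#'   such as ground-truth labels are preserved).
#' @param precursor_mz Precursor m/z as recorded by the instrument.
#' @param charge Precursor charge `n >= 1`.
#' @param mode Fragmentation mode, `"hcd"` or `"etd"` (may be `NA` when the
#'   source file does not say; assign it before merging).
#' @param title Scan title / identifier.
#' @param parent_mass Neutral peptide mass `m_p`; computed from
#'   `precursor_mz` and `charge` when missing.
#' @param constants Constants from [mass_constants()] (for the proton mass).
#' @return An object of class `novopair_spectrum`.
#' @export
spectrum <- function(peaks, precursor_mz, charge, mode = NA_character_,
                     title = NA_character_, parent_mass = NULL,
                     constants = mass_constants()) {
  peaks <- as_tibble(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    abort("peaks must have columns mz and intensity")
  }
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
      abort("All peak m/z values must be positive and finite.")
    }
    if (any(peaks$intensity < 0)) abort("Peak intensities must be >= 0.")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) abort("Precursor charge must be >= 1.")
  if (!is.na(mode)) {
    mode <- tolower(mode)
    if (!mode %in% c("hcd", "etd")) abort("mode must be 'hcd' or 'etd'")
  }
  if (is.null(parent_mass)) {
    parent_mass <- charge * (precursor_mz - constants$m_H)
  }
  structure(
    list(
      title = title, precursor_mz = precursor_mz, charge = charge,
      parent_mass = parent_mass, mode = mode, peaks = peaks
    ),
    class = "novopair_spectrum"
  )
}

#' @export
print.novopair_spectrum <- function(x, ...) {
  cat(sprintf(
    "<novopair_spectrum> %s | mode=%s charge=%d m_p=%.4f | %d peaks\n",
    x$title %||% "", x$mode %||% "?", x$charge, x$parent_mass, nrow(x$peaks)
  ))
  invisible(x)
}

#' Construct an annotated library spectrum
#'
#' A [spectrum()] carrying the peptide annotation used as ground truth during
#' training. The annotated peptide mass must agree with the recorded parent
#' mass within `mass_tol`.
#'
#' @inheritParams spectrum
#' @param peptide Annotated peptide sequence (one-letter code, non-empty).
#' @param mass_tol Maximum allowed |peptide mass - parent mass| (Da).
#' @param table Residue table used for the consistency check.
#' @return An object of class `c("novopair_library_spectrum",
#'   "novopair_spectrum")`.
#' @export
library_spectrum <- function(peaks, peptide, precursor_mz, charge,
                             mode = NA_character_, title = NA_character_,
                             parent_mass = NULL, mass_tol = 0.1,
                             table = amino_acid_table(),
                             constants = mass_constants()) {
  if (is.na(peptide) || nchar(peptide) == 0) {
    abort("Library spectrum requires a non-empty peptide annotation.")
  }
  sp <- spectrum(peaks, precursor_mz, charge, mode, title, parent_mass,
                 constants)
  pm <- peptide_mass(peptide, table, constants)
  if (abs(pm - sp$parent_mass) > mass_tol) {
    abort(
      sprintf(
        "Annotated peptide mass %.4f inconsistent with parent mass %.4f (> %g Da).",
        pm, sp$parent_mass, mass_tol
      ),
      class = "novopair_mass_inconsistent"
    )
  }
  sp$peptide <- peptide
  class(sp) <- c("novopair_library_spectrum", class(sp))
  sp
}

#' @export
print.novopair_library_spectrum <- function(x, ...) {
  cat(sprintf(
    "<novopair_library_spectrum> %s/%d | mode=%s | %d peaks\n",
    x$peptide, x$charge, x$mode %||% "?", nrow(x$peaks)
  ))
  invisible(x)
}

#' Pair one HCD and one ETD spectrum of the same peptide
#'
#' @param hcd,etd [spectrum()] objects; modes are checked/assigned.
#' @param tolerance Maximum allowed difference in parent mass (Da).
#' @return An object of class `novopair_pair`.
#' @export
spectrum_pair <- function(hcd, etd, tolerance = 0.02) {
  stopifnot(inherits(hcd, "novopair_spectrum"), inherits(etd, "novopair_spectrum"))
  if (!is.na(hcd$mode) && hcd$mode != "hcd") abort("First spectrum must be HCD.")
  if (!is.na(etd$mode) && etd$mode != "etd") abort("Second spectrum must be ETD.")
  hcd$mode <- "hcd"
  etd$mode <- "etd"
  if (abs(hcd$parent_mass - etd$parent_mass) > tolerance) {
    abort(
      sprintf(
        "Parent masses differ by %.4f Da (> %g): not the same peptide.",
        abs(hcd$parent_mass - etd$parent_mass), tolerance
      ),
      class = "novopair_pair_mass_mismatch"
    )
  }
  structure(
    list(hcd = hcd, etd = etd,
         parent_mass = (hcd$parent_mass + etd$parent_mass) / 2),
    class = "novopair_pair"
  )
}

#' @export
print.novopair_pair <- function(x, ...) {
  cat(sprintf(
    "<novopair_pair> m_p=%.4f | HCD %d peaks (z=%d), ETD %d peaks (z=%d)\n",
    x$parent_mass, nrow(x$hcd$peaks), x$hcd$charge,
    nrow(x$etd$peaks), x$etd$charge
  ))
  invisible(x)
}
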