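# Text readers/writers for the two peak-list formats the pipeline consumes:
# Mascot generic format (MGF) for experimental spectra and NIST-style MSP for
# annotated library spectra. Both are line-oriented text; parsing is strict
# about peak lines (a malformed one names its line number) and lenient about
# unknown headers.

#' Read a Mascot generic format (MGF) file
#'
#' One [spectrum()] per `BEGIN IONS`/`END IONS` block. `PEPMASS`, `CHARGE`
#' and `TITLE` are parsed; a non-standard `FRAGMENTATION=` key (written by
#' [write_mgf()]) sets the mode, otherwise use `mode`.
#'
#' @param path Path to an MGF text file.
#' @param mode Fragmentation mode to assign when the file does not say
#'   (`"hcd"`, `"etd"`, or `NA` to leave unset).
#' @param constants Constants from [mass_constants()].
#' @return A list of `novopair_spectrum` objects (empty, with a warning, if
#'   the file holds no blocks).
#' @export
read_mgf <- function(path, mode = NA_character_,
                     constants = mass_constants()) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- 0L
  title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
  block_mode <- mode
  mz <- numeric(0); int <- numeric(0)

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) abort(sprintf("Line %d: nested BEGIN IONS.", i))
      in_block <- TRUE; block_start <- i
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      block_mode <- mode
      mz <- numeric(0); int <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) abort(sprintf("Line %d: END IONS without BEGIN IONS.", i))
      if (is.na(pepmass) || is.na(charge)) {
        abort(sprintf(
          "Block starting at line %d lacks PEPMASS or CHARGE.", block_start
        ))
      }
      spectra[[length(spectra) + 1L]] <- spectrum(
        tibble(mz = mz, intensity = int),
        precursor_mz = pepmass, charge = charge, mode = block_mode,
        title = title, constants = constants
      )
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") title <- val
      else if (key == "PEPMASS") pepmass <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      else if (key == "CHARGE") {
        charge <- as.integer(sub("^([0-9]+)[+-]?$", "\\1", trimws(val)))
        if (grepl("-$", trimws(val))) charge <- charge  # magnitude only
      } else if (key == "FRAGMENTATION") block_mode <- tolower(val)
      # other headers (RTINSECONDS, SCANS, ...) are ignored
    } else if (in_block) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[1:2]))
      if (length(parts) < 2 || anyNA(vals)) {
        abort(sprintf("Line %d: malformed peak line '%s'.", i, ln),
              class = "novopair_parse_error")
      }
      mz <- c(mz, vals[1]); int <- c(int, vals[2])
    } else {
      abort(sprintf("Line %d: content outside BEGIN IONS block.", i),
            class = "novopair_parse_error")
    }
  }
  if (in_block) {
    abort(sprintf("Unterminated BEGIN IONS block starting at line %d.",
                  block_start),
          class = "novopair_parse_error")
  }
  if (length(spectra) == 0) warn(paste0("No spectra found in ", path))
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of `novopair_spectrum` objects (or a single one).
#' @param path Output path.
#' @param digits Number of decimal places for m/z and intensity.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, digits = 5) {
  if (inherits(spectra, "novopair_spectrum")) spectra <- list(spectra)
  fmt <- paste0("%.", digits, "f")
  out <- unlist(lapply(spectra, function(sp) {
    c(
      "BEGIN IONS",
      if (!is.na(sp$title)) paste0("TITLE=", sp$title),
      paste0("PEPMASS=", sprintf(fmt, sp$precursor_mz)),
      paste0("CHARGE=", sp$charge, "+"),
      if (!is.na(sp$mode)) paste0("FRAGMENTATION=", toupper(sp$mode)),
      sprintf(paste0(fmt, " ", fmt), sp$peaks$mz, sp$peaks$intensity),
      "END IONS",
      ""
    )
  }))
  writeLines(out, path)
  invisible(path)
}

# Parse one "Name:" field. Returns list(peptide, charge, modified) or NULL.
.parse_msp_name <- function(val) {
  val <- trimws(val)
  m <- regmatches(val, regexec("^([A-Za-z]+)/([0-9]+)(.*)$", val))[[1]]
  if (length(m) == 0) return(NULL)
  list(
    peptide = toupper(m[2]),
    charge = as.integer(m[3]),
    modified = nchar(trimws(m[4])) > 0
  )
}

#' Read a NIST-style MSP spectral library
#'
#' Parses `Name:`/`MW:`/`PrecursorMZ:`/`Comment:`/`Num peaks:` records. The
#' peptide and precursor charge come from the `Name: PEPTIDE/charge` field.
#' Records whose name carries modification tokens are skipped by default
#' (training uses unmodified peptides); records with a peak-count mismatch or
#' an annotation/mass inconsistency are skipped with a message.
#'
#' @param path Path to an MSP text file.
#' @param mode Fragmentation mode of the library (`"hcd"` or `"etd"`); a
#'   `Mode=` token inside `Comment:` overrides it.
#' @param include_modified Keep records with modification tokens in the name?
#' @param mass_tol Peptide/precursor consistency tolerance passed to
#'   [library_spectrum()].
#' @param table,constants Residue table and constants for the check.
#' @return A list of `novopair_library_spectrum` objects. The number of
#'   skipped records is attached as attribute `n_skipped`.
#' @export
read_msp <- function(path, mode = NA_character_, include_modified = FALSE,
                     mass_tol = 0.1, table = amino_acid_table(),
                     constants = mass_constants()) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  # split into records at "Name:" lines
  name_at <- grep("^Name:", lines)
  out <- list()
  n_skipped <- 0L
  bounds <- c(name_at, length(lines) + 1L)
  for (r in seq_along(name_at)) {
    rec <- lines[bounds[r]:(bounds[r + 1L] - 1L)]
    nm <- .parse_msp_name(sub("^Name:", "", rec[1]))
    if (is.null(nm) || (nm$modified && !include_modified)) {
      n_skipped <- n_skipped + 1L
      next
    }
    get_field <- function(key) {
      hit <- grep(paste0("^", key, ":"), rec, value = TRUE)
      if (length(hit) == 0) NA_character_ else trimws(sub("^[^:]+:", "", hit[1]))
    }
    mw <- suppressWarnings(as.numeric(get_field("MW")))
    pmz <- suppressWarnings(as.numeric(get_field("PrecursorMZ")))
    comment <- get_field("Comment")
    rec_mode <- mode
    if (!is.na(comment)) {
      mm <- regmatches(comment, regexec("Mode=([A-Za-z]+)", comment))[[1]]
      if (length(mm) == 2) rec_mode <- tolower(mm[2])
    }
    npk_line <- grep("^Num [Pp]eaks:", rec)
    if (length(npk_line) == 0) { n_skipped <- n_skipped + 1L; next }
    npk <- as.integer(trimws(sub("^[^:]+:", "", rec[npk_line[1]])))
    peak_lines <- rec[-seq_len(npk_line[1])]
    peak_lines <- peak_lines[trimws(peak_lines) != ""]
    if (length(peak_lines) != npk) {
      inform(sprintf(
        "MSP record '%s': Num peaks = %d but %d peak lines; skipped.",
        nm$peptide, npk, length(peak_lines)
      ))
      n_skipped <- n_skipped + 1L
      next
    }
    parts <- strsplit(trimws(peak_lines), "[ \t]+")
    mz <- as.numeric(vapply(parts, `[`, "", 1))
    int <- as.numeric(vapply(parts, `[`, "", 2))
    if (anyNA(mz) || anyNA(int)) { n_skipped <- n_skipped + 1L; next }
    parent <- if (!is.na(mw)) mw else nm$charge * (pmz - constants$m_H)
    sp <- tryCatch(
      library_spectrum(
        tibble(mz = mz, intensity = int),
        peptide = nm$peptide, precursor_mz = pmz %||% NA_real_,
        charge = nm$charge, mode = rec_mode, title = nm$peptide,
        parent_mass = parent, mass_tol = mass_tol,
        table = table, constants = constants
      ),
      error = function(e) NULL
    )
    if (is.null(sp)) { n_skipped <- n_skipped + 1L; next }
    out[[length(out) + 1L]] <- sp
  }
  if (n_skipped > 0) {
    inform(sprintf("read_msp: %d record(s) skipped.", n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write library spectra to an MSP file
#'
#' @param library A list of `novopair_library_spectrum` objects.
#' @param path Output path.
#' @param digits Decimal places for masses and intensities.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library, path, digits = 5) {
  if (inherits(library, "novopair_library_spectrum")) library <- list(library)
  fmt <- paste0("%.", digits, "f")
  out <- unlist(lapply(library, function(sp) {
    c(
      paste0("Name: ", sp$peptide, "/", sp$charge),
      paste0("MW: ", sprintf(fmt, sp$parent_mass)),
      paste0("PrecursorMZ: ", sprintf(fmt, sp$precursor_mz)),
      paste0("Comment: Mode=", toupper(sp$mode %||% "NA")),
      paste0("Num peaks: ", nrow(sp$peaks)),
      sprintf(paste0(fmt, " ", fmt), sp$peaks$mz, sp$peaks$intensity),
      ""
    )
  }))
  writeLines(out, path)
  invisible(path)
}

#' Pair HCD and ETD spectra of the same peptide
#'
#' Pairs by identical title when both sides have titles (annotated data),
#' then greedily by closest parent mass within `tolerance`, one-to-one.
#'
#' @param hcd,etd Lists of `novopair_spectrum` objects.
#' @param tolerance Parent-mass tolerance in Da.
#' @return A list of `novopair_pair` objects; unpaired counts are attached as
#'   attributes `n_unpaired_hcd` / `n_unpaired_etd`.
#' @export
pair_spectra <- function(hcd, etd, tolerance = 0.02) {
  if (length(hcd) == 0 || length(etd) == 0) {
    abort("Both spectrum lists must be non-empty.")
  }
  pairs <- list()
  used_h <- rep(FALSE, length(hcd))
  used_e <- rep(FALSE, length(etd))

  get_title <- function(s) {
    t <- s$title
    if (is.null(t) || is.na(t)) NA_character_ else as.character(t)
  }
  titles_h <- vapply(hcd, get_title, "")
  titles_e <- vapply(etd, get_title, "")
  for (j in seq_along(etd)) {
    if (is.na(titles_e[j])) next
    i <- which(!used_h & !is.na(titles_h) & titles_h == titles_e[j])
    if (length(i) >= 1) {
      i <- i[1]
      if (abs(hcd[[i]]$parent_mass - etd[[j]]$parent_mass) <= tolerance) {
        pairs[[length(pairs) + 1L]] <- spectrum_pair(hcd[[i]], etd[[j]], tolerance)
        used_h[i] <- TRUE; used_e[j] <- TRUE
      }
    }
  }

  # greedy closest-mass matching among the rest
  mh <- vapply(hcd, `[[`, 0, "parent_mass")
  me <- vapply(etd, `[[`, 0, "parent_mass")
  cand <- expand.grid(i = seq_along(hcd), j = seq_along(etd))
  cand$d <- abs(mh[cand$i] - me[cand$j])
  cand <- cand[cand$d <= tolerance, , drop = FALSE]
  cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_h[i] || used_e[j]) next
    pairs[[length(pairs) + 1L]] <- spectrum_pair(hcd[[i]], etd[[j]], tolerance)
    used_h[i] <- TRUE; used_e[j] <- TRUE
  }
  attr(pairs, "n_unpaired_hcd") <- sum(!used_h)
  attr(pairs, "n_unpaired_etd") <- sum(!used_e)
  pairs
}
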