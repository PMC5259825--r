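#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic residue masses of the 20 standard amino acids (Da).
.residue_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Nominal (integer) residue masses: the didactic "toy" scale where S = 87,
# E = 129, water = 18 and the proton is 1, so every mass identity can be
# checked by mental arithmetic.
.residue_int <- c(
  G = 57, A = 71, S = 87, P = 97, V = 99,
  T = 101, C = 103, L = 113, I = 113, N = 114,
  D = 115, Q = 128, K = 128, E = 129, M = 131,
  H = 137, F = 147, R = 156, Y = 163, W = 186
)

#' Amino-acid residue-mass table
#'
#' Returns the residue masses of the 20 standard amino acids, either on the
#' monoisotopic scale (default) or on a nominal integer scale. The integer
#' scale exists to make worked examples exactly checkable by hand; it is not
#' meant for real data.
#'
#' @param mode `"monoisotopic"` or `"integer"`.
#' @return A tibble with columns `residue` and `mass`, of class
#'   `novopair_aa_table`, carrying the mode as an attribute.
#' @examples
#' amino_acid_table()
#' amino_acid_table("integer")
#' @export
amino_acid_table <- function(mode = c("monoisotopic", "integer")) {
  mode <- match.arg(mode)
  masses <- if (mode == "integer") .residue_int else .residue_mono
  out <- tibble(residue = names(masses), mass = unname(masses))
  attr(out, "mode") <- mode
  class(out) <- c("novopair_aa_table", class(out))
  out
}

#' Mass constants used in fragment arithmetic
#'
#' Bundles the proton mass used in charge conversion and complementarity
#' relations, the water mass, and the neutral-loss masses considered during
#' peak selection (H2O and NH3).
#'
#' @inheritParams amino_acid_table
#' @return A list with elements `mode`, `m_H` (proton), `water`, `nh3`, `co`,
#'   and `losses` (named numeric vector of loss masses).
#' @export
mass_constants <- function(mode = c("monoisotopic", "integer")) {
  mode <- match.arg(mode)
  if (mode == "integer") {
    list(
      mode = mode, m_H = 1, water = 18, nh3 = 17, co = 28,
      losses = c(H2O = 18, NH3 = 17)
    )
  } else {
    list(
      mode = mode, m_H = 1.007276, water = 18.010565, nh3 = 17.026549,
      co = 27.994915,
      losses = c(H2O = 18.010565, NH3 = 17.026549)
    )
  }
}

#' Look up residue masses
#'
#' @param symbol Character vector of single-letter residue codes.
#' @param table A residue table from [amino_acid_table()] (or loaded with
#'   [read_residue_table()]).
#' @return Numeric vector of residue masses (Da).
#' @export
residue_mass <- function(symbol, table = amino_acid_table()) {
  idx <- match(symbol, table$residue)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    abort(
      paste0("Unknown amino-acid residue(s): ", paste(bad, collapse = ", ")),
      class = "novopair_invalid_residue"
    )
  }
  table$mass[idx]
}

.split_residues <- function(sequence) {
  if (is.na(sequence)) abort("Peptide sequence is NA.")
  if (nchar(sequence) == 0) return(character(0))
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water. The empty peptide is a single water
#' molecule.
#'
#' @param sequence Peptide string in one-letter code.
#' @inheritParams residue_mass
#' @param constants Constants from [mass_constants()]; its mode should match
#'   the residue table's.
#' @return Neutral (uncharged) peptide mass in Da.
#' @examples
#' peptide_mass("SE", amino_acid_table("integer"), mass_constants("integer")) # 234
#' @export
peptide_mass <- function(sequence, table = amino_acid_table(),
                         constants = mass_constants()) {
  res <- .split_residues(sequence)
  sum(residue_mass(res, table)) + constants$water
}

# Neutral mass of one fragment given the prefix/suffix residue sums.
# Series conventions (all expressed so that the in-spectrum complementarity
# relations hold exactly with the single constant m_H):
#   b = prefix;            y = suffix + water          => b+ + y+ = m_p + 2 m_H
#   c = b + NH3;           z = y + m_H - NH3 (z-dot)   => c+ + z+ = m_p + 3 m_H
#   a = b - CO;            x = y + CO + 2 m_H - ... (rarely used; see below)
.fragment_neutral <- function(series, prefix, suffix, constants) {
  switch(series,
    b = prefix,
    y = suffix + constants$water,
    c = prefix + constants$nh3,
    z = suffix + constants$water + constants$m_H - constants$nh3,
    a = prefix - constants$co,
    x = suffix + constants$water + constants$co - 2 * constants$m_H,
    abort(paste0("Unknown ion series: ", series))
  )
}

#' Theoretical fragment-ion ladder
#'
#' Enumerates fragment ions of the requested series, charges and neutral
#' losses for a peptide. N-terminal series (a, b, c) are indexed by prefix
#' length, C-terminal series (x, y, z) by suffix length. The z series is the
#' z-dot radical ion (`y + m_H - NH3`), the common ETD convention, so that
#' singly charged c/z partners sum to `m_p + 3 m_H` exactly.
#'
#' @param sequence Peptide string (length >= 2).
#' @param series Character vector from `c("a","b","c","x","y","z")`.
#' @param max_charge Fragments are generated at charges `1:max_charge`.
#' @param losses Character vector of neutral-loss names to add on top of the
#'   loss-free ladder; must be names of `constants$losses` (e.g. `"H2O"`).
#' @inheritParams peptide_mass
#' @return A tibble with columns `series`, `pos`, `charge`, `loss`
#'   (`"none"` for the plain ion), `neutral` and `mz`.
#' @export
theoretical_fragments <- function(sequence, series = c("b", "y"),
                                  max_charge = 1, losses = character(0),
                                  table = amino_acid_table(),
                                  constants = mass_constants()) {
  if (length(series) == 0) abort("At least one ion series is required.")
  series <- match.arg(series, c("a", "b", "c", "x", "y", "z"),
                      several.ok = TRUE)
  res <- .split_residues(sequence)
  n <- length(res)
  if (n < 2) abort("Peptide must contain at least 2 residues.")
  if (length(losses) > 0 && !all(losses %in% names(constants$losses))) {
    abort("losses must be a subset of names(constants$losses)")
  }
  masses <- residue_mass(res, table)
  prefix <- cumsum(masses)[-n]       # prefix of length p, positions 1..n-1
  suffix <- cumsum(rev(masses))[-n]  # suffix of length p (last p residues)

  loss_tags <- c("none", losses)
  loss_mass <- c(none = 0, constants$losses[losses])

  grid <- expand.grid(
    pos = seq_len(n - 1), series = series, charge = seq_len(max_charge),
    loss = loss_tags, stringsAsFactors = FALSE
  )
  neutral <- mapply(function(s, p, l) {
    .fragment_neutral(s, prefix[p], suffix[p], constants) - loss_mass[[l]]
  }, grid$series, grid$pos, grid$loss)
  mz <- (neutral + grid$charge * constants$m_H) / grid$charge
  out <- tibble(
    series = grid$series, pos = grid$pos, charge = grid$charge,
    loss = grid$loss, neutral = unname(neutral), mz = unname(mz)
  )
  dplyr::arrange(out, .data$series, .data$charge, .data$loss, .data$pos)
}

#' Convert an observed m/z to its charge-1 equivalent
#'
#' Under the assumption that a peak carries charge `i`, its singly charged
#' m/z is `i * mz - (i - 1) * m_H`.
#'
#' @param mz Observed m/z values.
#' @param charge Assumed charge `i >= 1`.
#' @param constants Constants from [mass_constants()].
#' @export
to_charge1 <- function(mz, charge, constants = mass_constants()) {
  charge * mz - (charge - 1) * constants$m_H
}

#' Load a residue-mass table from YAML or JSON
#'
#' Supports overriding individual residue masses (e.g. a fixed modification)
#' while keeping the other defaults. The file must contain a mapping from
#' one-letter residue codes to masses, optionally nested under a `residues`
#' key, with an optional top-level `mode`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `novopair_aa_table` tibble.
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mode <- raw$mode %||% "monoisotopic"
  res <- raw$residues %||% raw[setdiff(names(raw), "mode")]
  base <- amino_acid_table(mode)
  for (nm in names(res)) {
    m <- as.numeric(res[[nm]])
    if (!is.finite(m) || m <= 0) abort(paste0("Invalid mass for residue ", nm))
    if (nm %in% base$residue) {
      base$mass[base$residue == nm] <- m
    } else {
      base <- dplyr::bind_rows(base, tibble(residue = nm, mass = m))
    }
  }
  attr(base, "mode") <- mode
  class(base) <- unique(c("novopair_aa_table", class(base)))
  base
}

# Nearest-match test: is x within tol of any value in sorted vector `ref`?
# Returns logical the length of x. Used everywhere a mass difference is
# compared against the residue table or a theoretical ladder.
.near_any <- function(x, ref, tol) {
  if (length(ref) == 0) return(rep(FALSE, length(x)))
  ref <- sort(ref)
  i <- findInterval(x, ref)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(ref))
  d <- pmin(abs(x - ref[lo]), abs(x - ref[hi]))
  d <= tol
}

# Closest value in `ref` to x (scalar); NA if nothing within tol.
.closest_match <- function(x, ref, tol) {
  d <- abs(ref - x)
  j <- which.min(d)
  if (length(j) == 0 || d[j] > tol) return(NA_integer_)
  j
}
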