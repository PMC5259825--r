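# Synthetic spectra with known ground truth. The generator emulates the
# statistical structure the algorithm assumes — complete b/y (HCD) and c/z
# (ETD) fragment ladders at charges 1..n-1, optional neutral-loss satellite
# peaks, peak dropout, small m/z jitter, and uniform noise peaks kept well
# away from every theoretical fragment so per-peak truth labels are
# unambiguous. It does not model fragment intensities, isotope envelopes or
# correlated noise.

#' Simulation configuration
#'
#' Defaults describe a moderately clean, tryptic-like dataset: peptides of
#' 7-12 residues ending in K/R, precursors at charge 2-3, a 20% chance of a
#' water/ammonia satellite per fragment, 10% fragment dropout, 30% noise
#' peaks and 3 mDa mass jitter. Set `noise_fraction`, `dropout`, `jitter_sd`
#' and `loss_prob` to 0 for noise-free ladders.
#'
#' @param length_range Integer range of peptide lengths.
#' @param charge_range Integer range of precursor charges.
#' @param loss_prob Probability that a fragment also shows one neutral-loss
#'   satellite peak (H2O or NH3, equally likely).
#' @param dropout Probability that a theoretical fragment peak is absent.
#' @param noise_fraction Fraction of the final peak list that is noise
#'   (`n_noise = round(f/(1-f) * n_real)`).
#' @param jitter_sd Gaussian m/z jitter s.d. in Da.
#' @param mass_mode `"monoisotopic"` or `"integer"`.
#' @param seed Integer seed; required by every stochastic call.
#' @return A list of class `novopair_sim_config`.
#' @export
simulation_config <- function(length_range = c(7L, 12L),
                              charge_range = c(2L, 3L),
                              loss_prob = 0.2, dropout = 0.1,
                              noise_fraction = 0.3, jitter_sd = 0.003,
                              mass_mode = "monoisotopic", seed = NULL) {
  stopifnot(
    loss_prob >= 0, loss_prob <= 1, dropout >= 0, dropout < 1,
    noise_fraction >= 0, noise_fraction < 1, jitter_sd >= 0
  )
  structure(
    list(
      length_range = as.integer(length_range),
      charge_range = as.integer(charge_range),
      loss_prob = loss_prob, dropout = dropout,
      noise_fraction = noise_fraction, jitter_sd = jitter_sd,
      mass_mode = mass_mode, seed = seed
    ),
    class = "novopair_sim_config"
  )
}

.require_seed <- function(config, seed) {
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort("A seed is required for stochastic simulation.",
          class = "novopair_config_error")
  }
  as.integer(seed)
}

# Residues used for random peptides: I is excluded (indistinguishable from
# L by mass, so it would make exact-sequence recovery impossible by
# construction rather than by data).
.sim_alphabet <- function() {
  setdiff(names(.residue_mono), "I")
}

#' Random tryptic-like peptide
#'
#' Uniform residues from the 19-letter alphabet (no I), last residue K or R.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (overrides the config's).
#' @return A peptide string.
#' @export
random_peptide <- function(config = simulation_config(), seed = NULL) {
  seed <- .require_seed(config, seed)
  withr::with_seed(seed, {
    len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
    body <- sample(.sim_alphabet(), len - 1, replace = TRUE)
    paste(c(body, sample(c("K", "R"), 1)), collapse = "")
  })
}

# Derive a child seed from (seed, k); kept below 2^31 - 1.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k * 1009) %% 2147483647)
}

# Simulate one spectrum (one mode) for a peptide. The signal part (ladders,
# losses, jitter) and the noise part are drawn from two independently
# seeded streams, so libraries generated from the same base seed at
# different noise fractions share their real spectra exactly and their
# noise sets are nested (the smaller noise set is a prefix of the larger).
# Trained scores compared across noise levels then differ only through the
# added noise, which is the comparison the degradation property is about.
.simulate_spectrum <- function(peptide, mode, charge, config, table,
                               constants, signal_seed, noise_seed,
                               theta = 0.01) {
  series <- if (mode == "etd") c("c", "z") else c("b", "y")
  max_chg <- max(1L, charge - 1L)
  clean <- theoretical_fragments(peptide, series, max_charge = max_chg,
                                 losses = character(0),
                                 table = table, constants = constants)
  # full theoretical list (with losses, for the noise exclusion zone)
  all_theo <- theoretical_fragments(peptide, series, max_charge = max_chg,
                                    losses = names(constants$losses),
                                    table = table, constants = constants)
  sig <- withr::with_seed(signal_seed, {
    keep <- stats::runif(nrow(clean)) >= config$dropout
    real <- clean[keep, , drop = FALSE]
    ion <- sprintf("%s%d^%d", real$series, real$pos, real$charge)
    mz <- real$mz
    # neutral-loss satellites
    if (config$loss_prob > 0 && nrow(real) > 0) {
      has_loss <- stats::runif(nrow(real)) < config$loss_prob
      if (any(has_loss)) {
        which_loss <- sample(names(constants$losses), sum(has_loss),
                             replace = TRUE)
        lmz <- real$mz[has_loss] -
          constants$losses[which_loss] / real$charge[has_loss]
        mz <- c(mz, lmz)
        ion <- c(ion, sprintf("%s-%s", ion[has_loss], which_loss))
      }
    }
    if (config$jitter_sd > 0) {
      mz <- mz + stats::rnorm(length(mz), 0, config$jitter_sd)
    }
    list(mz = mz, ion = ion, intensity = stats::runif(length(mz), 0.2, 1))
  })
  n_real <- length(sig$mz)
  noise <- withr::with_seed(noise_seed, {
    out <- numeric(0)
    if (config$noise_fraction > 0 && n_real > 0) {
      n_noise <- round(config$noise_fraction / (1 - config$noise_fraction) *
                         n_real)
      m_p <- peptide_mass(peptide, table, constants)
      hi <- max(200, m_p + charge * constants$m_H)
      guard <- 0L
      while (length(out) < n_noise && guard < 10000L) {
        guard <- guard + 1L
        x <- stats::runif(1, 100, hi)
        if (!.near_any(x, all_theo$mz, 3 * theta)) out <- c(out, x)
      }
    }
    list(mz = out, intensity = stats::runif(length(out), 0.05, 0.3))
  })
  tibble(
    mz = c(sig$mz, noise$mz),
    intensity = c(sig$intensity, noise$intensity),
    is_noise = c(rep(FALSE, n_real), rep(TRUE, length(noise$mz))),
    ion = c(sig$ion, rep(NA_character_, length(noise$mz)))
  )
}

#' Simulate an HCD/ETD spectrum pair with ground truth
#'
#' Both spectra share the peptide (hence the parent mass); the HCD spectrum
#' is built from b/y ladders, the ETD spectrum from c/z ladders, at
#' fragment charges 1..n-1. Per-peak truth labels (`is_noise`, `ion`)
#' travel inside the peak tables.
#'
#' @param peptide Peptide string (>= 2 residues).
#' @param config A [simulation_config()].
#' @param seed Integer seed (overrides the config's).
#' @param theta Exclusion tolerance for noise placement.
#' @return A `novopair_pair` whose spectra carry truth columns; the peptide
#'   is attached as attribute `peptide`.
#' @export
simulate_pair <- function(peptide, config = simulation_config(),
                          seed = NULL, theta = 0.01) {
  if (nchar(peptide) < 2) abort("Peptide must have at least 2 residues.")
  seed <- .require_seed(config, seed)
  table <- amino_acid_table(config$mass_mode)
  constants <- mass_constants(config$mass_mode)
  m_p <- peptide_mass(peptide, table, constants)
  chg <- withr::with_seed(seed, {
    sample(seq(config$charge_range[1], config$charge_range[2]), 2,
           replace = TRUE)
  })
  hcd_peaks <- .simulate_spectrum(peptide, "hcd", chg[1], config, table,
                                  constants,
                                  signal_seed = .derive_seed(seed, 1L),
                                  noise_seed = .derive_seed(seed, 2L),
                                  theta = theta)
  etd_peaks <- .simulate_spectrum(peptide, "etd", chg[2], config, table,
                                  constants,
                                  signal_seed = .derive_seed(seed, 3L),
                                  noise_seed = .derive_seed(seed, 4L),
                                  theta = theta)
  hcd <- spectrum(hcd_peaks, precursor_mz = m_p / chg[1] + constants$m_H,
                  charge = chg[1], mode = "hcd",
                  title = paste0("sim|", peptide),
                  parent_mass = m_p, constants = constants)
  etd <- spectrum(etd_peaks, precursor_mz = m_p / chg[2] + constants$m_H,
                  charge = chg[2], mode = "etd",
                  title = paste0("sim|", peptide),
                  parent_mass = m_p, constants = constants)
  pair <- spectrum_pair(hcd, etd, tolerance = 0.02)
  attr(pair, "peptide") <- peptide
  pair
}

#' Simulate an annotated spectral library
#'
#' Random tryptic-like peptides, one annotated spectrum each in the
#' requested mode, suitable as training input or for writing out as MSP.
#'
#' @param n_peptides Number of library spectra.
#' @param mode `"hcd"` or `"etd"`.
#' @param config A [simulation_config()].
#' @param seed Integer seed (overrides the config's).
#' @param theta Noise exclusion tolerance.
#' @return A list of `novopair_library_spectrum` objects.
#' @export
simulate_library <- function(n_peptides, mode = "hcd",
                             config = simulation_config(), seed = NULL,
                             theta = 0.01) {
  stopifnot(n_peptides >= 1)
  mode <- match.arg(tolower(mode), c("hcd", "etd"))
  seed <- .require_seed(config, seed)
  table <- amino_acid_table(config$mass_mode)
  constants <- mass_constants(config$mass_mode)
  lapply(seq_len(n_peptides), function(i) {
    meta <- withr::with_seed(.derive_seed(seed, 3L * i), {
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      body <- sample(.sim_alphabet(), len - 1, replace = TRUE)
      list(
        pep = paste(c(body, sample(c("K", "R"), 1)), collapse = ""),
        chg = sample(seq(config$charge_range[1], config$charge_range[2]), 1)
      )
    })
    peaks <- .simulate_spectrum(meta$pep, mode, meta$chg, config, table,
                                constants,
                                signal_seed = .derive_seed(seed, 3L * i + 1L),
                                noise_seed = .derive_seed(seed, 3L * i + 2L),
                                theta = theta)
    m_p <- peptide_mass(meta$pep, table, constants)
    library_spectrum(
      peaks, peptide = meta$pep, precursor_mz = m_p / meta$chg + constants$m_H,
      charge = meta$chg, mode = mode,
      title = sprintf("simlib|%03d|%s", i, meta$pep),
      parent_mass = m_p, table = table, constants = constants
    )
  })
}
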