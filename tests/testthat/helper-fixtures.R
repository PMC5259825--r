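# Shared fixtures: the integer-mass toy spectrum pair used in the merge
# examples, small score models, and a clean (noise-free) simulation config.

toy_table <- amino_acid_table("integer")
toy_constants <- mass_constants("integer")

# HCD {130,199,277,346} at charge 2, ETD {132,182,234} at charge 3,
# parent mass 492, all masses integer.
toy_pair <- function() {
  hcd <- spectrum(
    tibble::tibble(mz = c(130, 199, 277, 346), intensity = 1),
    precursor_mz = 492 / 2 + 1, charge = 2, mode = "hcd",
    title = "toy", parent_mass = 492, constants = toy_constants
  )
  etd <- spectrum(
    tibble::tibble(mz = c(132, 182, 234), intensity = 1),
    precursor_mz = 492 / 3 + 1, charge = 3, mode = "etd",
    title = "toy", parent_mass = 492, constants = toy_constants
  )
  spectrum_pair(hcd, etd, tolerance = 0.5)
}

# Distinct scores so score composition is visible in sums; the HCD
# complementarity score is position-independent here, as in the toy example.
toy_models <- function(comp_hcd = 0.75) {
  list(
    hcd = score_model("hcd", aa = 0.61, comp_m = comp_hcd, comp_e = comp_hcd),
    etd = score_model("etd", aa = 0.66, comp = 0.42)
  )
}

# Unit score models: merged-peak scores become counts of fired criteria.
unit_models <- function() {
  list(
    hcd = score_model("hcd", aa = 1, comp_m = 1, comp_e = 1),
    etd = score_model("etd", aa = 1, comp = 1)
  )
}

clean_config <- function(...) {
  simulation_config(loss_prob = 0, dropout = 0, noise_fraction = 0,
                    jitter_sd = 0, ...)
}

# Integer tolerance used with the toy fixtures (exact integer matching).
toy_theta <- 0.25
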