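# The worked toy example drives most expectations here: HCD {130,199,277,346}
# at charge 2 and ETD {132,182,234} at charge 3 with m_p = 492 on the
# integer mass scale, loss mass 18.

test_that("charge expansion produces n-1 charge-1 hypotheses", {
  pr <- toy_pair()
  he <- expand_charges(pr$etd, toy_constants)
  expect_equal(sort(unique(he$charge)), c(1, 2))
  expect_equal(he$mz1[he$charge == 1], c(132, 182, 234))
  expect_equal(he$mz1[he$charge == 2], c(263, 363, 467))  # 2*mz - m_H
  hc <- expand_charges(pr$hcd, toy_constants)
  expect_equal(unique(hc$charge), 1)
  expect_equal(hc$mz1, c(130, 199, 277, 346))
  # degenerate precursor
  sp1 <- spectrum(tibble::tibble(mz = 100, intensity = 1), 200, 1)
  expect_error(expand_charges(sp1), class = "novopair_degenerate_precursor")
  # empty peak list still yields (empty) hypotheses
  sp0 <- spectrum(tibble::tibble(mz = numeric(0), intensity = numeric(0)),
                  200, 3)
  expect_equal(nrow(expand_charges(sp0)), 0)
})

test_that("aa-difference criterion selects the middle ion with its loss", {
  pr <- toy_pair()
  aa <- select_aa_difference(expand_charges(pr$hcd, toy_constants),
                             toy_table, toy_constants, toy_theta)
  # |(199-130) - a_S + 18| = 0 and |(346-199) - a_E - 18| = 0: only 199,
  # inferred to carry a water loss
  expect_equal(aa$mz1, 199)
  expect_equal(aa$sigma, 18)
  # 277 must NOT be selected: its would-be witnesses need losses on the
  # flanking ions, which the criterion does not model
  expect_false(277 %in% aa$mz1)
  # nothing on the ETD hypotheses
  aa_e <- select_aa_difference(expand_charges(pr$etd, toy_constants),
                               toy_table, toy_constants, toy_theta)
  expect_equal(nrow(aa_e), 0)
})

test_that("aa-difference handles small and loss-free cases", {
  hyp2 <- tibble::tibble(charge = 1L, source_index = 1:2,
                         source_mz = c(100, 187), mz1 = c(100, 187))
  expect_equal(nrow(select_aa_difference(hyp2, toy_table, toy_constants,
                                         toy_theta)), 0)
  hyp3 <- tibble::tibble(charge = 1L, source_index = 1:3,
                         source_mz = c(100, 187, 244),
                         mz1 = c(100, 187, 244))
  aa <- select_aa_difference(hyp3, toy_table, toy_constants, toy_theta)
  expect_equal(aa$mz1, 187)  # diffs 87 = S and 57 = G, sigma = 0
  expect_equal(aa$sigma, 0)
})

test_that("aa-difference agrees with a brute-force triple scan", {
  # independent O(p^3) oracle, same selection rule
  oracle <- function(mz1, masses, sigmas, theta) {
    sel <- logical(length(mz1))
    for (v in seq_along(mz1)) {
      for (u in seq_len(length(mz1))) {
        for (t in seq_len(length(mz1))) {
          if (!(mz1[u] < mz1[v] && mz1[v] < mz1[t])) next
          for (s in sigmas) {
            okl <- any(abs((mz1[v] - mz1[u]) - masses + s) <= theta)
            okr <- any(abs((mz1[t] - mz1[v]) - masses - s) <= theta)
            if (okl && okr) sel[v] <- TRUE
          }
        }
      }
    }
    sel
  }
  mono <- amino_acid_table()
  ct <- mass_constants()
  cfg <- simulation_config(noise_fraction = 0.4, jitter_sd = 0.002)
  for (s in 1:4) {
    pep <- random_peptide(cfg, seed = 500 + s)
    pair <- simulate_pair(pep, cfg, seed = 600 + s)
    hyp <- expand_charges(pair$hcd, ct)
    hyp1 <- hyp[hyp$charge == 1, ]
    got <- select_aa_difference(hyp1, mono, ct, 0.01)
    want <- hyp1$mz1[oracle(hyp1$mz1, mono$mass, c(0, ct$losses), 0.01)]
    expect_equal(sort(got$mz1), sort(want))
  }
})

test_that("complementarity finds the toy pairs and infers charge", {
  pr <- toy_pair()
  # HCD: with inferred losses from the aa step, 199 (+18) pairs with 277
  hyp_h <- expand_charges(pr$hcd, toy_constants)
  aa <- select_aa_difference(hyp_h, toy_table, toy_constants, toy_theta)
  ch <- select_complementarity(hyp_h, "hcd", 492, toy_constants, toy_theta,
                               sigma_mode = "inferred", inferred_losses = aa)
  expect_equal(nrow(ch), 1)
  expect_setequal(c(ch$u_mz1, ch$v_mz1), c(199, 277))
  # the literal free-sigma reading also admits (130, 346)
  ch_free <- select_complementarity(hyp_h, "hcd", 492, toy_constants,
                                    toy_theta, sigma_mode = "free")
  expect_setequal(paste(ch_free$u_mz1, ch_free$v_mz1),
                  c("199 277", "130 346"))
  # ETD: 132 (i=1) pairs with 363 (i=2); source peak 182 at inferred charge 2
  ce <- select_complementarity(expand_charges(pr$etd, toy_constants), "etd",
                               492, toy_constants, toy_theta,
                               sigma_mode = "inferred")
  expect_equal(nrow(ce), 1)
  expect_setequal(c(ce$u_mz1, ce$v_mz1), c(132, 363))
  partner <- if (ce$u_mz1 == 132) "v" else "u"
  expect_equal(ce[[paste0(partner, "_charge")]], 2L)
  sidx <- ce[[paste0(partner, "_source_index")]]
  expect_equal(pr$etd$peaks$mz[sidx], 182)
})

test_that("complementarity is symmetric and empty when nothing sums up", {
  hyp <- tibble::tibble(charge = 1L, source_index = 1:3,
                        source_mz = c(100, 150, 210),
                        mz1 = c(100, 150, 210))
  out <- select_complementarity(hyp, "hcd", 1000, toy_constants, toy_theta,
                                sigma_mode = "free")
  expect_equal(nrow(out), 0)
  # u and v both reported (pair row carries both members)
  hyp2 <- tibble::tibble(charge = 1L, source_index = 1:2,
                         source_mz = c(200, 294), mz1 = c(200, 294))
  out2 <- select_complementarity(hyp2, "hcd", 492, toy_constants, toy_theta,
                                 sigma_mode = "free")
  expect_equal(nrow(out2), 1)
  expect_setequal(c(out2$u_mz1, out2$v_mz1), c(200, 294))
})

test_that("merge_pair reproduces the toy merged spectrum with score sums", {
  m <- merge_pair(toy_pair(), toy_models(), toy_table, toy_constants,
                  theta = toy_theta)
  expect_s3_class(m, "novopair_merged")
  expect_equal(m$mz, c(132, 199, 277, 363))
  expect_equal(m$ss, c(0.42, 0.61 + 0.75, 0.75, 0.42))
  expect_equal(m$mode, c("etd", "hcd", "hcd", "etd"))
  expect_equal(attr(m, "m_p"), 492)
  # every ss equals the sum of its provenance scores
  for (i in seq_len(nrow(m))) {
    expect_equal(m$ss[i], sum(m$source[[i]]$score))
  }
  # the inferred +2 charge of the 182 peak is recorded in provenance
  src363 <- m$source[[which(m$mz == 363)]]
  expect_equal(src363$source_mz, 182)
  expect_equal(src363$charge, 2L)
})

test_that("merging empty spectra yields an empty merged spectrum", {
  e1 <- spectrum(tibble::tibble(mz = numeric(0), intensity = numeric(0)),
                 precursor_mz = 247, charge = 2, mode = "hcd",
                 parent_mass = 492, constants = toy_constants)
  e2 <- spectrum(tibble::tibble(mz = numeric(0), intensity = numeric(0)),
                 precursor_mz = 165, charge = 3, mode = "etd",
                 parent_mass = 492, constants = toy_constants)
  m <- merge_pair(spectrum_pair(e1, e2, 0.5), toy_models(), toy_table,
                  toy_constants, theta = toy_theta)
  expect_equal(nrow(m), 0)
  expect_s3_class(m, "novopair_merged")
})

test_that("a peak satisfying one criterion via several witnesses scores once", {
  # 5-peak integer ladder G-A-S-A: 1, 58, 129, 216, 287 (b-type + proton);
  # middle peaks have multiple (u, t) witness triples
  mzs <- c(58, 129, 216, 287, 344)  # diffs: 71(A) 87(S) 71(A) 57(G)
  m_p <- 500
  hcd <- spectrum(tibble::tibble(mz = mzs, intensity = 1), m_p / 2 + 1, 2,
                  "hcd", parent_mass = m_p, constants = toy_constants)
  etd <- spectrum(tibble::tibble(mz = 100, intensity = 1), m_p / 2 + 1, 2,
                  "etd", parent_mass = m_p, constants = toy_constants)
  m <- merge_pair(spectrum_pair(hcd, etd, 0.5), unit_models(), toy_table,
                  toy_constants, theta = toy_theta)
  # 216 has witness triples (129, 287) and (58, 344) among others, but the
  # aa criterion contributes exactly once: unit score model -> ss = 1
  expect_equal(m$ss[m$mz == 216], 1)
  aa_rows <- m$source[[which(m$mz == 216)]]
  expect_equal(sum(aa_rows$criterion == "aa"), 1)
})

test_that("on noise-free pairs every selected peak is a true fragment", {
  cfg <- clean_config()
  mono <- amino_acid_table()
  ct <- mass_constants()
  for (s in 1:3) {
    pep <- random_peptide(cfg, seed = 700 + s)
    pair <- simulate_pair(pep, cfg, seed = 800 + s)
    m <- merge_pair(pair, unit_models(), mono, ct, theta = 0.01)
    theo_h <- theoretical_fragments(pep, c("b", "y"),
                                    max(1, pair$hcd$charge - 1),
                                    character(0), mono, ct)$mz
    theo_e <- theoretical_fragments(pep, c("c", "z"),
                                    max(1, pair$etd$charge - 1),
                                    character(0), mono, ct)$mz
    for (i in seq_len(nrow(m))) {
      src <- m$source[[i]]
      for (j in seq_len(nrow(src))) {
        theo <- if (src$mode[j] == "etd") theo_e else theo_h
        expect_lte(min(abs(theo - src$source_mz[j])), 0.01)
      }
    }
  }
})
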