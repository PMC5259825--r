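test_that("real-ion annotation separates ladder peaks from planted noise", {
  cfg <- clean_config()
  lib <- simulate_library(1, "hcd", cfg, seed = 31)
  sp <- lib[[1]]
  expect_true(all(annotate_real_ions(sp)))

  # add one off-ladder peak far from every theoretical fragment
  theo <- theoretical_fragments(sp$peptide, c("b", "y"),
                                max(1, sp$charge - 1),
                                names(mass_constants()$losses))
  off <- 150.0
  while (min(abs(theo$mz - off)) < 0.05) off <- off + 0.171
  pk <- dplyr::bind_rows(sp$peaks[, c("mz", "intensity")],
                         tibble::tibble(mz = off, intensity = 1))
  sp2 <- library_spectrum(pk, sp$peptide, sp$precursor_mz, sp$charge,
                          mode = "hcd", parent_mass = sp$parent_mass)
  marks <- annotate_real_ions(sp2)
  expect_false(marks[which(abs(sp2$peaks$mz - off) < 1e-9)])
  expect_equal(sum(marks), nrow(sp2$peaks) - 1)

  # boundary convention: a peak exactly at tolerance is real (offset and
  # tolerance chosen exactly representable in binary)
  b1 <- theo$mz[theo$series == "b" & theo$pos == 1 & theo$loss == "none"][1]
  delta <- 0.0078125
  pk3 <- tibble::tibble(mz = b1 + delta, intensity = 1)
  sp3 <- library_spectrum(pk3, sp$peptide, sp$precursor_mz, sp$charge,
                          mode = "hcd", parent_mass = sp$parent_mass)
  expect_true(annotate_real_ions(sp3, tolerance = delta))
})

test_that("per-spectrum accuracy counts selected vs selected-and-real", {
  cfg <- clean_config()
  sp <- simulate_library(1, "hcd", cfg, seed = 33)[[1]]
  acc <- spectrum_criterion_accuracy(sp, "aa")
  expect_equal(acc$accuracy, 1)
  expect_false(acc$skipped)
  expect_equal(acc$n_real, acc$n_select)

  # a 3-peak spectrum with no residue-spaced differences: nothing selected
  pep <- "GGGGGGK"
  m_p <- peptide_mass(pep)
  pk <- tibble::tibble(mz = c(150.123, 250.456, 380.789), intensity = 1)
  sp0 <- library_spectrum(pk, pep, m_p / 2 + 1.007276, 2, mode = "hcd",
                          parent_mass = m_p)
  acc0 <- spectrum_criterion_accuracy(sp0, "aa")
  expect_true(acc0$skipped)
  expect_true(is.na(acc0$accuracy))
})

test_that("training averages per-spectrum accuracies over contributors", {
  cfg <- clean_config()
  lib <- simulate_library(8, "etd", cfg, seed = 35)
  model <- train_score_model(lib, "etd")
  expect_s3_class(model, "novopair_score_model")
  expect_equal(unname(model$scores), rep(1, 2))
  expect_named(model$scores, c("aa", "comp"))

  # adding a spectrum that selects nothing leaves the scores unchanged
  pep <- "GGGGGGK"
  m_p <- peptide_mass(pep)
  dud <- library_spectrum(
    tibble::tibble(mz = c(150.123, 250.456), intensity = 1),
    pep, m_p / 2 + 1.007276, 2, mode = "etd", parent_mass = m_p
  )
  model2 <- train_score_model(c(lib, list(dud)), "etd")
  expect_equal(model2$scores, model$scores)
  expect_equal(model2$n_spectra[["aa"]], model$n_spectra[["aa"]])

  expect_error(train_score_model(list(), "etd"),
               class = "novopair_training_error")
  expect_error(train_score_model(list(dud), "etd"),
               class = "novopair_training_error")
})

test_that("HCD training produces the positional comp split", {
  cfg <- clean_config()
  model <- train_score_model(simulate_library(8, "hcd", cfg, seed = 37),
                             "hcd")
  expect_named(model$scores, c("aa", "comp_m", "comp_e"))
  expect_true(all(model$scores >= 0 & model$scores <= 1))
})

test_that("a planted noise peak that mimics residue spacing lowers accuracy", {
  # GASK b/y ladders plus one planted peak at b1 + G, which has flanking
  # witnesses (b1 below, b3 above via G then T) but is no fragment ion:
  # the aa criterion selects b2, y2 and the plant -> accuracy 2/3
  pep <- "GASK"
  m_p <- peptide_mass(pep)
  fr <- theoretical_fragments(pep, c("b", "y"), 1)
  plant <- fr$mz[fr$series == "b" & fr$pos == 1] + residue_mass("G")
  all_theo <- theoretical_fragments(pep, c("b", "y"), 1,
                                    names(mass_constants()$losses))
  expect_gt(min(abs(all_theo$mz - plant)), 0.05)  # clean plant
  sp <- library_spectrum(
    tibble::tibble(mz = c(fr$mz, plant), intensity = 1),
    pep, m_p / 2 + 1.007276, 2, mode = "hcd", parent_mass = m_p
  )
  acc <- spectrum_criterion_accuracy(sp, "aa")
  expect_equal(acc$n_select, 3L)
  expect_equal(acc$n_real, 2L)
  expect_equal(acc$accuracy, 2 / 3)
})

test_that("score models round trip through JSON with schema checks", {
  m <- score_model("hcd", aa = 0.61, comp_m = 0.79, comp_e = 0.92,
                   n_spectra = c(aa = 10L, comp_m = 9L, comp_e = 10L),
                   params = list(theta = 0.01))
  path <- withr::local_tempfile(fileext = ".json")
  write_score_model(m, path)
  back <- read_score_model(path)
  expect_equal(back$scores, m$scores)
  expect_equal(back$mode, "hcd")
  expect_equal(back$params$theta, 0.01)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"foo": 1}', bad)
  expect_error(read_score_model(bad), class = "novopair_config_error")

  expect_error(score_model("hcd", aa = 1.2, comp_m = 1, comp_e = 1),
               class = "novopair_config_error")
  expect_error(score_model("etd", aa = 0.5), class = "novopair_config_error")
})

test_that("tidy and glance summarise score models", {
  m <- score_model("etd", aa = 0.66, comp = 0.42,
                   n_spectra = c(aa = 5L, comp = 4L),
                   params = list(theta = 0.01, tolerance = 0.01,
                                 mass_mode = "monoisotopic"))
  td <- tidy(m)
  expect_equal(td$criterion, c("aa", "comp"))
  expect_equal(td$estimate, c(0.66, 0.42))
  expect_equal(td$n_spectra, c(5L, 4L))
  gl <- glance(m)
  expect_equal(gl$mode, "etd")
  expect_equal(gl$theta, 0.01)
})
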