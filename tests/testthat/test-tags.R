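# Tag fixtures use hand-computed integer chains; scored-peak tibbles stand
# in for merged spectra (generate_tags only needs mz / ss / mode columns).

mk_peaks <- function(mz, ss = 1, mode = "hcd") {
  tibble::tibble(mz = mz, ss = ss, mode = mode)
}

test_that("length-3 tags are read from residue-spaced peak chains", {
  tg <- generate_tags(mk_peaks(c(88, 175, 304, 417)), toy_table, toy_theta)
  expect_equal(tg$sequence, "SEL")      # diffs 87, 129, 113
  expect_equal(tg$length, 3L)
  expect_equal(tg$mz[[1]], c(88, 175, 304, 417))

  expect_equal(nrow(generate_tags(mk_peaks(c(88, 175, 304)), toy_table,
                                  toy_theta)), 0)

  tg2 <- generate_tags(mk_peaks(c(88, 175, 304, 417, 474)), toy_table,
                       toy_theta)
  expect_setequal(tg2$sequence, c("SEL", "ELG"))
})

test_that("tag chains agree with an exhaustive 4-subset oracle", {
  lk_mass <- sort(unique(toy_table$mass))
  for (s in 1:3) {
    mz <- withr::with_seed(900 + s, sort(sample(50:600, 25)))
    tg <- generate_tags(mk_peaks(mz), toy_table, toy_theta)
    # oracle: every 4-subset whose consecutive diffs are residue masses
    n_oracle <- 0L
    cmb <- utils::combn(length(mz), 4)
    for (j in seq_len(ncol(cmb))) {
      d <- diff(mz[cmb[, j]])
      if (all(vapply(d, function(x) any(abs(x - lk_mass) <= toy_theta),
                     TRUE))) {
        n_oracle <- n_oracle + 1L
      }
    }
    expect_equal(nrow(tg), n_oracle)
  }
})

test_that("tags extend through two-residue overlaps to a fixed point", {
  # TAGTA chain: peaks at cumulative T, A, G, T, A offsets
  res <- c("T", "A", "G", "T", "A")
  mz <- 100 + cumsum(c(0, residue_mass(res, toy_table)))
  tg <- generate_tags(mk_peaks(mz), toy_table, toy_theta)
  # the consecutive chains, plus isobaric cross-chains (A+G matches K/Q)
  expect_true(all(c("TAG", "AGT", "GTA") %in% tg$sequence))
  ext <- extend_tags(tg, toy_theta)
  expect_true(all(c("TAGT", "AGTA", "TAGTA") %in% ext$sequence))
  # the full-length tag is supported by all six peaks
  full <- ext[ext$sequence == "TAGTA", ]
  expect_equal(full$mz[[1]], mz)
  # fixed point: extending again adds nothing
  ext2 <- extend_tags(ext, toy_theta)
  expect_setequal(ext2$sequence, ext$sequence)
  # no overlap -> unchanged
  lone <- generate_tags(mk_peaks(c(88, 175, 304, 417)), toy_table, toy_theta)
  expect_equal(extend_tags(lone, toy_theta)$sequence, lone$sequence)
})

test_that("tag extension result is independent of input order", {
  res <- c("T", "A", "G", "T", "A", "G")
  mz <- 100 + cumsum(c(0, residue_mass(res, toy_table)))
  tg <- generate_tags(mk_peaks(mz), toy_table, toy_theta)
  for (s in 1:3) {
    perm <- withr::with_seed(s, sample(nrow(tg)))
    ext <- extend_tags(tg[perm, ], toy_theta)
    expect_setequal(ext$sequence, extend_tags(tg, toy_theta)$sequence)
  }
})

test_that("tag scoring matches the published weights and both variants", {
  mk_tag <- function(ss) {
    out <- tibble::tibble(
      sequence = "AAA", length = 3L, s_t = NA_real_, mode_class = "hcd",
      peak_idx = list(1:4), mz = list(c(100, 171, 242, 313)), ss = list(ss)
    )
    class(out) <- c("novopair_tags", class(out))
    out
  }
  # l_t = 3, uniform unit scores: printed weights (1.1, 1.1, 1.0, 0.9)
  expect_equal(score_tags(mk_tag(rep(1, 4)))$s_t, 1.025)
  # symmetric variant: (1.0, 1.1, 1.1, 1.0)
  expect_equal(score_tags(mk_tag(rep(1, 4)), symmetric = TRUE)$s_t, 1.05)
  # only the first peak scored: weight 1.1 on ss = 2
  expect_equal(score_tags(mk_tag(c(2, 0, 0, 0)))$s_t, 0.55)
  expect_equal(score_tags(mk_tag(rep(0, 4)))$s_t, 0)
})

test_that("tag selection ranks by score with deterministic ties", {
  base <- generate_tags(mk_peaks(c(88, 175, 304, 417)), toy_table, toy_theta)
  tags <- dplyr::bind_rows(lapply(1:15, function(i) {
    t <- base
    t$sequence <- paste0("T", sprintf("%02d", i))
    t$ss <- list(rep(i / 15, 4))
    t
  }))
  class(tags) <- c("novopair_tags", class(tags))
  sel <- select_tags(score_tags(tags), sel = 10, per_mode = FALSE)
  expect_equal(nrow(sel), 10)
  expect_equal(sel$s_t, sort(sel$s_t, decreasing = TRUE))
  expect_equal(nrow(select_tags(score_tags(tags[1:4, ]), sel = 10,
                                per_mode = FALSE)), 4)

  # equal scores at the cut: longer first, then lexicographic
  t1 <- base; t1$sequence <- "BBB"; t1$ss <- list(rep(1, 4))
  t2 <- base; t2$sequence <- "AAA"; t2$ss <- list(rep(1, 4))
  t3 <- tibble::tibble(
    sequence = "CCCC", length = 4L, s_t = NA_real_, mode_class = "hcd",
    peak_idx = list(1:5), mz = list(seq(100, 500, 100)),
    ss = list(c(1.36, 1.36, 1, 1, 0.56))  # tuned so s_t ties at length 4
  )
  tie <- dplyr::bind_rows(t2, t1, t3)
  class(tie) <- c("novopair_tags", class(tie))
  tie <- score_tags(tie)
  # force exact tie by overwriting scores
  tie$s_t <- c(1, 1, 1)
  sel2 <- select_tags(tie, sel = 2, per_mode = FALSE)
  expect_equal(sel2$sequence, c("CCCC", "AAA"))
  sel3 <- select_tags(tie, sel = 2, per_mode = FALSE)
  expect_identical(sel2$sequence, sel3$sequence)
})

test_that("per-mode tag budgets are honoured", {
  mk <- function(seqs, mode) {
    dplyr::bind_rows(lapply(seqs, function(sq) {
      tibble::tibble(sequence = sq, length = 3L, s_t = NA_real_,
                     mode_class = mode, peak_idx = list(1:4),
                     mz = list(c(88, 175, 304, 417)), ss = list(rep(1, 4)))
    }))
  }
  tags <- dplyr::bind_rows(mk(paste0("H", 1:12), "hcd"),
                           mk(paste0("E", 1:5), "etd"))
  class(tags) <- c("novopair_tags", class(tags))
  sel <- select_tags(score_tags(tags), sel = 10, per_mode = TRUE)
  expect_equal(sum(sel$mode_class == "hcd"), 10)
  expect_equal(sum(sel$mode_class == "etd"), 5)
})

test_that("emitted tags re-validate against the residue table", {
  cfg <- clean_config()
  pair <- simulate_pair("TESTPEPK", cfg, seed = 51)
  m <- merge_pair(pair, unit_models())
  tags <- extend_tags(generate_tags(m), 0.01)
  lk_mass <- sort(unique(amino_acid_table()$mass))
  for (i in seq_len(nrow(tags))) {
    d <- diff(tags$mz[[i]])
    expect_true(all(vapply(d, function(x) any(abs(x - lk_mass) <= 0.011),
                           TRUE)))
    expect_equal(tags$length[i], nchar(tags$sequence[i]))
    expect_equal(tags$length[i] + 1L, length(tags$mz[[i]]))
  }
})
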