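# Peak selection and spectrum merging.
#
# Both selection criteria work on charge-1 re-expressions of a spectrum's
# peaks: under the assumption that every peak carries charge i (i = 1..n-1,
# n the precursor charge), its charge-1 m/z is i*mz - (i-1)*m_H. The
# amino-acid-difference criterion is evaluated within one charge hypothesis;
# the complementarity criterion may pair peaks across hypotheses of the same
# spectrum.

#' Expand a spectrum into its charge hypotheses
#'
#' For a precursor of charge `n`, fragment ions can carry charges 1..n-1.
#' Each hypothesis re-expresses every peak at charge 1 under a uniform
#' assumed charge `i`.
#'
#' @param spec A [spectrum()].
#' @param constants Constants from [mass_constants()].
#' @return A tibble with one row per (peak, assumed charge): columns
#'   `charge` (assumed `i`), `source_index`, `source_mz`, `mz1` (charge-1
#'   m/z), sorted by `charge` then `mz1`.
#' @export
expand_charges <- function(spec, constants = mass_constants()) {
  stopifnot(inherits(spec, "novopair_spectrum"))
  n <- spec$charge
  if (n < 2) {
    abort("Precursor charge must be >= 2 to expand fragment charges.",
          class = "novopair_degenerate_precursor")
  }
  mz <- spec$peaks$mz
  out <- purrr::map_dfr(seq_len(n - 1L), function(i) {
    tibble(
      charge = i, source_index = seq_along(mz), source_mz = mz,
      mz1 = to_charge1(mz, i, constants)
    )
  })
  dplyr::arrange(out, .data$charge, .data$mz1)
}

# Core of the aa-difference criterion on one sorted charge-1 vector.
# A middle ion v is selected if there are u < v < t with
#   (v - u) = a_i - sigma   and   (t - v) = a_j + sigma
# for the same sigma in {0} U losses: sigma is the loss carried by v itself
# (a fragment that lost water sits 18 Da below the spacing expected from its
# neighbours on the left, and 18 Da above on the right).
.aa_select_one <- function(mz1, masses, sigmas, theta) {
  p <- length(mz1)
  sel_sigma <- rep(NA_real_, p)
  if (p < 3) return(sel_sigma)
  for (v in 2:(p - 1)) {
    dl <- mz1[v] - mz1[seq_len(v - 1)]
    dr <- mz1[(v + 1):p] - mz1[v]
    for (s in sigmas) {
      if (any(.near_any(dl + s, masses, theta)) &&
          any(.near_any(dr - s, masses, theta))) {
        sel_sigma[v] <- s
        break
      }
    }
  }
  sel_sigma
}

#' Select middle ions by the amino-acid mass-difference criterion
#'
#' A peak `v` is selected when flanking peaks `u < v < t` exist in the same
#' charge hypothesis whose differences to `v` both read as residue masses
#' once `v`'s own neutral loss `sigma` is accounted for:
#' `|(v - u) - a_i + sigma| <= theta` and `|(t - v) - a_j - sigma| <= theta`
#' with a single `sigma` from `{0}` and the loss masses. Only the middle ion
#' is selected.
#'
#' @param hypotheses A tibble from [expand_charges()] (one or more charge
#'   hypotheses; the criterion is applied within each).
#' @param table Residue table.
#' @param constants Constants (supplies the loss masses).
#' @param theta Selection tolerance in Da.
#' @return A tibble of selected middle ions: `charge`, `source_index`,
#'   `source_mz`, `mz1`, `sigma` (inferred loss mass, 0 when none).
#' @export
select_aa_difference <- function(hypotheses, table = amino_acid_table(),
                                 constants = mass_constants(), theta = 0.01) {
  sigmas <- c(0, unname(constants$losses))
  masses <- sort(unique(table$mass))
  out <- hypotheses |>
    dplyr::group_by(.data$charge) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$mz1)
      df$sigma <- .aa_select_one(df$mz1, masses, sigmas, theta)
      df[!is.na(df$sigma), c("source_index", "source_mz", "mz1", "sigma")]
    }) |>
    dplyr::ungroup()
  out
}

#' Select complementary ion pairs
#'
#' Two charge-1 peaks `u`, `v` of the same spectrum are complementary when
#' they flank one backbone cleavage: `u+ + v+ = m_p + 2 m_H` for HCD (b/y)
#' or `m_p + 3 m_H` for ETD (c/z). Pairs may span different charge
#' hypotheses. Neutral losses are handled in one of two ways:
#'
#' * `sigma_mode = "inferred"` (the pipeline default): each peak's m/z is
#'   first corrected by the loss inferred for it by
#'   [select_aa_difference()] (0 when none), and the relation is then tested
#'   without slack.
#' * `sigma_mode = "free"`: the relation is tested with an explicit
#'   `+/- sigma` term over `{0}` and the loss masses.
#'
#' @param hypotheses Tibble from [expand_charges()] covering all charge
#'   hypotheses of one spectrum.
#' @param mode `"hcd"` or `"etd"` (chooses `2 m_H` vs `3 m_H`).
#' @param m_p Neutral parent peptide mass.
#' @param constants,theta As in [select_aa_difference()].
#' @param sigma_mode `"inferred"` or `"free"`.
#' @param inferred_losses Optional tibble with columns `source_index`,
#'   `charge`, `sigma` (the output of [select_aa_difference()]); used only in
#'   `"inferred"` mode.
#' @return A tibble of selected pairs, one row per pair: columns
#'   `u_source_index`, `u_charge`, `u_mz1`, `v_source_index`, `v_charge`,
#'   `v_mz1`, `sigma` (total loss offset used) and `middle` (both members in
#'   the middle two quarters of the spectrum's m/z range).
#' @export
select_complementarity <- function(hypotheses, mode, m_p,
                                   constants = mass_constants(), theta = 0.01,
                                   sigma_mode = c("free", "inferred"),
                                   inferred_losses = NULL) {
  mode <- match.arg(tolower(mode), c("hcd", "etd"))
  sigma_mode <- match.arg(sigma_mode)
  k <- if (mode == "hcd") 2 else 3
  target <- m_p + k * constants$m_H

  h <- dplyr::arrange(hypotheses, .data$charge, .data$mz1)
  p <- nrow(h)
  empty <- tibble(
    u_source_index = integer(0), u_charge = integer(0), u_mz1 = numeric(0),
    v_source_index = integer(0), v_charge = integer(0), v_mz1 = numeric(0),
    sigma = numeric(0), middle = logical(0)
  )
  if (p < 2) return(empty)

  corr <- rep(0, p)
  if (sigma_mode == "inferred" && !is.null(inferred_losses) &&
      nrow(inferred_losses) > 0) {
    key <- paste(h$source_index, h$charge)
    lk <- paste(inferred_losses$source_index, inferred_losses$charge)
    m <- match(key, lk)
    corr <- ifelse(is.na(m), 0, inferred_losses$sigma[m])
  }
  sigmas <- if (sigma_mode == "free") {
    c(0, unname(constants$losses), -unname(constants$losses))
  } else 0

  x <- h$mz1 + corr
  # positional split of the charge-1 m/z axis into four equal parts; the
  # axis top is the largest possible charge-1 fragment value (m_p + k m_H),
  # which keeps the middle/end classification independent of which peaks
  # happen to be observed
  qmax <- target
  in_middle <- h$mz1 >= 0.25 * qmax & h$mz1 <= 0.75 * qmax

  # vectorised pair scan: all index pairs a < b with a different source peak
  pr <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  a <- pr[, 1]; b <- pr[, 2]
  keep <- h$source_index[a] != h$source_index[b]
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) return(empty)
  dev0 <- target - (x[a] + x[b])
  hit <- rep(FALSE, length(a))
  best_sig <- numeric(length(a))
  for (s in sigmas) {
    ok <- !hit & abs(dev0 - s) <= theta
    best_sig[ok] <- s
    hit <- hit | ok
  }
  a <- a[hit]; b <- b[hit]
  if (length(a) == 0) return(empty)
  sig <- if (sigma_mode == "free") best_sig[hit][seq_along(a)] else
    corr[a] + corr[b]
  tibble(
    u_source_index = h$source_index[a], u_charge = h$charge[a],
    u_mz1 = h$mz1[a],
    v_source_index = h$source_index[b], v_charge = h$charge[b],
    v_mz1 = h$mz1[b],
    sigma = sig, middle = in_middle[a] & in_middle[b]
  )
}

# Run both criteria on one spectrum; returns the raw selections.
# Used by merge_pair() and by the library-training accuracies.
.select_peaks <- function(spec, table, constants, theta,
                          sigma_mode = "inferred") {
  hyp <- expand_charges(spec, constants)
  aa <- select_aa_difference(hyp, table, constants, theta)
  comp <- select_complementarity(
    hyp, spec$mode, spec$parent_mass, constants, theta,
    sigma_mode = sigma_mode, inferred_losses = aa
  )
  list(hypotheses = hyp, aa = aa, comp = comp)
}

# Long form of comp pairs: one row per selected member.
.comp_members <- function(comp) {
  if (nrow(comp) == 0) {
    return(tibble(source_index = integer(0), charge = integer(0),
                  mz1 = numeric(0), middle = logical(0)))
  }
  dplyr::bind_rows(
    tibble(source_index = comp$u_source_index, charge = comp$u_charge,
           mz1 = comp$u_mz1, middle = comp$middle),
    tibble(source_index = comp$v_source_index, charge = comp$v_charge,
           mz1 = comp$v_mz1, middle = comp$middle)
  )
}

# Score the selections of one spectrum with its mode's score model.
# Each (source peak, assumed charge) scores each criterion type at most
# once; a peak in several complementary pairs takes the best positional
# score. Returns one row per scored charge-1 peak.
.score_selected <- function(sel, mode, model) {
  aa_score <- model$scores[["aa"]]
  aa <- sel$aa
  aa_rows <- if (nrow(aa) > 0) {
    tibble(
      source_index = aa$source_index, charge = aa$charge, mz1 = aa$mz1,
      criterion = "aa", score = aa_score, sigma = aa$sigma
    )
  } else NULL

  cm <- .comp_members(sel$comp)
  comp_rows <- if (nrow(cm) > 0) {
    cm$score <- if (mode == "hcd") {
      ifelse(cm$middle, model$scores[["comp_m"]], model$scores[["comp_e"]])
    } else {
      model$scores[["comp"]]
    }
    cm |>
      dplyr::group_by(.data$source_index, .data$charge) |>
      dplyr::summarise(
        mz1 = .data$mz1[1], score = max(.data$score), .groups = "drop"
      ) |>
      dplyr::mutate(criterion = "comp", sigma = NA_real_)
  } else NULL

  out <- dplyr::bind_rows(aa_rows, comp_rows)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(source_index = integer(0), charge = integer(0),
                  mz1 = numeric(0), criterion = character(0),
                  score = numeric(0), sigma = numeric(0)))
  }
  out
}

#' Merge an HCD/ETD spectrum pair into one scored spectrum
#'
#' Runs both selection criteria on every charge hypothesis of both spectra,
#' scores each selected peak with the library-trained significance score of
#' the criterion that fired (HCD complementarity uses the positional
#' middle/end split), sums scores over distinct criteria, and coalesces
#' selected charge-1 peaks that agree within `theta` into single scored
#' peaks at the score-weighted mean m/z. Unselected peaks are dropped.
#'
#' @param pair A [spectrum_pair()].
#' @param models A list with elements `hcd` and `etd`, each a
#'   [score_model()].
#' @param table,constants,theta As in [select_aa_difference()].
#' @param sigma_mode Loss handling for complementarity, see
#'   [select_complementarity()].
#' @return A tibble of class `novopair_merged` with columns `mz`, `ss`
#'   (significance score), `mode` (`"hcd"`, `"etd"` or `"both"`) and
#'   `source` (list column: one row per contributing selection with `mode`,
#'   `source_mz`, `charge`, `criterion`, `sigma`, `score`). Attributes
#'   `m_p` and `theta` carry the merge context.
#' @export
merge_pair <- function(pair, models, table = amino_acid_table(),
                       constants = mass_constants(), theta = 0.01,
                       sigma_mode = "inferred") {
  stopifnot(inherits(pair, "novopair_pair"))
  for (m in c("hcd", "etd")) {
    if (!inherits(models[[m]], "novopair_score_model")) {
      abort(sprintf("models$%s must be a novopair_score_model.", m),
            class = "novopair_config_error")
    }
  }
  scored <- purrr::map_dfr(c("hcd", "etd"), function(m) {
    sp <- pair[[m]]
    if (nrow(sp$peaks) == 0) return(NULL)
    sel <- .select_peaks(sp, table, constants, theta, sigma_mode)
    rows <- .score_selected(sel, m, models[[m]])
    if (nrow(rows) == 0) return(NULL)
    rows$mode <- m
    rows$source_mz <- sp$peaks$mz[rows$source_index]
    rows
  })
  .build_merged(scored, pair$parent_mass, theta)
}

# Collapse scored selection rows into the merged spectrum tibble.
.build_merged <- function(scored, m_p, theta) {
  if (is.null(scored) || nrow(scored) == 0) {
    out <- tibble(mz = numeric(0), ss = numeric(0), mode = character(0),
                  source = list())
  } else {
    # one scored peak per (mode, source peak, assumed charge); ss = sum over
    # distinct criteria
    peaks <- scored |>
      dplyr::group_by(.data$mode, .data$source_index, .data$charge) |>
      dplyr::group_modify(function(df, key) {
        tibble(
          mz1 = df$mz1[1], ss = sum(df$score),
          source = list(tibble(
            mode = key$mode, source_mz = df$source_mz, charge = key$charge,
            criterion = df$criterion, sigma = df$sigma, score = df$score
          ))
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$mz1)
    # coalesce peaks within theta (greedy cluster over the sorted axis)
    cl <- cumsum(c(TRUE, diff(peaks$mz1) > theta))
    out <- peaks |>
      dplyr::mutate(cluster = cl) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(
        mz = if (dplyr::n() == 1) {
          .data$mz1[1]  # keep singleton m/z exact
        } else if (sum(.data$ss) > 0) {
          sum(.data$mz1 * .data$ss) / sum(.data$ss)
        } else mean(.data$mz1),
        ss = sum(.data$ss),
        mode = if (length(unique(.data$mode)) > 1) "both" else .data$mode[1],
        source = list(dplyr::bind_rows(.data$source)),
        .groups = "drop"
      ) |>
      dplyr::select(-"cluster") |>
      dplyr::arrange(.data$mz)
  }
  attr(out, "m_p") <- m_p
  attr(out, "theta") <- theta
  class(out) <- c("novopair_merged", class(out))
  out
}
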