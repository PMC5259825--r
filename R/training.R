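# Library training: the significance score of a selection criterion is its
# average precision over an annotated spectral library — on each library
# spectrum, run the selector, count how many selected peaks are true
# fragment ions of the annotated peptide, and average the per-spectrum
# fractions over all spectra that selected at least one peak.

#' Construct a score model
#'
#' Significance scores of the selection criteria for one fragmentation
#' mode. HCD models carry the positional split of the complementarity score
#' (middle vs end pairs); ETD models carry a single complementarity score.
#'
#' @param mode `"hcd"` or `"etd"`.
#' @param aa Amino-acid-difference score, in `[0, 1]`.
#' @param comp ETD complementarity score (ETD mode only).
#' @param comp_m,comp_e HCD complementarity scores for pairs in the middle
#'   two quarters / the two end quarters of the m/z range (HCD mode only).
#' @param n_spectra Named integer vector: contributing spectra per score
#'   (optional, for provenance).
#' @param params Named list of training parameters (theta, tolerance, ...).
#' @return An object of class `novopair_score_model`.
#' @export
score_model <- function(mode, aa, comp = NULL, comp_m = NULL, comp_e = NULL,
                        n_spectra = NULL, params = list()) {
  mode <- match.arg(tolower(mode), c("hcd", "etd"))
  scores <- if (mode == "hcd") {
    if (is.null(comp_m) || is.null(comp_e)) {
      abort("HCD score model needs comp_m and comp_e.",
            class = "novopair_config_error")
    }
    c(aa = aa, comp_m = comp_m, comp_e = comp_e)
  } else {
    if (is.null(comp)) {
      abort("ETD score model needs comp.", class = "novopair_config_error")
    }
    c(aa = aa, comp = comp)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    abort("All significance scores must lie in [0, 1].",
          class = "novopair_config_error")
  }
  structure(
    list(mode = mode, scores = scores,
         n_spectra = n_spectra, params = params),
    class = "novopair_score_model"
  )
}

#' @export
print.novopair_score_model <- function(x, ...) {
  cat(sprintf("<novopair_score_model> mode=%s\n", x$mode))
  print(round(x$scores, 4))
  invisible(x)
}

#' Mark which peaks of a library spectrum are real fragment ions
#'
#' A peak is real when its observed m/z matches any theoretical fragment of
#' the annotated peptide — series per mode (b/y for HCD, c/z for ETD),
#' charges 1..n-1, neutral losses none/H2O/NH3 — within `tolerance`
#' (closed interval).
#'
#' @param spec A [library_spectrum()] with its mode set.
#' @param table,constants Residue table and constants.
#' @param tolerance Match tolerance (Da); defaults to the selection
#'   threshold theta.
#' @return Logical vector, one element per peak.
#' @export
annotate_real_ions <- function(spec, table = amino_acid_table(),
                               constants = mass_constants(),
                               tolerance = 0.01) {
  stopifnot(inherits(spec, "novopair_library_spectrum"))
  series <- if (spec$mode == "etd") c("c", "z") else c("b", "y")
  theo <- theoretical_fragments(
    spec$peptide, series = series, max_charge = max(1L, spec$charge - 1L),
    losses = names(constants$losses), table = table, constants = constants
  )
  .near_any(spec$peaks$mz, theo$mz, tolerance)
}

# Theoretical charge-1 m/z ladder used to validate charge-1 re-expressions.
.theo_mz1 <- function(spec, table, constants) {
  series <- if (spec$mode == "etd") c("c", "z") else c("b", "y")
  theo <- theoretical_fragments(
    spec$peptide, series = series, max_charge = 1,
    losses = names(constants$losses), table = table, constants = constants
  )
  sort(theo$mz)
}

#' Per-spectrum accuracy of a selection criterion
#'
#' Runs the merge module's selector on one annotated library spectrum and
#' reports the fraction of selected peaks that are real fragment ions.
#' Selected peaks are counted once per source peak. For `"comp_m"` /
#' `"comp_e"` only pairs in the corresponding position class contribute.
#'
#' @param spec A [library_spectrum()].
#' @param criterion One of `"aa"`, `"comp"`, `"comp_m"`, `"comp_e"`.
#' @param table,constants Residue table and constants.
#' @param theta Selection tolerance.
#' @param tolerance Real-ion annotation tolerance (defaults to `theta`).
#' @param sigma_mode Loss handling for complementarity, see
#'   [select_complementarity()].
#' @return A one-row tibble: `criterion`, `n_select`, `n_real`, `accuracy`
#'   (`NA` with `skipped = TRUE` when nothing was selected).
#' @export
spectrum_criterion_accuracy <- function(spec, criterion,
                                        table = amino_acid_table(),
                                        constants = mass_constants(),
                                        theta = 0.01, tolerance = theta,
                                        sigma_mode = "inferred") {
  criterion <- match.arg(criterion, c("aa", "comp", "comp_m", "comp_e"))
  .criterion_accuracies(spec, criterion, table, constants, theta, tolerance,
                        sigma_mode)
}

# All requested criterion accuracies from a single selector run (the
# selection is criterion-agnostic, so computing it once per spectrum is
# both faster and guarantees consistency across criteria).
.criterion_accuracies <- function(spec, criteria, table, constants, theta,
                                  tolerance, sigma_mode) {
  real <- annotate_real_ions(spec, table, constants, tolerance)
  sel <- .select_peaks(spec, table, constants, theta, sigma_mode)
  cm <- .comp_members(sel$comp)
  purrr::map_dfr(criteria, function(cr) {
    idx <- if (cr == "aa") {
      unique(sel$aa$source_index)
    } else if (cr == "comp_m") {
      unique(cm$source_index[cm$middle])
    } else if (cr == "comp_e") {
      unique(cm$source_index[!cm$middle])
    } else {
      unique(cm$source_index)
    }
    n_select <- length(idx)
    n_real <- sum(real[idx])
    tibble(
      criterion = cr, n_select = n_select, n_real = n_real,
      accuracy = if (n_select > 0) n_real / n_select else NA_real_,
      skipped = n_select == 0
    )
  })
}

#' Train a score model on an annotated spectral library
#'
#' The significance score of each criterion is the unweighted mean of the
#' per-spectrum accuracies over all spectra that selected at least one peak
#' for that criterion. HCD training produces the positional middle/end
#' split of the complementarity score; ETD training a single score.
#'
#' @param library A list of [library_spectrum()] objects, all of one mode.
#' @param mode `"hcd"` or `"etd"`.
#' @param table,constants,theta,tolerance,sigma_mode As in
#'   [spectrum_criterion_accuracy()].
#' @return A [score_model()].
#' @export
train_score_model <- function(library, mode,
                              table = amino_acid_table(),
                              constants = mass_constants(),
                              theta = 0.01, tolerance = theta,
                              sigma_mode = "inferred") {
  mode <- match.arg(tolower(mode), c("hcd", "etd"))
  if (length(library) == 0) {
    abort("Training library is empty.", class = "novopair_training_error")
  }
  criteria <- if (mode == "hcd") c("aa", "comp_m", "comp_e") else c("aa", "comp")
  acc <- purrr::map_dfr(library, function(sp) {
    .criterion_accuracies(sp, criteria, table, constants, theta, tolerance,
                          sigma_mode)
  })
  means <- acc |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(score = mean(.data$accuracy), n = dplyr::n(),
                     .groups = "drop")
  missing <- setdiff(criteria, means$criterion)
  if (length(missing) > 0) {
    abort(
      paste0("No library spectrum contributed to score(s): ",
             paste(missing, collapse = ", ")),
      class = "novopair_training_error"
    )
  }
  s <- stats::setNames(means$score, means$criterion)
  n <- stats::setNames(as.integer(means$n), means$criterion)
  params <- list(theta = theta, tolerance = tolerance,
                 losses = as.list(constants$losses), sigma_mode = sigma_mode,
                 mass_mode = constants$mode)
  if (mode == "hcd") {
    score_model("hcd", aa = s[["aa"]], comp_m = s[["comp_m"]],
                comp_e = s[["comp_e"]], n_spectra = n, params = params)
  } else {
    score_model("etd", aa = s[["aa"]], comp = s[["comp"]],
                n_spectra = n, params = params)
  }
}

#' Write / read a score model as JSON
#'
#' The JSON schema is versioned so trained models remain loadable.
#'
#' @param model A [score_model()].
#' @param path Output (input) path.
#' @return `path` invisibly (for the writer); a [score_model()] (reader).
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "novopair_score_model"))
  obj <- list(
    schema = "novopair-score-model/1",
    mode = model$mode,
    scores = as.list(model$scores),
    n_spectra = if (is.null(model$n_spectra)) NULL else as.list(model$n_spectra),
    params = model$params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !startsWith(obj$schema, "novopair-score-model")) {
    abort("Not a novopair score-model JSON file.",
          class = "novopair_config_error")
  }
  s <- obj$scores
  n <- if (!is.null(obj$n_spectra)) unlist(obj$n_spectra) else NULL
  if (obj$mode == "hcd") {
    score_model("hcd", aa = s$aa, comp_m = s$comp_m, comp_e = s$comp_e,
                n_spectra = n, params = as.list(obj$params))
  } else {
    score_model("etd", aa = s$aa, comp = s$comp,
                n_spectra = n, params = as.list(obj$params))
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score model
#'
#' @param x A [score_model()].
#' @param ... Unused.
#' @return One row per significance score: `criterion`, `estimate`,
#'   `n_spectra`.
#' @method tidy novopair_score_model
#' @export
tidy.novopair_score_model <- function(x, ...) {
  tibble(
    criterion = names(x$scores),
    estimate = unname(x$scores),
    n_spectra = if (is.null(x$n_spectra)) NA_integer_ else
      as.integer(x$n_spectra[names(x$scores)])
  )
}

#' @rdname tidy.novopair_score_model
#' @method glance novopair_score_model
#' @export
glance.novopair_score_model <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_scores = length(x$scores),
    theta = x$params$theta %||% NA_real_,
    tolerance = x$params$tolerance %||% NA_real_,
    mass_mode = x$params$mass_mode %||% NA_character_
  )
}
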