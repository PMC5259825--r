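# End-to-end driver: pair the input spectra, merge each pair with the
# trained score models, and sequence every pair. This is what the command
# line tool wraps.

#' Pipeline configuration
#'
#' Default parameter set of the method: selection threshold theta = 0.01 Da,
#' tag budget Sel = 10 per experimental spectrum, per-segment stop threshold
#' K = 10, and C = 3 output candidates per spectrum pair.
#'
#' @param theta Peak-selection / graph tolerance (Da).
#' @param sel Tag budget per source class.
#' @param K Per-segment stop threshold for path search.
#' @param C Candidates output per pair.
#' @param pair_tolerance Parent-mass tolerance when pairing spectra (Da).
#' @param mass_mode `"monoisotopic"`, or `"integer"` for the didactic
#'   integer-mass mode.
#' @param symmetric_weights Use the symmetric tag-weight variant?
#' @param sigma_mode Loss handling during merging ("inferred" or "free").
#' @return A list of class `novopair_config`.
#' @export
pipeline_config <- function(theta = 0.01, sel = 10, K = 10, C = 3,
                            pair_tolerance = 0.02,
                            mass_mode = "monoisotopic",
                            symmetric_weights = FALSE,
                            sigma_mode = "inferred") {
  stopifnot(theta > 0, sel >= 1, K >= 1, C >= 1, pair_tolerance > 0)
  structure(
    list(theta = theta, sel = sel, K = K, C = C,
         pair_tolerance = pair_tolerance, mass_mode = mass_mode,
         symmetric_weights = symmetric_weights, sigma_mode = sigma_mode),
    class = "novopair_config"
  )
}

#' Run the full sequencing pipeline
#'
#' Accepts either in-memory pairs or MGF paths. Per-pair failures are
#' reported and skipped; the run continues.
#'
#' @param pairs A list of [spectrum_pair()]s, or `NULL` to read from files.
#' @param hcd,etd MGF paths (used when `pairs` is `NULL`).
#' @param models List with `hcd` and `etd` [score_model()]s, or paths to
#'   model JSON files.
#' @param config A [pipeline_config()].
#' @return A tibble with one row per candidate: `pair_id`, `rank`,
#'   `sequence`, `score`, `n_gap`. A run report (counts of pairs, tags,
#'   candidates, failures) is attached as attribute `report`.
#' @export
run_pipeline <- function(pairs = NULL, hcd = NULL, etd = NULL, models,
                         config = pipeline_config()) {
  table <- amino_acid_table(config$mass_mode)
  constants <- mass_constants(config$mass_mode)
  if (is.character(models)) {
    models <- lapply(models, read_score_model)
    names(models) <- vapply(models, `[[`, "", "mode")
  }
  if (is.null(pairs)) {
    if (is.null(hcd) || is.null(etd)) {
      abort("Provide either `pairs` or both `hcd` and `etd` MGF paths.",
            class = "novopair_config_error")
    }
    hs <- read_mgf(hcd, mode = "hcd", constants = constants)
    es <- read_mgf(etd, mode = "etd", constants = constants)
    if (length(hs) == 0 || length(es) == 0) {
      abort("Input MGF file(s) contain no spectra.",
            class = "novopair_config_error")
    }
    pairs <- pair_spectra(hs, es, tolerance = config$pair_tolerance)
  }
  results <- vector("list", length(pairs))
  n_fail <- 0L
  for (i in seq_along(pairs)) {
    res <- tryCatch(
      sequence_pair(
        pairs[[i]], models, table, constants,
        theta = config$theta, sel = config$sel, K = config$K, C = config$C,
        symmetric_weights = config$symmetric_weights,
        sigma_mode = config$sigma_mode
      ),
      error = function(e) {
        inform(sprintf("Pair %d failed: %s", i, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      n_fail <- n_fail + 1L
      next
    }
    if (nrow(res) > 0) {
      res$pair_id <- pairs[[i]]$hcd$title %||% as.character(i)
      if (is.na(res$pair_id[1])) res$pair_id <- as.character(i)
      results[[i]] <- res[, c("pair_id", "rank", "sequence", "score", "n_gap")]
    }
  }
  out <- dplyr::bind_rows(results)
  if (nrow(out) == 0) {
    out <- tibble(pair_id = character(0), rank = integer(0),
                  sequence = character(0), score = numeric(0),
                  n_gap = integer(0))
  }
  attr(out, "report") <- list(
    n_pairs = length(pairs),
    n_pairs_with_candidates = length(unique(out$pair_id)),
    n_candidates = nrow(out),
    n_failed = n_fail
  )
  out
}

#' Write candidates as TSV
#'
#' @param candidates Output of [run_pipeline()] or a `novopair_candidates`
#'   tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  df <- as.data.frame(candidates[, setdiff(names(candidates), "vertex_ids")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
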