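# Tag-anchored sequencing: each selected tag is located in the spectrum
# graph under the ion-series interpretations compatible with its source
# spectra; the regions between the tag and the two termini are then searched
# for the K best partial paths each, and left path + tag + right path are
# assembled into full-length candidates ranked by their peak-score sum.

.candidate_cols <- function() {
  tibble(
    rank = integer(0), sequence = character(0), score = numeric(0),
    n_gap = integer(0), tag = character(0), tag_series = character(0),
    vertex_ids = list()
  )
}

# Locate one tag in the graph under one series interpretation.
# Returns NULL, or list(start_id, end_id, sequence, interior_ids).
.anchor_tag <- function(graph, tag_mz, tag_seq, series, constants, theta) {
  pref <- vapply(tag_mz, .prefix_of, 0, series = series,
                 m_p = graph$m_p, constants = constants)
  if (series %in% c("y", "z")) {
    pref <- rev(pref)
    tag_seq <- paste(rev(strsplit(tag_seq, "")[[1]]), collapse = "")
  }
  if (is.unsorted(pref, strictly = TRUE)) return(NULL)
  v <- graph$vertices
  ids <- vapply(pref, function(p) {
    d <- abs(v$prefix - p)
    j <- which.min(d)
    if (d[j] <= theta) v$id[j] else NA_integer_
  }, 0L)
  if (anyNA(ids) || any(duplicated(ids))) return(NULL)
  list(
    start_id = ids[1], end_id = ids[length(ids)], sequence = tag_seq,
    interior_ids = ids[-c(1, length(ids))]
  )
}

#' Assemble and rank full-length peptide candidates
#'
#' For every selected tag, anchors it in the graph under the ion-series
#' interpretations allowed by its source class (HCD tags as b or y, ETD as
#' c or z, mixed tags under all four), enumerates up to `K` best paths from
#' the source to the tag start and from the tag end to the sink, assembles
#' left path + tag + right path, validates the candidate mass against
#' `m_p`, and returns the `C` highest-scoring distinct sequences. The
#' candidate score `cs` is the sum of the significance scores of all
#' vertices on its path; ties break by fewer gap edges, then
#' lexicographically.
#'
#' @param graph A `novopair_graph` from [build_graph()].
#' @param tags A selected `novopair_tags` tibble ([select_tags()]).
#' @param table,constants Residue table and constants.
#' @param K Per-segment stop threshold ([enumerate_segment_paths()]).
#' @param C Number of candidates to output.
#' @param mass_tol Candidate-mass tolerance; defaults to
#'   `theta * (n residues + 1)`.
#' @return A tibble of class `novopair_candidates`: `rank`, `sequence`,
#'   `score`, `n_gap`, `tag`, `tag_series`, `vertex_ids` (list).
#' @export
assemble_and_rank <- function(graph, tags, table = amino_acid_table(),
                              constants = mass_constants(), K = 10, C = 3,
                              mass_tol = NULL) {
  theta <- graph$theta
  out <- .candidate_cols()
  if (nrow(tags) == 0) {
    class(out) <- c("novopair_candidates", class(out))
    return(out)
  }
  series_for <- function(cls) switch(cls, hcd = c("b", "y"),
                                     etd = c("c", "z"),
                                     c("b", "y", "c", "z"))
  rows <- list()
  for (i in seq_len(nrow(tags))) {
    tag_mz <- tags$mz[[i]]
    for (sr in series_for(tags$mode_class[i])) {
      anch <- .anchor_tag(graph, tag_mz, tags$sequence[i], sr, constants,
                          theta)
      if (is.null(anch)) next
      left <- enumerate_segment_paths(graph, graph$source_id, anch$start_id, K)
      right <- enumerate_segment_paths(graph, anch$end_id, graph$sink_id, K)
      if (nrow(left) == 0 || nrow(right) == 0) next
      interior_score <- sum(graph$vertices$score[
        match(anch$interior_ids, graph$vertices$id)])
      for (a in seq_len(nrow(left))) {
        for (b in seq_len(nrow(right))) {
          seqc <- paste0(left$sequence[a], anch$sequence, right$sequence[b])
          rows[[length(rows) + 1L]] <- tibble(
            sequence = seqc,
            score = left$score[a] + interior_score + right$score[b],
            n_gap = left$n_gap[a] + right$n_gap[b],
            tag = tags$sequence[i], tag_series = sr,
            vertex_ids = list(c(left$vertex_ids[[a]], anch$interior_ids,
                                right$vertex_ids[[b]]))
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    inform("No tag could be anchored; no candidates produced.")
    class(out) <- c("novopair_candidates", class(out))
    return(out)
  }
  cand <- dplyr::bind_rows(rows)
  # mass validation
  tol <- mass_tol %||% (theta * (nchar(cand$sequence) + 1))
  pm <- vapply(cand$sequence, peptide_mass, 0, table = table,
               constants = constants)
  cand <- cand[abs(pm - graph$m_p) <= tol, , drop = FALSE]
  if (nrow(cand) == 0) {
    inform("No mass-valid candidate assembly.")
    class(out) <- c("novopair_candidates", class(out))
    return(out)
  }
  cand <- cand |>
    dplyr::arrange(dplyr::desc(.data$score), .data$n_gap, .data$sequence) |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE) |>
    dplyr::slice_head(n = C)
  cand$rank <- seq_len(nrow(cand))
  cand <- cand[, c("rank", "sequence", "score", "n_gap", "tag",
                   "tag_series", "vertex_ids")]
  class(cand) <- c("novopair_candidates", class(cand))
  cand
}

#' Sequence one HCD/ETD spectrum pair end to end
#'
#' Merge, tag generation/extension/scoring/selection, graph construction
#' and candidate assembly in one call.
#'
#' @param pair A [spectrum_pair()].
#' @param models List with `hcd` and `etd` [score_model()]s.
#' @param table,constants Residue table and constants.
#' @param theta Selection/graph tolerance (Da).
#' @param sel Tag budget per source class.
#' @param K Per-segment stop threshold.
#' @param C Number of output candidates.
#' @param symmetric_weights Use the symmetric tag-weight variant?
#' @param sigma_mode Loss handling during merging.
#' @return A `novopair_candidates` tibble (possibly empty).
#' @export
sequence_pair <- function(pair, models, table = amino_acid_table(),
                          constants = mass_constants(), theta = 0.01,
                          sel = 10, K = 10, C = 3,
                          symmetric_weights = FALSE,
                          sigma_mode = "inferred") {
  merged <- merge_pair(pair, models, table, constants, theta, sigma_mode)
  tags <- generate_tags(merged, table, theta) |>
    extend_tags(theta) |>
    score_tags(symmetric = symmetric_weights) |>
    select_tags(sel = sel)
  if (nrow(tags) == 0) {
    out <- .candidate_cols()
    class(out) <- c("novopair_candidates", class(out))
    return(out)
  }
  graph <- build_graph(merged, pair$parent_mass, table, constants, theta)
  assemble_and_rank(graph, tags, table, constants, K = K, C = C)
}

#' Collapse isobaric residues for sequence comparison
#'
#' Maps residues indistinguishable by mass to a canonical letter (I to L),
#' so candidate/truth comparisons are mass-fair.
#'
#' @param sequence Character vector of peptide strings.
#' @return Canonicalized strings.
#' @export
canonical_sequence <- function(sequence) {
  gsub("I", "L", sequence, fixed = TRUE)
}
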