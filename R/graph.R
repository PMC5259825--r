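# Spectrum graph over the merged spectrum, in N-terminal prefix-mass space.
# Every scored peak spawns prefix interpretations according to its source
# mode (HCD: b and y; ETD: c and z); interpretations within theta coalesce
# into one vertex whose score is the sum of the distinct contributing
# peaks' scores. Edges connect vertices whose prefix difference reads as one
# residue (residue edge) or as a 2-3 residue mass sum (gap edge). Peptides
# are source-to-sink paths.

# Prefix-mass interpretation of a charge-1 m/z under one ion series.
.prefix_of <- function(mz, series, m_p, constants) {
  switch(series,
    b = mz - constants$m_H,
    y = m_p + constants$m_H - mz,
    c = mz - constants$m_H - constants$nh3,
    z = m_p + 2 * constants$m_H - constants$nh3 - mz
  )
}

# All 2- and 3-residue mass sums with a deterministic (alphabetical) label.
.gap_sums <- function(table) {
  lk <- .residue_lookup(table)
  n <- length(lk$mass)
  two <- expand.grid(i = seq_len(n), j = seq_len(n))
  two <- two[two$i <= two$j, ]
  g2 <- tibble(
    mass = lk$mass[two$i] + lk$mass[two$j],
    label = paste0(lk$label[two$i], lk$label[two$j])
  )
  three <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  three <- three[three$i <= three$j & three$j <= three$k, ]
  g3 <- tibble(
    mass = lk$mass[three$i] + lk$mass[three$j] + lk$mass[three$k],
    label = paste0(lk$label[three$i], lk$label[three$j], lk$label[three$k])
  )
  g <- dplyr::bind_rows(g2, g3)
  g <- g[order(g$mass, g$label), ]
  g[!duplicated(g$mass), ]
}

#' Build the spectrum graph from a merged spectrum
#'
#' @param merged A `novopair_merged` tibble from [merge_pair()].
#' @param m_p Neutral parent peptide mass (defaults to the merged
#'   spectrum's `m_p` attribute).
#' @param table,constants Residue table and constants.
#' @param theta Tolerance for vertex coalescing and edge matching (Da).
#' @return An object of class `novopair_graph`: list with `vertices`
#'   (tibble `id`, `prefix`, `score`), `edges` (tibble `from`, `to`, `type`,
#'   `label`, `mass`), `source_id`, `sink_id`, `m_p`, `residue_sum`,
#'   `theta`.
#' @export
build_graph <- function(merged, m_p = attr(merged, "m_p"),
                        table = amino_acid_table(),
                        constants = mass_constants(), theta = 0.01) {
  if (is.null(m_p)) abort("m_p is required (attribute missing).")
  R <- m_p - constants$water
  min_res <- min(table$mass)

  interp <- NULL
  if (nrow(merged) > 0) {
    modes <- if ("mode" %in% names(merged)) merged$mode else "both"
    series_of <- function(m) switch(m, hcd = c("b", "y"), etd = c("c", "z"),
                                    c("b", "y", "c", "z"))
    interp <- purrr::map_dfr(seq_len(nrow(merged)), function(i) {
      sr <- series_of(modes[i])
      tibble(
        peak = i, series = sr,
        prefix = vapply(sr, function(s) {
          .prefix_of(merged$mz[i], s, m_p, constants)
        }, 0),
        score = merged$ss[i]
      )
    })
    keep <- interp$prefix >= min_res - theta & interp$prefix <= R - min_res + theta
    interp <- interp[keep, , drop = FALSE]
  }

  verts <- tibble(prefix = c(0, R), score = c(0, 0), peak = c(NA, NA))
  if (!is.null(interp) && nrow(interp) > 0) {
    interp <- interp[order(interp$prefix), , drop = FALSE]
    cl <- cumsum(c(TRUE, diff(interp$prefix) > theta))
    clustered <- interp |>
      dplyr::mutate(cluster = cl) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::group_modify(function(df, key) {
        # one contribution per distinct merged peak in the cluster
        tibble(
          score = sum(vapply(split(df$score, df$peak), max, 0)),
          prefix = stats::weighted.mean(df$prefix, df$score)
        )
      }) |>
      dplyr::ungroup()
    verts <- dplyr::bind_rows(
      tibble(prefix = 0, score = 0, peak = NA),
      tibble(prefix = clustered$prefix, score = clustered$score, peak = NA),
      tibble(prefix = R, score = 0, peak = NA)
    )
  }
  verts <- verts[order(verts$prefix), c("prefix", "score")]
  # a peak interpretation may coincide with a terminus; drop near-duplicates
  dup <- c(FALSE, diff(verts$prefix) <= theta)
  if (any(dup)) {
    cl <- cumsum(!dup)
    verts <- verts |>
      dplyr::mutate(cluster = cl) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(prefix = .data$prefix[1], score = sum(.data$score),
                       .groups = "drop") |>
      dplyr::select(-"cluster")
  }
  verts$id <- seq_len(nrow(verts))
  vertices <- verts[, c("id", "prefix", "score")]
  source_id <- vertices$id[which.min(abs(vertices$prefix - 0))]
  sink_id <- vertices$id[which.min(abs(vertices$prefix - R))]
  # termini carry no peak evidence
  vertices$score[c(source_id, sink_id)] <- 0

  lk <- .residue_lookup(table)
  gaps <- .gap_sums(table)
  edges <- list()
  n <- nrow(vertices)
  for (i in seq_len(max(n - 1, 0))) {
    d <- vertices$prefix[(i + 1):n] - vertices$prefix[i]
    ri <- which(.near_any(d, lk$mass, theta))
    for (j in ri) {
      m <- .closest_match(d[j], lk$mass, theta)
      edges[[length(edges) + 1L]] <- tibble(
        from = vertices$id[i], to = vertices$id[i + j],
        type = "residue", label = lk$label[m], mass = d[j]
      )
    }
    gi <- which(.near_any(d, gaps$mass, theta) & !.near_any(d, lk$mass, theta))
    for (j in gi) {
      m <- .closest_match(d[j], gaps$mass, theta)
      edges[[length(edges) + 1L]] <- tibble(
        from = vertices$id[i], to = vertices$id[i + j],
        type = "gap", label = gaps$label[m], mass = d[j]
      )
    }
  }
  edges <- if (length(edges) > 0) dplyr::bind_rows(edges) else
    tibble(from = integer(0), to = integer(0), type = character(0),
           label = character(0), mass = numeric(0))

  structure(
    list(
      vertices = vertices, edges = edges,
      source_id = source_id, sink_id = sink_id,
      m_p = m_p, residue_sum = R, theta = theta
    ),
    class = "novopair_graph"
  )
}

#' @export
print.novopair_graph <- function(x, ...) {
  cat(sprintf(
    "<novopair_graph> %d vertices, %d edges (%d residue, %d gap), m_p=%.4f\n",
    nrow(x$vertices), nrow(x$edges), sum(x$edges$type == "residue"),
    sum(x$edges$type == "gap"), x$m_p
  ))
  invisible(x)
}

# Deterministic total order on (score desc, gaps asc, sequence, id string).
.path_order <- function(score, gaps, seq, ids) {
  order(-score, gaps, seq, ids)
}

#' Enumerate the K best paths of one graph segment
#'
#' Exact top-K enumeration of paths from vertex `from` to vertex `to`,
#' ranked by the sum of vertex scores along the path (both endpoints
#' included), ties broken deterministically (fewer gap edges, then
#' lexicographic sequence, then vertex ids). Implemented as a top-K dynamic
#' program over the prefix-ordered DAG, so the returned paths are exactly
#' the K best among all paths.
#'
#' @param graph A `novopair_graph`.
#' @param from,to Vertex ids delimiting the segment (`from` upstream).
#' @param K Stop threshold: maximum number of paths returned.
#' @return A tibble with one row per path: `sequence` (edge labels
#'   concatenated; gap-edge labels contribute their residue multiset),
#'   `score`, `n_gap`, `vertex_ids` (list). Zero rows when the segment is
#'   disconnected.
#' @export
enumerate_segment_paths <- function(graph, from, to, K = 10) {
  stopifnot(inherits(graph, "novopair_graph"), K >= 1)
  v <- graph$vertices
  if (!from %in% v$id || !to %in% v$id) {
    abort("Anchor vertices not present in graph.")
  }
  p_from <- v$prefix[v$id == from]
  p_to <- v$prefix[v$id == to]
  if (p_from > p_to) abort("`from` must lie upstream of `to`.")

  if (from == to) {
    return(tibble(
      sequence = "", score = v$score[v$id == from], n_gap = 0L,
      vertex_ids = list(from)
    ))
  }

  ids <- v$id[v$prefix >= p_from - 1e-12 & v$prefix <= p_to + 1e-12]
  ids <- ids[order(v$prefix[match(ids, v$id)], ids)]
  e <- graph$edges[graph$edges$from %in% ids & graph$edges$to %in% ids, ]

  # partial paths per vertex, truncated to the K best under the total order
  part <- stats::setNames(vector("list", length(ids)), as.character(ids))
  part[[as.character(from)]] <- tibble(
    sequence = "", score = v$score[v$id == from], n_gap = 0L,
    ids_str = as.character(from), vertex_ids = list(from)
  )
  for (vid in ids) {
    cur <- part[[as.character(vid)]]
    if (is.null(cur) || nrow(cur) == 0) next
    o <- .path_order(cur$score, cur$n_gap, cur$sequence, cur$ids_str)
    cur <- cur[o[seq_len(min(K, length(o)))], ]
    part[[as.character(vid)]] <- cur
    out_e <- e[e$from == vid, ]
    for (r in seq_len(nrow(out_e))) {
      nxt <- as.character(out_e$to[r])
      ext <- cur
      ext$sequence <- paste0(cur$sequence, out_e$label[r])
      ext$score <- cur$score + v$score[v$id == out_e$to[r]]
      ext$n_gap <- cur$n_gap + as.integer(out_e$type[r] == "gap")
      ext$ids_str <- paste(cur$ids_str, out_e$to[r])
      ext$vertex_ids <- lapply(cur$vertex_ids, function(x) c(x, out_e$to[r]))
      part[[nxt]] <- dplyr::bind_rows(part[[nxt]], ext)
    }
  }
  res <- part[[as.character(to)]]
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(sequence = character(0), score = numeric(0),
                  n_gap = integer(0), vertex_ids = list()))
  }
  o <- .path_order(res$score, res$n_gap, res$sequence, res$ids_str)
  res <- res[o[seq_len(min(K, length(o)))], ]
  tibble(sequence = res$sequence, score = res$score, n_gap = res$n_gap,
         vertex_ids = res$vertex_ids)
}
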