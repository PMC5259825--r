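# Random-DAG fixtures in the spectrum graph's internal representation, plus
# an exhaustive path oracle. Used by the graph unit tests and the search
# correctness checks.

mk_graph <- function(prefix, score, edges, m_p = max(prefix) + 18.010565,
                     theta = 0.01) {
  v <- tibble::tibble(id = seq_along(prefix), prefix = prefix, score = score)
  structure(
    list(vertices = v, edges = edges, source_id = 1L,
         sink_id = length(prefix), m_p = m_p,
         residue_sum = max(prefix), theta = theta),
    class = "novopair_graph"
  )
}

rand_dag <- function(seed, n) {
  withr::with_seed(seed, {
    prefix <- sort(stats::runif(n, 0, 1000))
    prefix[1] <- 0
    score <- c(0, round(stats::runif(n - 2), 3), 0)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < 0.35
    pairs <- pairs[keep, , drop = FALSE]
    edges <- tibble::tibble(
      from = pairs[, 1], to = pairs[, 2],
      type = sample(c("residue", "gap"), nrow(pairs), replace = TRUE),
      label = sample(LETTERS[1:6], nrow(pairs), replace = TRUE),
      mass = prefix[pairs[, 2]] - prefix[pairs[, 1]]
    )
    mk_graph(prefix, score, edges)
  })
}

# independent oracle: depth-first enumeration of every path from `from` to
# `to`, with the total vertex score and gap count of each
all_paths <- function(g, from, to) {
  res <- list()
  walk <- function(v, ids, score, gaps) {
    if (v == to) {
      res[[length(res) + 1L]] <<- list(score = score, gaps = gaps, ids = ids)
      return()
    }
    out <- g$edges[g$edges$from == v, ]
    for (r in seq_len(nrow(out))) {
      w <- out$to[r]
      walk(w, c(ids, w), score + g$vertices$score[w],
           gaps + (out$type[r] == "gap"))
    }
  }
  walk(from, from, g$vertices$score[from], 0L)
  res
}
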