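# Sequence tags: short stretches of sequence read directly from consecutive
# peak mass differences on the merged spectrum. Base tags are three residues
# (four supporting peaks); tags overlapping by two residues and by their
# supporting peaks are merged into longer tags until a fixed point.

# Unique residue-mass lookup with canonical labels (I/L -> "L"; exact
# integer-mode ties such as K/Q = 128 resolve alphabetically).
.residue_lookup <- function(table) {
  sp <- split(table$residue, table$mass)
  mass <- as.numeric(names(sp))
  label <- vapply(sp, function(r) if ("L" %in% r) "L" else sort(r)[1], "")
  o <- order(mass)
  list(mass = mass[o], label = unname(label)[o])
}

.empty_tags <- function() {
  out <- tibble(
    sequence = character(0), length = integer(0), s_t = numeric(0),
    mode_class = character(0), peak_idx = list(), mz = list(), ss = list()
  )
  class(out) <- c("novopair_tags", class(out))
  out
}

.tag_mode_class <- function(modes) {
  h <- sum(modes %in% c("hcd", "both"))
  e <- sum(modes %in% c("etd", "both"))
  if (h > e) "hcd" else if (e > h) "etd" else "mixed"
}

#' Generate length-3 sequence tags from a merged spectrum
#'
#' Every chain of four peaks `P1 < P2 < P3 < P4` whose three consecutive m/z
#' differences each match a residue mass within `theta` yields one tag.
#' Residues indistinguishable by mass are reported canonically (I/L as "L").
#'
#' @param merged A `novopair_merged` tibble (from [merge_pair()]), or any
#'   tibble with columns `mz`, `ss` and optionally `mode`.
#' @param table Residue table.
#' @param theta Matching tolerance in Da.
#' @return A `novopair_tags` tibble: `sequence`, `length`, `s_t` (NA until
#'   [score_tags()]), `mode_class`, and list columns `peak_idx`, `mz`, `ss`.
#' @export
generate_tags <- function(merged, table = amino_acid_table(), theta = 0.01) {
  mz <- merged$mz
  ss <- merged$ss
  modes <- if ("mode" %in% names(merged)) merged$mode else
    rep(NA_character_, length(mz))
  p <- length(mz)
  if (p < 4) return(.empty_tags())
  lk <- .residue_lookup(table)

  # successor lists: j > i with a residue-mass difference
  succ <- vector("list", p)
  lab <- vector("list", p)
  for (i in seq_len(p - 1)) {
    d <- mz[(i + 1):p] - mz[i]
    hit <- which(.near_any(d, lk$mass, theta))
    succ[[i]] <- i + hit
    lab[[i]] <- vapply(d[hit], function(x) {
      lk$label[.closest_match(x, lk$mass, theta)]
    }, "")
  }

  rows <- list()
  for (i1 in seq_len(p)) {
    s1 <- succ[[i1]]
    for (a in seq_along(s1)) {
      i2 <- s1[a]
      s2 <- succ[[i2]]
      for (b in seq_along(s2)) {
        i3 <- s2[b]
        s3 <- succ[[i3]]
        for (cc in seq_along(s3)) {
          i4 <- s3[cc]
          idx <- c(i1, i2, i3, i4)
          rows[[length(rows) + 1L]] <- list(
            sequence = paste0(lab[[i1]][a], lab[[i2]][b], lab[[i3]][cc]),
            idx = idx
          )
        }
      }
    }
  }
  if (length(rows) == 0) return(.empty_tags())
  out <- tibble(
    sequence = vapply(rows, `[[`, "", "sequence"),
    length = 3L,
    s_t = NA_real_,
    mode_class = vapply(rows, function(r) .tag_mode_class(modes[r$idx]), ""),
    peak_idx = lapply(rows, `[[`, "idx"),
    mz = lapply(rows, function(r) mz[r$idx]),
    ss = lapply(rows, function(r) ss[r$idx])
  )
  out <- out[!duplicated(paste(out$sequence,
                               vapply(out$peak_idx, paste, "", collapse = ","))), ]
  class(out) <- c("novopair_tags", class(out))
  out
}

#' Extend tags by two-residue overlap
#'
#' A tag whose last two residues and last three supporting peaks coincide
#' (peak m/z within `theta`) with the first two residues / first three peaks
#' of a length-3 tag grows by one residue; newly created tags are added to
#' the set and the process repeats until no new tag can be formed. The
#' result is independent of merge order.
#'
#' @param tags A `novopair_tags` tibble (from [generate_tags()]).
#' @param theta Peak-match tolerance in Da.
#' @return The enlarged `novopair_tags` tibble.
#' @export
extend_tags <- function(tags, theta = 0.01) {
  if (nrow(tags) == 0) return(tags)
  base3 <- tags[tags$length == 3L, , drop = FALSE]
  if (nrow(base3) == 0) return(tags)

  key_of <- function(seq, mzs) paste(seq, paste(round(mzs, 6), collapse = ","))
  seen <- new.env(parent = emptyenv())
  all_rows <- lapply(seq_len(nrow(tags)), function(i) tags[i, , drop = FALSE])
  for (r in all_rows) assign(key_of(r$sequence, r$mz[[1]]), TRUE, envir = seen)

  b3_head2 <- substr(base3$sequence, 1, 2)
  frontier <- all_rows
  while (length(frontier) > 0) {
    new_rows <- list()
    for (ta in frontier) {
      la <- ta$length
      tail2 <- substr(ta$sequence, la - 1, la)
      amz <- ta$mz[[1]]
      cand <- which(b3_head2 == tail2)
      for (j in cand) {
        bmz <- base3$mz[[j]]
        if (all(abs(amz[(la - 1):(la + 1)] - bmz[1:3]) <= theta)) {
          nseq <- paste0(ta$sequence, substr(base3$sequence[j], 3, 3))
          nmz <- c(amz, bmz[4])
          k <- key_of(nseq, nmz)
          if (!exists(k, envir = seen, inherits = FALSE)) {
            assign(k, TRUE, envir = seen)
            nr <- ta
            nr$sequence <- nseq
            nr$length <- la + 1L
            nr$peak_idx <- list(c(ta$peak_idx[[1]], base3$peak_idx[[j]][4]))
            nr$mz <- list(nmz)
            nr$ss <- list(c(ta$ss[[1]], base3$ss[[j]][4]))
            nr$mode_class <- if (ta$mode_class == base3$mode_class[j])
              ta$mode_class else "mixed"
            new_rows[[length(new_rows) + 1L]] <- nr
          }
        }
      }
    }
    all_rows <- c(all_rows, new_rows)
    frontier <- new_rows
  }
  out <- dplyr::bind_rows(all_rows)
  class(out) <- unique(c("novopair_tags", class(out)))
  out
}

# Eq.-style positional weights for the l-th of l_t + 1 supporting peaks.
.tag_weights <- function(lt, symmetric = FALSE) {
  l <- seq_len(lt + 1)
  if (symmetric) {
    1 + 0.1 * pmin(l - 1, lt + 1 - l)
  } else {
    1 + 0.1 * pmin(l, lt - l)
  }
}

#' Score tags from their supporting-peak scores
#'
#' The tag score is the weighted mean of its `l_t + 1` supporting-peak
#' significance scores, with position weights `1 + 0.1 * min(l, l_t - l)`
#' (the published form; its end weights are asymmetric). With
#' `symmetric = TRUE` the weight is `1 + 0.1 * min(l - 1, l_t + 1 - l)`,
#' which down-weights both termini equally.
#'
#' @param tags A `novopair_tags` tibble.
#' @param symmetric Use the symmetric weight variant?
#' @return The same tibble with `s_t` filled in.
#' @export
score_tags <- function(tags, symmetric = FALSE) {
  if (nrow(tags) == 0) return(tags)
  tags$s_t <- vapply(seq_len(nrow(tags)), function(i) {
    ss <- tags$ss[[i]]
    w <- .tag_weights(tags$length[i], symmetric)
    mean(ss * w)
  }, 0)
  tags
}

#' Select the top-ranked tags
#'
#' Tags are ranked by `s_t` (ties: longer tag first, then lexicographic) and
#' the best `sel` are kept — per source-spectrum class (`hcd` / `etd` /
#' `mixed`) when `per_mode = TRUE`, mirroring a per-experimental-spectrum
#' tag budget.
#'
#' @param tags A scored `novopair_tags` tibble.
#' @param sel Number of tags to keep (per class).
#' @param per_mode Apply the budget per mode class?
#' @return The selected `novopair_tags` tibble, ranked.
#' @export
select_tags <- function(tags, sel = 10, per_mode = TRUE) {
  if (nrow(tags) == 0) return(tags)
  if (any(is.na(tags$s_t))) tags <- score_tags(tags)
  out <- dplyr::arrange(tags, dplyr::desc(.data$s_t),
                        dplyr::desc(.data$length), .data$sequence)
  if (per_mode) {
    out <- out |>
      dplyr::group_by(.data$mode_class) |>
      dplyr::slice_head(n = sel) |>
      dplyr::ungroup() |>
      dplyr::arrange(dplyr::desc(.data$s_t), dplyr::desc(.data$length),
                     .data$sequence)
  } else {
    out <- dplyr::slice_head(out, n = sel)
  }
  class(out) <- unique(c("novopair_tags", class(out)))
  out
}
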