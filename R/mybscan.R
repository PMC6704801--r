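AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Build a position-specific scoring model for a MYB repeat
#'
#' Estimates a log-odds position-specific scoring matrix (PSSM) from a
#' gap-free seed alignment of repeat sequences. The score of residue `r`
#' at position `p` is
#' `log2((count[p,r] + pseudocount * background[r]) / (n + pseudocount) / background[r])`
#' in bits, so a column matching the background scores ~0 and the model is
#' deterministic for a fixed seed alignment.
#'
#' @param seed_alignment Character vector of >= 2 equal-length, gap-free
#'   repeat sequences (rows of the seed alignment).
#' @param background Named numeric vector of background residue
#'   frequencies over the 20 amino acids (positive, summing to 1).
#'   Default is uniform.
#' @param pseudocount Pseudocount multiplier on the background (default
#'   0.5), avoiding -Inf scores on small seeds.
#' @param score_threshold Bit-score threshold used by [scan_repeats()].
#'   Defaults to 25% of the maximum attainable window score; see
#'   [calibrate_threshold()] for an empirical-null alternative.
#' @return An object of class `repeat_profile` with elements `L`, `pssm`
#'   (L x 20 matrix), `background`, `pseudocount` and `score_threshold`.
#' @export
build_profile <- function(seed_alignment, background = NULL, pseudocount = 0.5,
                          score_threshold = NULL) {
  if (length(seed_alignment) < 2) abort("seed alignment needs at least 2 rows")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1) abort("seed alignment rows have unequal lengths")
  L <- lens[1]
  if (L < 1) abort("seed alignment is empty")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA20)
  }
  background <- background[AA20]
  if (any(is.na(background)) || any(background <= 0)) {
    abort("background must assign a positive frequency to all 20 residues")
  }
  background <- background / sum(background)
  rows <- do.call(rbind, strsplit(seed_alignment, ""))
  if (any(!rows %in% AA20)) {
    abort("seed alignment contains non-standard residues or gaps")
  }
  counts <- vapply(
    seq_len(L),
    function(p) tabulate(factor(rows[, p], levels = AA20), nbins = 20),
    numeric(20)
  )
  counts <- t(counts) # L x 20
  colnames(counts) <- AA20
  n <- length(seed_alignment)
  freq <- sweep(counts, 2, pseudocount * background, `+`) / (n + pseudocount)
  pssm <- log2(sweep(freq, 2, background, `/`))
  if (is.null(score_threshold)) {
    score_threshold <- 0.25 * sum(apply(pssm, 1, max))
  }
  structure(
    list(
      L = L, pssm = pssm, background = background,
      pseudocount = pseudocount, score_threshold = score_threshold
    ),
    class = "repeat_profile"
  )
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat(
    "<repeat_profile> length", x$L, "residues, threshold",
    round(x$score_threshold, 2), "bits\n"
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.repeat_profile <- function(x, ...) {
  as_tibble(x$pssm) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "residue", values_to = "score")
}

#' @exportS3Method generics::glance
glance.repeat_profile <- function(x, ...) {
  tibble(
    length = x$L,
    score_threshold = x$score_threshold,
    max_score = sum(apply(x$pssm, 1, max))
  )
}

# integer-encode a protein over AA20; non-standard residues (X) get NA and
# score 0 in any window containing them
encode_protein <- function(seq) {
  match(strsplit(seq, "")[[1]], AA20)
}

window_scores <- function(enc, pssm) {
  L <- nrow(pssm)
  n <- length(enc)
  if (n < L) return(numeric(0))
  starts <- seq_len(n - L + 1)
  vapply(starts, function(s) {
    idx <- enc[s:(s + L - 1)]
    sc <- pssm[cbind(seq_len(L), idx)]
    sum(sc, na.rm = TRUE)
  }, numeric(1))
}

#' Calibrate a scan threshold on a shuffle null
#'
#' Shuffles each protein `n_shuffles` times, records the maximum window
#' score of each shuffle, and returns the requested quantile of that
#' empirical null of per-protein maxima. A threshold at the `q`-th
#' quantile leaves a shuffled (repeat-free) protein hit-free with
#' probability ~`q`.
#'
#' @param seqs A data frame with columns `id` and `seq`, or a single
#'   sequence string.
#' @param profile A [build_profile()] object.
#' @param n_shuffles Number of shuffles per protein.
#' @param q Quantile of the null distribution of per-shuffle maxima.
#' @param seed Seed for the shuffle stream.
#' @return Threshold in bits.
#' @export
calibrate_threshold <- function(seqs, profile, n_shuffles = 1000, q = 0.999,
                                seed = 1) {
  if (is.character(seqs)) seqs <- tibble(id = "q", seq = seqs)
  withr::with_seed(seed, {
    maxima <- unlist(lapply(seqs$seq, function(s) {
      enc <- encode_protein(s)
      vapply(seq_len(n_shuffles), function(i) {
        sc <- window_scores(sample(enc), profile$pssm)
        if (length(sc) == 0) -Inf else max(sc)
      }, numeric(1))
    }))
  })
  unname(stats::quantile(maxima, q, type = 7))
}

#' Scan proteins for MYB repeats
#'
#' Scores every length-`L` window of each protein against the profile and
#' keeps windows at or above the bit-score threshold by greedy
#' non-overlapping selection (descending score, ties to the leftmost
#' start). Surviving repeats are indexed left to right. Adjacent repeats
#' separated by more than `max_gap` residues fall into separate tandem
#' clusters; the `cluster` column marks each repeat's cluster and
#' [classify_family()] counts only the largest cluster. Proteins shorter
#' than `L` yield no repeats; windows never extend past either terminus.
#'
#' @param seqs A data frame with columns `id` and `seq` (see
#'   [read_fasta()]).
#' @param profile A [build_profile()] object.
#' @param max_gap Maximum residue gap between adjacent repeats of one
#'   tandem cluster (default 30).
#' @param score_threshold Optional override of `profile$score_threshold`.
#' @return A tibble with columns `protein_id`, `start`, `end` (0-based
#'   half-open residue coordinates), `score`, `repeat_index` and
#'   `cluster`.
#' @export
scan_repeats <- function(seqs, profile, max_gap = 30, score_threshold = NULL) {
  stopifnot(inherits(profile, "repeat_profile"))
  thr <- score_threshold %||% profile$score_threshold
  L <- profile$L
  res <- purrr::map2(seqs$id, seqs$seq, function(id, s) {
    sc <- window_scores(encode_protein(s), profile$pssm)
    cand <- which(sc >= thr)
    if (length(cand) == 0) return(NULL)
    # greedy selection: descending score, leftmost start on ties
    ord <- cand[order(-sc[cand], cand)]
    taken <- integer(0)
    for (s0 in ord) {
      if (!any(abs(taken - s0) < L)) taken <- c(taken, s0)
    }
    taken <- sort(taken)
    gaps <- c(0, taken[-1] - (head(taken, -1) + L))
    tibble(
      protein_id = id,
      start = taken - 1L,
      end = taken - 1L + L,
      score = sc[taken],
      repeat_index = seq_along(taken),
      cluster = cumsum(gaps > max_gap) + 1L
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      protein_id = character(), start = integer(), end = integer(),
      score = numeric(), repeat_index = integer(), cluster = integer()
    )
  }
  out
}

#' Classify proteins into MYB subfamilies by repeat count
#'
#' The subfamily is a pure function of the repeat count of the largest
#' tandem cluster: 0 repeats is `none`, 1 is `1R`, 2 is `R2R3`, 3 is
#' `3R`, and 4 or more is `4R`.
#'
#' @param repeats Output of [scan_repeats()].
#' @param protein_ids Optional character vector of all scanned proteins,
#'   so proteins without repeats receive an explicit `none` call.
#' @return A tibble with columns `protein_id`, `n_repeats`, `subfamily`.
#' @export
classify_family <- function(repeats, protein_ids = NULL) {
  counts <- if (nrow(repeats) == 0) {
    tibble(protein_id = character(), n_repeats = integer())
  } else {
    repeats |>
      count(.data$protein_id, .data$cluster, name = "k") |>
      group_by(.data$protein_id) |>
      summarise(n_repeats = max(.data$k), .groups = "drop")
  }
  if (!is.null(protein_ids)) {
    counts <- tibble(protein_id = protein_ids) |>
      left_join(counts, by = "protein_id") |>
      mutate(n_repeats = ifelse(is.na(.data$n_repeats), 0L, .data$n_repeats))
  }
  mutate(counts, subfamily = subfamily_label(.data$n_repeats))
}

subfamily_label <- function(n) {
  dplyr::case_when(
    n <= 0 ~ "none",
    n == 1 ~ "1R",
    n == 2 ~ "R2R3",
    n == 3 ~ "3R",
    TRUE ~ "4R"
  )
}

#' Per-column conservation statistics for a repeat alignment
#'
#' Computes, for each alignment column, the residue frequencies, the
#' modal residue and its frequency, and the information content
#' `IC = log2(20) - H` in bits, where `H` is the Shannon entropy of the
#' observed column frequencies (no small-sample correction). Gap and `X`
#' characters are excluded from a column's frequency vector.
#'
#' @param repeat_alignment Character vector of equal-length aligned
#'   repeat sequences.
#' @return An object of class `conservation_profile`: a tibble with
#'   columns `position`, `modal_residue`, `modal_freq`, `ic`, plus a
#'   `freq` attribute holding the position x residue frequency matrix.
#' @export
logo_stats <- function(repeat_alignment) {
  if (length(repeat_alignment) == 0) abort("empty alignment")
  lens <- nchar(repeat_alignment)
  if (length(unique(lens)) != 1) abort("alignment rows have unequal lengths")
  L <- lens[1]
  rows <- do.call(rbind, strsplit(repeat_alignment, ""))
  freq <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA20))
  stat <- purrr::map(seq_len(L), function(p) {
    col <- rows[, p]
    col <- col[col %in% AA20]
    if (length(col) == 0) abort(paste0("column ", p, " has no standard residues"))
    f <- tabulate(factor(col, levels = AA20), nbins = 20) / length(col)
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    list(
      f = f,
      row = tibble(
        position = p,
        modal_residue = AA20[which.max(f)],
        modal_freq = max(f),
        ic = log2(20) - h
      )
    )
  })
  for (p in seq_len(L)) freq[p, ] <- stat[[p]]$f
  out <- bind_rows(purrr::map(stat, "row"))
  attr(out, "freq") <- freq
  attr(out, "n_seqs") <- length(repeat_alignment)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.conservation_profile <- function(x, ...) {
  freq <- attr(x, "freq")
  as_tibble(freq) |>
    mutate(position = row_number()) |>
    tidyr::pivot_longer(-"position", names_to = "residue", values_to = "freq") |>
    filter(.data$freq > 0)
}

#' @exportS3Method generics::glance
glance.conservation_profile <- function(x, ...) {
  tibble(
    n_seqs = attr(x, "n_seqs"),
    length = nrow(x),
    mean_ic = mean(x$ic),
    max_ic = max(x$ic)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.conservation_profile <- function(object, ...) {
  df <- as_tibble(unclass(object)[c("position", "modal_residue", "ic")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$modal_residue),
      vjust = -0.3, size = 2.8
    ) +
    ggplot2::ylim(0, log2(20) * 1.08) +
    ggplot2::labs(
      x = "alignment position", y = "information content (bits)",
      title = "Repeat conservation profile"
    ) +
    ggplot2::theme_minimal()
}
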