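#' Filter marker anchors to a jointly monotone subset
#'
#' Real genetic maps contain local inversions, so per chromosome the
#' anchors used for interpolation are reduced to the longest subsequence
#' that is strictly increasing in physical position when ordered by
#' genetic position. Dropped markers are reported via a message.
#'
#' @param anchors A data frame with columns `marker_id`, `chrom`, `cm`,
#'   `bp`.
#' @return The filtered anchor tibble, ordered by `chrom`, `cm`.
#' @export
filter_anchors <- function(anchors) {
  out <- anchors |>
    as_tibble() |>
    arrange(.data$chrom, .data$cm, .data$bp) |>
    group_by(.data$chrom) |>
    filter(row_number() %in% lis_indices(.data$bp)) |>
    ungroup()
  dropped <- setdiff(anchors$marker_id, out$marker_id)
  if (length(dropped) > 0) {
    inform(paste0(
      "dropped ", length(dropped), " non-monotone anchor(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  out
}

# indices of a longest strictly increasing subsequence (O(n^2); maps are small)
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  idx <- integer(0)
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  idx
}

#' Anchor genetic positions to physical coordinates
#'
#' Piecewise-linear interpolation of cM positions between the two
#' bracketing anchors on a chromosome; queries outside the anchored
#' range are clamped to the nearest anchor's bp. Anchors are first
#' reduced to a jointly monotone subset (see [filter_anchors()]).
#'
#' @param anchors A marker-anchor table (`marker_id`, `chrom`, `cm`,
#'   `bp`).
#' @param chrom Chromosome of the queries.
#' @param cm Numeric vector of genetic positions to anchor.
#' @return Numeric vector of interpolated physical positions (bp).
#' @export
anchor_to_bp <- function(anchors, chrom, cm) {
  a <- filter(filter_anchors(anchors), .data$chrom == !!chrom)
  if (nrow(a) < 2) {
    abort(paste0("need at least 2 monotone anchors on chromosome '", chrom, "'"))
  }
  approx(a$cm, a$bp, xout = cm, rule = 2, ties = "ordered")$y
}

#' Detect same-trait QTL hotspots on a genetic map
#'
#' For each trait x chromosome, QTL peak positions are sorted and a
#' candidate window `[peak, peak + window]` is anchored at every peak.
#' Windows holding at least `min_count` peaks are kept; overlapping kept
#' windows of the same trait are merged (so a merged hotspot may span
#' more than one window), and the reported interval is the min-max range
#' of member peaks. When only a support interval is given, the peak is
#' its midpoint. Hotspot ids follow the `FL_Hotspot_c5` pattern, with an
#' ordinal `_k` suffix when one trait has several hotspots on a
#' chromosome.
#'
#' @param qtls A QTL table with columns `qtl_id`, `trait`, `chrom` and
#'   `cm` (or `cm_start`/`cm_end`).
#' @param window Window width in cM (default 20).
#' @param min_count Minimum number of same-trait QTL per window (default
#'   4).
#' @return A tibble of class `hotspot_set`: `hotspot_id`, `trait`,
#'   `chrom`, `cm_lo`, `cm_hi`, `qtl_count` and a `members` list-column
#'   of member QTL ids.
#' @export
detect_hotspots <- function(qtls, window = 20, min_count = 4) {
  empty <- tibble(
    hotspot_id = character(), trait = character(), chrom = character(),
    cm_lo = numeric(), cm_hi = numeric(), qtl_count = integer(),
    members = list()
  )
  if (nrow(qtls) == 0) return(new_hotspot_set(empty, window, min_count))
  qtls <- as_tibble(qtls)
  if (!"cm" %in% names(qtls)) qtls$cm <- NA_real_
  if (all(c("cm_start", "cm_end") %in% names(qtls))) {
    qtls <- mutate(qtls, cm = ifelse(
      is.na(.data$cm), (.data$cm_start + .data$cm_end) / 2, .data$cm
    ))
  }
  if (any(is.na(qtls$cm))) abort("every QTL needs a cm peak or a cm_start/cm_end interval")
  res <- qtls |>
    arrange(.data$trait, .data$chrom, .data$cm, .data$qtl_id) |>
    group_by(.data$trait, .data$chrom) |>
    dplyr::group_map(function(g, key) {
      hs <- windowed_clusters(g$cm, window, min_count)
      if (length(hs) == 0) return(NULL)
      bind_rows(lapply(hs, function(idx) {
        tibble(
          trait = key$trait, chrom = key$chrom,
          cm_lo = min(g$cm[idx]), cm_hi = max(g$cm[idx]),
          qtl_count = length(idx), members = list(g$qtl_id[idx])
        )
      }))
    }) |>
    bind_rows()
  if (nrow(res) == 0) return(new_hotspot_set(empty, window, min_count))
  res <- res |>
    group_by(.data$trait, .data$chrom) |>
    mutate(
      hotspot_id = if (n() == 1) {
        paste0(.data$trait, "_Hotspot_", .data$chrom)
      } else {
        paste0(.data$trait, "_Hotspot_", .data$chrom, "_", row_number())
      }
    ) |>
    ungroup() |>
    select(
      "hotspot_id", "trait", "chrom", "cm_lo", "cm_hi", "qtl_count", "members"
    ) |>
    arrange(.data$chrom, .data$cm_lo, .data$trait)
  new_hotspot_set(res, window, min_count)
}

# given sorted peak positions, return index sets of merged qualifying windows
windowed_clusters <- function(cm, window, min_count) {
  n <- length(cm)
  kept <- list()
  for (i in seq_len(n)) {
    idx <- which(cm >= cm[i] & cm <= cm[i] + window)
    if (length(idx) >= min_count) kept[[length(kept) + 1]] <- idx
  }
  if (length(kept) == 0) return(list())
  # merge overlapping index sets
  merged <- list(kept[[1]])
  for (k in kept[-1]) {
    last <- merged[[length(merged)]]
    if (length(intersect(last, k)) > 0) {
      merged[[length(merged)]] <- sort(union(last, k))
    } else {
      merged[[length(merged) + 1]] <- k
    }
  }
  merged
}

new_hotspot_set <- function(df, window, min_count) {
  attr(df, "window") <- window
  attr(df, "min_count") <- min_count
  class(df) <- c("hotspot_set", class(df))
  df
}

#' Anchor hotspot intervals to physical coordinates
#'
#' Interpolates each hotspot's cM interval to bp via [anchor_to_bp()].
#' The resulting `[bp_lo, bp_hi)` interval is half-open.
#'
#' @param hotspots A [detect_hotspots()] result.
#' @param anchors A marker-anchor table.
#' @return `hotspots` with added `bp_lo` and `bp_hi` columns; hotspots on
#'   chromosomes absent from the anchors are dropped with a message.
#' @export
anchor_hotspots <- function(hotspots, anchors) {
  anchored_chroms <- unique(anchors$chrom)
  off <- filter(hotspots, !.data$chrom %in% anchored_chroms)
  if (nrow(off) > 0) {
    inform(paste0(
      "dropping ", nrow(off), " hotspot(s) on unanchored chromosome(s): ",
      paste(unique(off$chrom), collapse = ", ")
    ))
  }
  hs <- filter(hotspots, .data$chrom %in% anchored_chroms)
  out <- hs |>
    group_by(.data$chrom) |>
    mutate(
      bp_lo = anchor_to_bp(anchors, .data$chrom[1], .data$cm_lo),
      bp_hi = anchor_to_bp(anchors, .data$chrom[1], .data$cm_hi)
    ) |>
    ungroup()
  new_hotspot_set(out, attr(hotspots, "window"), attr(hotspots, "min_count"))
}

#' Co-localize genes with anchored hotspot intervals
#'
#' Half-open interval overlap of gene `[start, end)` with hotspot
#' `[bp_lo, bp_hi)` on the same chromosome: a gene whose end equals a
#' hotspot's start does not overlap it. A gene may join several
#' hotspots; genes on chromosomes with no anchored hotspot chromosome
#' set are reported as unplaced and excluded.
#'
#' @param genes A gene-model table (`gene_id`, `chrom`, `start`, `end`;
#'   0-based half-open, see [read_gene_models()]).
#' @param hotspots An [anchor_hotspots()] result (with `bp_lo`/`bp_hi`).
#' @param anchors Optional marker-anchor table defining which
#'   chromosomes are placeable; defaults to the hotspot chromosomes.
#' @return A tibble with one row per gene x hotspot overlap
#'   (`gene_id`, `chrom`, `start`, `end`, `hotspot_id`, `trait`), sorted
#'   by `chrom`, `start`; unplaced gene ids are attached as the
#'   `"unplaced"` attribute.
#' @export
colocalize <- function(genes, hotspots, anchors = NULL) {
  if (!all(c("bp_lo", "bp_hi") %in% names(hotspots))) {
    abort("hotspots must be anchored first (see anchor_hotspots())")
  }
  placeable <- if (is.null(anchors)) unique(hotspots$chrom) else unique(anchors$chrom)
  unplaced <- unique(genes$gene_id[!genes$chrom %in% placeable])
  if (length(unplaced) > 0) {
    inform(paste0(length(unplaced), " gene(s) on unplaced chromosomes/scaffolds excluded"))
  }
  g <- filter(as_tibble(genes), .data$chrom %in% placeable)
  hits <- g |>
    dplyr::inner_join(
      select(as_tibble(hotspots), "hotspot_id", "trait", "chrom", "bp_lo", "bp_hi"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    filter(.data$start < .data$bp_hi, .data$bp_lo < .data$end) |>
    select("gene_id", "chrom", "start", "end", "hotspot_id", "trait") |>
    arrange(.data$chrom, .data$start, .data$hotspot_id)
  attr(hits, "unplaced") <- unplaced
  hits
}

#' Write anchored hotspots as BED6
#'
#' Emits `chrom`, half-open `[bp_lo, bp_hi)`, the hotspot id, the QTL
#' count as score, and `.` strand.
#'
#' @param hotspots An [anchor_hotspots()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  rows <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t.",
    hotspots$chrom, as.integer(round(hotspots$bp_lo)),
    as.integer(round(hotspots$bp_hi)), hotspots$hotspot_id,
    hotspots$qtl_count
  )
  writeLines(rows, path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hotspot_set <- function(object, qtls = NULL, ...) {
  p <- ggplot2::ggplot(object)
  if (!is.null(qtls)) {
    p <- p + ggplot2::geom_point(
      data = qtls,
      ggplot2::aes(x = .data$cm, y = .data$trait),
      shape = 3, colour = "grey50"
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$cm_lo, xend = .data$cm_hi,
        y = .data$trait, yend = .data$trait, colour = .data$trait
      ),
      linewidth = 3, alpha = 0.6
    ) +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "genetic position (cM)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
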