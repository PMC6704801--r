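#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching columns among pairwise-comparable columns.
#' Columns where either sequence carries a gap (`-`) or ambiguity
#' (`X`/`N`) are excluded pairwise.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return Mismatch proportion in `[0, 1]`.
#' @export
#' @examples
#' p_distance("A-AA", "AGAT") # gap column dropped -> 1/3
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("aligned sequences differ in length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  skip <- c("-", "X", "N", ".")
  ok <- !(ca %in% skip) & !(cb %in% skip)
  if (!any(ok)) abort("no comparable columns between the two sequences")
  mean(ca[ok] != cb[ok])
}

#' Pairwise p-distance matrix for a set of aligned sequences
#'
#' @param seqs A data frame with columns `id` and `seq` (all sequences
#'   aligned to the same length).
#' @return A symmetric numeric matrix with zero diagonal, dimnames taken
#'   from `id`.
#' @export
p_distance_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- p_distance(seqs$seq[i], seqs$seq[j])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted tree by the Saitou-Nei neighbor-joining
#' agglomeration. Negative branch-length estimates are clamped to zero
#' with the deficit transferred to the sister branch, so reported lengths
#' stay interpretable while leaf-to-leaf path lengths are preserved
#' around the affected node. For two taxa the single edge is split
#' equally.
#'
#' @param d A symmetric non-negative distance matrix with labeled rows
#'   and columns (or a `dist` object).
#' @return An [ape::phylo] tree (serializable with [ape::write.tree()]).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (nrow(d) < 2) abort("need at least 2 taxa")
  if (any(is.na(d))) abort("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-12) abort("distance matrix is not symmetric")
  if (any(d < 0)) abort("distance matrix has negative entries")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 2) {
    tr <- ape::read.tree(text = sprintf(
      "(%s:%f,%s:%f);", rownames(d)[1], d[1, 2] / 2, rownames(d)[2], d[1, 2] / 2
    ))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clamp_negative_edges(tr)
}

# set negative edge lengths to 0 and add the deficit to the sister edge
# (the other child edge of the same parent node)
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0) {
      s <- sibs[1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
      if (tr$edge.length[s] < 0) tr$edge.length[s] <- 0
    }
  }
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Optional clade-support resampling: alignment columns are resampled
#' with replacement `n_boot` times, the p-distance NJ tree is rebuilt on
#' each pseudo-alignment, and clade support counts are attached as node
#' labels of the reference tree. Fully seeded and off the main analysis
#' path (supports are not used downstream).
#'
#' @param seqs A data frame with columns `id` and `seq`, aligned to a
#'   common length.
#' @param n_boot Number of bootstrap pseudo-alignments (default 100).
#' @param seed Seed for the resampling stream.
#' @return The NJ tree on the full alignment with `node.label` holding
#'   bootstrap support counts (out of `n_boot`).
#' @export
nj_bootstrap <- function(seqs, n_boot = 100, seed = 1) {
  ref <- nj_tree(p_distance_matrix(seqs))
  chars <- do.call(rbind, strsplit(seqs$seq, ""))
  L <- ncol(chars)
  boots <- withr::with_seed(seed, {
    purrr::map(seq_len(n_boot), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- tibble(
        id = seqs$id,
        seq = apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      )
      tryCatch(nj_tree(p_distance_matrix(res)), error = function(e) NULL)
    })
  })
  boots <- boots[!vapply(boots, is.null, logical(1))]
  ref$node.label <- ape::prop.clades(ref, boots, rooted = FALSE)
  ref
}

#' Assign queries to annotated subgroups by nearest reference
#'
#' Each query receives the subgroup label of its nearest labeled
#' reference, unless that distance exceeds `cutoff`, in which case the
#' query is called lineage-specific (`"G-S"`). Ties are broken by the
#' lexicographically smallest reference id.
#'
#' @param distances A data frame with columns `query_id`, `reference_id`
#'   and `distance`.
#' @param references A data frame with columns `reference_id` and
#'   `subgroup`.
#' @param cutoff Maximum distance at which a reference label is copied
#'   (default 0.6).
#' @return A tibble with columns `query_id`, `subgroup`,
#'   `nearest_reference_id`, `distance`.
#' @export
assign_subgroup <- function(distances, references, cutoff = 0.6) {
  if (nrow(references) == 0) abort("empty reference set")
  stopifnot(
    all(c("query_id", "reference_id", "distance") %in% names(distances)),
    all(c("reference_id", "subgroup") %in% names(references))
  )
  distances |>
    dplyr::semi_join(references, by = "reference_id") |>
    arrange(.data$query_id, .data$distance, .data$reference_id) |>
    group_by(.data$query_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    left_join(references, by = "reference_id") |>
    mutate(subgroup = ifelse(.data$distance > cutoff, "G-S", .data$subgroup)) |>
    select(
      "query_id", "subgroup",
      nearest_reference_id = "reference_id", "distance"
    )
}
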