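# Independent oracles used by the unit and acceptance tests. These are
# deliberately written with a different structure than the package code
# (table-driven lookups, hardcoded permutations, exhaustive search) so they
# can act as cross-checks.

GC <- Biostrings::GENETIC_CODE
SLOTS <- c("a2", "d5", "at_ad1", "dt_ad1", "at_ad2", "dt_ad2")

# ---- scenario oracle: absent-set lookup table --------------------------------
oracle_scenario <- function(present) {
  absent <- paste(SLOTS[!present[SLOTS]], collapse = "+")
  if (absent == "") return("RETAINED_ALL")
  table <- c(
    "at_ad1" = "LOSS_ONE_SUBGENOME_AD1",
    "dt_ad1" = "LOSS_ONE_SUBGENOME_AD1",
    "at_ad2" = "LOSS_ONE_SUBGENOME_AD2",
    "dt_ad2" = "LOSS_ONE_SUBGENOME_AD2",
    "at_ad1+dt_ad1" = "LOSS_BOTH_SUBGENOMES_AD1",
    "at_ad2+dt_ad2" = "LOSS_BOTH_SUBGENOMES_AD2",
    "a2" = "LOSS_DIPLOID_ONLY",
    "d5" = "LOSS_DIPLOID_ONLY",
    "a2+d5" = "LOSS_DIPLOID_ONLY",
    "a2+at_ad1" = "LOSS_SUBGENOME_AND_PROGENITOR",
    "a2+at_ad2" = "LOSS_SUBGENOME_AND_PROGENITOR",
    "d5+dt_ad1" = "LOSS_SUBGENOME_AND_PROGENITOR",
    "d5+dt_ad2" = "LOSS_SUBGENOME_AND_PROGENITOR"
  )
  if (absent %in% names(table)) unname(table[absent]) else "OTHER"
}

# turn a named logical presence vector into a one-row group tibble
pattern_group <- function(present, id = "g") {
  vals <- ifelse(present[SLOTS], "gene", NA_character_)
  out <- as.list(stats::setNames(vals, SLOTS))
  out$group_id <- id
  tibble::as_tibble(out)
}

# ---- NG86 oracle: exhaustive enumeration with hardcoded permutations ---------
oracle_syn_sites <- function(codon) {
  aa <- GC[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (base in c("A", "C", "G", "T")) {
      if (base == substr(codon, pos, pos)) next
      mut <- paste0(
        substr(codon, 1, pos - 1), base, substr(codon, pos + 1, 3)
      )
      if (GC[[mut]] == aa) syn <- syn + 1
    }
  }
  syn / 3
}

hard_perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
)

oracle_pair_diffs <- function(ca, cb) {
  dpos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(dpos)
  if (k == 0) return(c(sd = 0, nd = 0))
  acc_s <- c()
  acc_n <- c()
  for (ord in hard_perms[[as.character(k)]]) {
    path <- ca
    steps_s <- 0
    steps_n <- 0
    valid <- TRUE
    for (step in dpos[ord]) {
      nxt <- paste0(
        substr(path, 1, step - 1), substr(cb, step, step),
        substr(path, step + 1, 3)
      )
      if (GC[[nxt]] == "*" && nxt != cb) {
        valid <- FALSE
        break
      }
      if (GC[[path]] == GC[[nxt]]) steps_s <- steps_s + 1 else steps_n <- steps_n + 1
      path <- nxt
    }
    if (valid) {
      acc_s <- c(acc_s, steps_s)
      acc_n <- c(acc_n, steps_n)
    }
  }
  if (length(acc_s) == 0) return(c(sd = 0, nd = k))
  c(sd = mean(acc_s), nd = mean(acc_n))
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, 1)) + sum(vapply(cb, oracle_syn_sites, 1))) / 2
  d <- vapply(seq_along(ca), function(i) oracle_pair_diffs(ca[i], cb[i]), numeric(2))
  list(S = S, N = 3 * length(ca) - S, Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

# ---- NJ oracle: brute-force topology search with least-squares fit -----------
# for each candidate unrooted topology, fit branch lengths by ordinary least
# squares on leaf-pair path indicators; an additive matrix fits exactly on a
# unique topology
tree_design_matrix <- function(tr) {
  n <- length(tr$tip.label)
  pairs <- utils::combn(n, 2)
  X <- matrix(0, ncol(pairs), nrow(tr$edge))
  for (p in seq_len(ncol(pairs))) {
    nodes <- ape::nodepath(tr, pairs[1, p], pairs[2, p])
    for (s in seq_len(length(nodes) - 1)) {
      e <- which(
        (tr$edge[, 1] == nodes[s] & tr$edge[, 2] == nodes[s + 1]) |
          (tr$edge[, 1] == nodes[s + 1] & tr$edge[, 2] == nodes[s])
      )
      X[p, e] <- 1
    }
  }
  X
}

oracle_best_topology <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  cands <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pairs <- utils::combn(n, 2)
  dvec <- d[cbind(
    match(taxa[pairs[1, ]], taxa), match(taxa[pairs[2, ]], taxa)
  )]
  best <- NULL
  best_rss <- Inf
  for (i in seq_along(cands)) {
    tr <- cands[[i]] # [[ restores tip labels from the multiPhylo attribute
    X <- tree_design_matrix(tr)
    beta <- qr.coef(qr(X), dvec)
    beta[is.na(beta)] <- 0
    rss <- sum((X %*% beta - dvec)^2)
    if (rss < best_rss) {
      best_rss <- rss
      tr$edge.length <- as.numeric(beta)
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}

# random unrooted tree with positive branch lengths and its additive matrix
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1)))
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
    list(tree = tr, d = d)
  })
}
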