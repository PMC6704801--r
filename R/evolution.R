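ORTHOLOG_SLOTS <- c("a2", "d5", "at_ad1", "dt_ad1", "at_ad2", "dt_ad2")

SCENARIO_LEVELS <- c(
  "RETAINED_ALL",
  "LOSS_ONE_SUBGENOME_AD1", "LOSS_ONE_SUBGENOME_AD2",
  "LOSS_BOTH_SUBGENOMES_AD1", "LOSS_BOTH_SUBGENOMES_AD2",
  "LOSS_DIPLOID_ONLY", "LOSS_SUBGENOME_AND_PROGENITOR", "OTHER"
)

# label one presence pattern: named logical over ORTHOLOG_SLOTS
scenario_label <- function(p) {
  p <- p[ORTHOLOG_SLOTS]
  if (!any(p)) abort("ortholog group with all slots absent")
  absent <- ORTHOLOG_SLOTS[!p]
  tet <- c("at_ad1", "dt_ad1", "at_ad2", "dt_ad2")
  if (length(absent) == 0) return("RETAINED_ALL")
  if (length(absent) == 1 && absent %in% tet) {
    return(paste0("LOSS_ONE_SUBGENOME_", toupper(sub("^.t_", "", absent))))
  }
  if (setequal(absent, c("at_ad1", "dt_ad1"))) return("LOSS_BOTH_SUBGENOMES_AD1")
  if (setequal(absent, c("at_ad2", "dt_ad2"))) return("LOSS_BOTH_SUBGENOMES_AD2")
  if (all(absent %in% c("a2", "d5"))) return("LOSS_DIPLOID_ONLY")
  pairs <- list(
    c("a2", "at_ad1"), c("a2", "at_ad2"),
    c("d5", "dt_ad1"), c("d5", "dt_ad2")
  )
  if (length(absent) == 2 && any(vapply(pairs, setequal, logical(1), absent))) {
    return("LOSS_SUBGENOME_AND_PROGENITOR")
  }
  "OTHER"
}

#' Classify ortholog presence/absence patterns into gene-loss scenarios
#'
#' Each ortholog group spans six genome roles: the diploid progenitors
#' (`a2`, `d5`) and the A/D subgenome copies of the two allotetraploids
#' (`at_ad1`, `dt_ad1`, `at_ad2`, `dt_ad2`). A slot is present when it
#' holds a non-missing, non-empty gene id. The fixed decision table is:
#' all six present is `RETAINED_ALL`; exactly one tetraploid subgenome
#' copy absent (its progenitor necessarily present) is
#' `LOSS_ONE_SUBGENOME_AD1`/`_AD2`; both subgenome copies of one
#' tetraploid absent with everything else present is
#' `LOSS_BOTH_SUBGENOMES_AD1`/`_AD2`; only diploid slot(s) absent with
#' all four tetraploid copies present is `LOSS_DIPLOID_ONLY`; exactly one
#' subgenome copy plus its corresponding progenitor absent is
#' `LOSS_SUBGENOME_AND_PROGENITOR`; every other pattern is `OTHER`.
#'
#' @param groups A data frame with a `group_id` column and the six slot
#'   columns (gene id or `NA`).
#' @return `groups` with an added `scenario` column.
#' @export
classify_scenarios <- function(groups) {
  missing_cols <- setdiff(ORTHOLOG_SLOTS, names(groups))
  if (length(missing_cols) > 0) {
    abort(paste0("missing slot column(s): ", paste(missing_cols, collapse = ", ")))
  }
  pres <- presence_matrix(groups)
  lab <- vapply(seq_len(nrow(groups)), function(i) scenario_label(pres[i, ]), character(1))
  mutate(as_tibble(groups), scenario = lab)
}

presence_matrix <- function(groups) {
  m <- vapply(
    ORTHOLOG_SLOTS,
    function(s) !is.na(groups[[s]]) & as.character(groups[[s]]) != "",
    logical(nrow(groups))
  )
  matrix(m, nrow = nrow(groups), dimnames = list(NULL, ORTHOLOG_SLOTS))
}

#' Summarise gene losses across a set of ortholog groups
#'
#' A group counts as a lost pair for a tetraploid when at least one of
#' its two subgenome slots is absent (a group missing both subgenome
#' copies still counts once). Also reports the per-scenario histogram,
#' whose counts sum to the number of groups.
#'
#' @param groups A data frame of ortholog groups (see
#'   [classify_scenarios()]).
#' @return An object of class `loss_summary` with elements `species`
#'   (tibble: `species`, `lost_groups`), `scenarios` (tibble: `scenario`,
#'   `n`) and `n_groups`.
#' @export
count_losses <- function(groups) {
  if (nrow(groups) == 0) abort("empty ortholog group list")
  cls <- classify_scenarios(groups)
  pres <- presence_matrix(groups)
  species <- tibble(
    species = c("AD1", "AD2"),
    lost_groups = c(
      sum(!pres[, "at_ad1"] | !pres[, "dt_ad1"]),
      sum(!pres[, "at_ad2"] | !pres[, "dt_ad2"])
    )
  )
  scen <- cls |>
    count(scenario = factor(.data$scenario, levels = SCENARIO_LEVELS),
          name = "n", .drop = FALSE) |>
    mutate(scenario = as.character(.data$scenario))
  structure(
    list(species = species, scenarios = scen, n_groups = nrow(groups)),
    class = "loss_summary"
  )
}

#' @export
print.loss_summary <- function(x, ...) {
  cat("<loss_summary>", x$n_groups, "ortholog groups\n")
  cat(sprintf(
    "  lost pairs: AD1 = %d, AD2 = %d\n",
    x$species$lost_groups[1], x$species$lost_groups[2]
  ))
  print(filter(x$scenarios, .data$n > 0))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.loss_summary <- function(x, ...) x$scenarios

#' @exportS3Method generics::glance
glance.loss_summary <- function(x, ...) {
  tibble(
    n_groups = x$n_groups,
    lost_ad1 = x$species$lost_groups[1],
    lost_ad2 = x$species$lost_groups[2]
  )
}

## ---- Nei-Gojobori (1986) dN/dS ----

GENETIC_CODE <- Biostrings::GENETIC_CODE

codon_split <- function(cds, which_arg) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    abort(paste0(which_arg, " length ", nchar(cds), " is not a multiple of 3"))
  }
  if (grepl("[^ACGT]", cds)) abort(paste0(which_arg, " contains non-ACGT characters"))
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  stops <- which(GENETIC_CODE[codons] == "*")
  if (length(stops) > 0) {
    abort(paste0(which_arg, " has internal stop codon at codon ", stops[1]))
  }
  codons
}

# fraction of synonymous one-step changes per codon (summed over the three
# positions); changes to stop codons count as nonsynonymous, so the
# synonymous + nonsynonymous site counts always total 3 per codon
syn_sites_codon <- function(codon) {
  aa <- GENETIC_CODE[[codon]]
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(c("A", "C", "G", "T"), ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways passing through a stop codon are
# excluded, and if every pathway does, the raw differences count as
# nonsynonymous
codon_pair_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  orders <- perms(pos)
  tot_s <- 0
  tot_n <- 0
  n_valid <- 0
  for (ord in orders) {
    cur <- ca
    s <- 0
    n <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (GENETIC_CODE[[nxt]] == "*" && nxt != cb) {
        ok <- FALSE
        break
      }
      if (GENETIC_CODE[[cur]] == GENETIC_CODE[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) {
      tot_s <- tot_s + s
      tot_n <- tot_n + n
      n_valid <- n_valid + 1
    }
  }
  if (n_valid == 0) return(c(sd = 0, nd = k))
  c(sd = tot_s / n_valid, nd = tot_n / n_valid)
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) {
    warn(paste0("proportion ", signif(p, 3), " exceeds the Jukes-Cantor correctable range"))
    return(NA_real_)
  }
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences; mutations to stop codons count as nonsynonymous, so
#' sites total three per codon) and observed differences averaged over
#' all minimal mutational pathways at multi-hit codons, excluding
#' pathways through stop codons. Proportions are Jukes-Cantor corrected
#' (`d = -3/4 * log(1 - 4p/3)`) and `omega = dN/dS`. The selection call
#' is `purifying` for `omega < 1`, `positive` for `omega > 1`, `neutral`
#' at exactly 1, and `undefined` when `dS = 0` (including identical
#' sequences).
#'
#' @param cds_a,cds_b In-frame coding sequences of equal length (multiple
#'   of 3, A/C/G/T only, no internal stop codons).
#' @return A one-row tibble with columns `n_codons`, `N`, `S`, `Nd`,
#'   `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, `selection`.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) abort("coding sequences differ in length")
  codons_a <- codon_split(cds_a, "cds_a")
  codons_b <- codon_split(cds_b, "cds_b")
  nc <- length(codons_a)
  s_a <- sum(vapply(codons_a, syn_sites_codon, numeric(1)))
  s_b <- sum(vapply(codons_b, syn_sites_codon, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * nc - S
  diffs <- vapply(
    seq_len(nc),
    function(i) codon_pair_diffs(codons_a[i], codons_b[i]),
    numeric(2)
  )
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  selection <- if (is.na(omega)) {
    "undefined"
  } else if (omega < 1) {
    "purifying"
  } else if (omega > 1) "positive" else "neutral"
  tibble(
    n_codons = nc, N = N, S = S, Nd = Nd, Sd = Sd,
    pN = pN, pS = pS, dN = dN, dS = dS,
    omega = omega, selection = selection
  )
}

#' dN/dS for a table of sequence pairs
#'
#' @param pairs A data frame with columns `pair_id`, `cds_a`, `cds_b`
#'   and any annotation columns (e.g. `subgenome`), all preserved.
#' @return One [ng86_dnds()] row per pair, bound to the input columns
#'   other than the sequences.
#' @export
dnds_pairs <- function(pairs) {
  res <- bind_rows(purrr::map2(pairs$cds_a, pairs$cds_b, ng86_dnds))
  dplyr::bind_cols(
    select(as_tibble(pairs), -dplyr::any_of(c("cds_a", "cds_b"))),
    res
  )
}

#' Median dN/dS by subgenome
#'
#' Summarises the distribution of `omega` per subgenome, the statistic
#' used to describe asymmetric evolution of the A and D subgenomes.
#'
#' @param dnds A data frame with columns `subgenome` and `omega`.
#' @return A tibble with `subgenome`, `n`, `median_omega`.
#' @export
subgenome_asymmetry <- function(dnds) {
  dnds |>
    filter(!is.na(.data$omega)) |>
    group_by(.data$subgenome) |>
    summarise(n = n(), median_omega = median(.data$omega), .groups = "drop")
}

#' Reciprocal-best-hit ortholog pairing on p-distance
#'
#' Convenience builder pairing sequences from two genomes when each is
#' the other's nearest neighbour by [p_distance()]. Orthology input for
#' the scenario analysis is normally supplied, not computed.
#'
#' @param seqs_a,seqs_b Data frames with columns `id` and `seq` (aligned
#'   to a common length).
#' @return A tibble with columns `id_a`, `id_b`, `distance`.
#' @export
rbh_pairs <- function(seqs_a, seqs_b) {
  d <- matrix(0, nrow(seqs_a), nrow(seqs_b), dimnames = list(seqs_a$id, seqs_b$id))
  for (i in seq_len(nrow(seqs_a))) {
    for (j in seq_len(nrow(seqs_b))) {
      d[i, j] <- p_distance(seqs_a$seq[i], seqs_b$seq[j])
    }
  }
  best_b <- apply(d, 1, which.min)
  best_a <- apply(d, 2, which.min)
  keep <- which(best_a[best_b] == seq_len(nrow(seqs_a)))
  tibble(
    id_a = seqs_a$id[keep],
    id_b = seqs_b$id[best_b[keep]],
    distance = d[cbind(keep, best_b[keep])]
  )
}
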