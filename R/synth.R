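#' Synthetic-data generators
#'
#' Every generator is a pure function of its seed and arguments: the same
#' call is byte-identical on rerun, and each generator draws from its own
#' substream derived from the seed, so adding one generator never
#' perturbs another's output. Each returns the tables the pipeline
#' consumes plus a truth table sufficient to score downstream recovery.
#'
#' @name synth
NULL

# per-generator substream so generators never share a random stream
substream_seed <- function(seed, name) {
  offsets <- c(
    repeat_family = 1L, proteome = 2L, qtl_map = 3L, bil = 4L,
    allele_matrix = 5L, ortholog = 6L, codon = 7L
  )
  (as.integer(seed) %% 190000L) * 10007L + offsets[[name]] * 131L
}

#' Consensus MYB repeat used by the generators
#'
#' A fixed 53-residue helix-turn-helix repeat consensus with the
#' regularly spaced tryptophans characteristic of MYB DNA-binding
#' repeats.
#'
#' @return A 53-character string.
#' @export
myb_consensus <- function() {
  "LKKGPWTPEEDEILVDYIQKHGHGNWRALPKLAGLLRCGKSCRLRWTNYLRPD"
}

mutate_repeat <- function(consensus, sub_rate) {
  chars <- strsplit(consensus, "")[[1]]
  hit <- stats::runif(length(chars)) < sub_rate
  if (any(hit)) {
    chars[hit] <- vapply(
      chars[hit],
      function(r) sample(setdiff(AA20, r), 1),
      character(1)
    )
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Generate a seed alignment of MYB-like repeats
#'
#' Samples repeats from the consensus with independent per-position
#' substitutions.
#'
#' @param n_repeats Number of rows.
#' @param consensus Consensus repeat string.
#' @param sub_rate Per-position substitution probability (default 0.1).
#' @param seed Seed (mandatory).
#' @return Character vector of equal-length repeat sequences.
#' @export
gen_repeat_family <- function(n_repeats = 30, consensus = myb_consensus(),
                              sub_rate = 0.1, seed) {
  withr::with_seed(substream_seed(seed, "repeat_family"), {
    vapply(seq_len(n_repeats), function(i) mutate_repeat(consensus, sub_rate),
           character(1))
  })
}

#' Generate a synthetic proteome with planted MYB repeats
#'
#' A fraction of proteins carry `k` tandem repeats sampled from the
#' consensus (per-position substitution rate `sub_rate`) at recorded
#' offsets, separated by short gaps; the remaining proteins are i.i.d.
#' draws from the background residue distribution.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param family_fraction Fraction carrying planted repeats (default
#'   0.3).
#' @param repeat_count_probs Distribution of repeat counts for family
#'   proteins, names "1".."4" (default heavily favouring two repeats,
#'   the R2R3 architecture).
#' @param sub_rate Per-position substitution rate of planted repeats.
#' @param consensus Consensus repeat.
#' @param gap_range Integer range of residues between adjacent repeats.
#' @param flank_range Integer range of flank lengths around the repeat
#'   region.
#' @param background_len_range Length range of background proteins.
#' @param seed Seed (mandatory).
#' @return A list with `proteins` (tibble `id`, `seq`, `moltype`) and
#'   `truth` (tibble `protein_id`, `k`, `repeat_index`, `start`; 0-based
#'   repeat offsets).
#' @export
gen_proteome <- function(n_proteins = 200, family_fraction = 0.3,
                         repeat_count_probs = c("1" = 0.2, "2" = 0.6, "3" = 0.15, "4" = 0.05),
                         sub_rate = 0.1, consensus = myb_consensus(),
                         gap_range = c(5L, 20L), flank_range = c(20L, 80L),
                         background_len_range = c(150L, 400L), seed) {
  stopifnot(family_fraction >= 0, family_fraction <= 1)
  L <- nchar(consensus)
  withr::with_seed(substream_seed(seed, "proteome"), {
    n_family <- round(n_proteins * family_fraction)
    ids <- sprintf("P%04d", seq_len(n_proteins))
    is_family <- seq_len(n_proteins) <= n_family
    truth <- list()
    seqs <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      if (is_family[i]) {
        k <- as.integer(sample(names(repeat_count_probs), 1, prob = repeat_count_probs))
        left <- random_protein(sample(flank_range[1]:flank_range[2], 1))
        body <- left
        starts <- integer(k)
        for (j in seq_len(k)) {
          if (j > 1) {
            body <- paste0(body, random_protein(sample(gap_range[1]:gap_range[2], 1)))
          }
          starts[j] <- nchar(body)
          body <- paste0(body, mutate_repeat(consensus, sub_rate))
        }
        body <- paste0(body, random_protein(sample(flank_range[1]:flank_range[2], 1)))
        seqs[i] <- body
        truth[[length(truth) + 1]] <- tibble(
          protein_id = ids[i], k = k, repeat_index = seq_len(k), start = starts
        )
      } else {
        seqs[i] <- random_protein(sample(background_len_range[1]:background_len_range[2], 1))
      }
    }
    list(
      proteins = tibble(id = ids, seq = seqs, moltype = "protein"),
      truth = if (length(truth) > 0) bind_rows(truth) else
        tibble(protein_id = character(), k = integer(),
               repeat_index = integer(), start = integer())
    )
  })
}

#' Generate a synthetic QTL map with planted hotspots
#'
#' Planted clusters draw `size` same-trait QTL peaks uniformly within a
#' span narrower than the hotspot window, each cluster on its own
#' trait x chromosome combination. Background QTL are scattered
#' singletons, at most `min_count - 1` per trait x chromosome and kept
#' at least `window` cM away from a planted same-trait cluster, so the
#' truth table alone determines which hotspots exist. Marker anchors
#' are laid out every `anchor_step` cM with monotone jittered physical
#' spacing.
#'
#' @param n_clusters Number of planted clusters (default 5).
#' @param cluster_sizes Integer vector sampled for cluster sizes
#'   (default 4:8).
#' @param cluster_span_range Span range (cM) of planted clusters; must
#'   stay below `window`.
#' @param n_background Number of scattered background QTL (default 50).
#' @param chroms Chromosome names.
#' @param chrom_len_cm Chromosome length in cM.
#' @param traits Trait vocabulary.
#' @param window,min_count Hotspot rule parameters the map is built for.
#' @param anchor_step Anchor spacing in cM.
#' @param seed Seed (mandatory).
#' @return A list with `qtls`, `anchors` and `truth` (tibble
#'   `cluster_id`, `trait`, `chrom`, `cm_lo`, `cm_hi`, `size`,
#'   `members`).
#' @export
gen_qtl_map <- function(n_clusters = 5, cluster_sizes = 4:8,
                        cluster_span_range = c(5, 15), n_background = 50,
                        chroms = paste0("c", 1:13), chrom_len_cm = 200,
                        traits = c("FL", "FS", "FE", "FU", "MIC", "SFC", "LP"),
                        window = 20, min_count = 4, anchor_step = 10, seed) {
  if (cluster_span_range[2] >= window) {
    abort("cluster span must stay below the hotspot window")
  }
  withr::with_seed(substream_seed(seed, "qtl_map"), {
    combos <- tidyr::expand_grid(trait = traits, chrom = chroms)
    pick <- combos[sample(nrow(combos), n_clusters), ]
    truth_empty <- tibble(
      cluster_id = character(), trait = character(), chrom = character(),
      cm_lo = numeric(), cm_hi = numeric(), size = integer(), members = list()
    )
    truth <- list(truth_empty)
    qtl_rows <- list()
    qid <- 0
    for (i in seq_len(n_clusters)) {
      size <- sample(cluster_sizes, 1)
      span <- stats::runif(1, cluster_span_range[1], cluster_span_range[2])
      lo <- stats::runif(1, 0, chrom_len_cm - span)
      peaks <- sort(stats::runif(size, lo, lo + span))
      ids <- sprintf("Q%03d", qid + seq_len(size))
      qid <- qid + size
      qtl_rows[[length(qtl_rows) + 1]] <- tibble(
        qtl_id = ids, trait = pick$trait[i], chrom = pick$chrom[i],
        cm = peaks, source = "planted"
      )
      truth[[i + 1]] <- tibble(
        cluster_id = sprintf("cluster%02d", i),
        trait = pick$trait[i], chrom = pick$chrom[i],
        cm_lo = min(peaks), cm_hi = max(peaks), size = size,
        members = list(ids)
      )
    }
    truth <- bind_rows(truth)
    # background singletons: capped per combo and kept clear of planted
    # same-trait clusters so they can neither form nor extend a hotspot
    combo_count <- setNames(
      rep(0L, nrow(combos)), paste(combos$trait, combos$chrom)
    )
    bg <- list()
    while (length(bg) < n_background) {
      j <- sample(nrow(combos), 1)
      key <- paste(combos$trait[j], combos$chrom[j])
      if (combo_count[[key]] >= min_count - 1L) next
      cm <- stats::runif(1, 0, chrom_len_cm)
      near <- filter(
        truth,
        .data$trait == combos$trait[j], .data$chrom == combos$chrom[j],
        cm >= .data$cm_lo - window, cm <= .data$cm_hi + window
      )
      if (nrow(near) > 0) next
      combo_count[[key]] <- combo_count[[key]] + 1L
      qid <- qid + 1
      bg[[length(bg) + 1]] <- tibble(
        qtl_id = sprintf("Q%03d", qid), trait = combos$trait[j],
        chrom = combos$chrom[j], cm = cm, source = "background"
      )
    }
    qtls <- bind_rows(c(qtl_rows, bg))
    anchors <- bind_rows(lapply(chroms, function(ch) {
      cms <- seq(0, chrom_len_cm, by = anchor_step)
      steps <- stats::runif(length(cms) - 1, 0.6e6, 1.2e6)
      tibble(
        marker_id = sprintf("%s_M%02d", ch, seq_along(cms)),
        chrom = ch, cm = cms, bp = cumsum(c(1e5, steps))
      )
    }))
    list(qtls = qtls, anchors = anchors, truth = truth)
  })
}

#' Generate a synthetic backcross inbred line (BIL) experiment
#'
#' Emulates a BC1F7 population: marker genotypes are independent
#' Bernoulli draws of the donor allele at frequency `donor_freq` (0.25
#' after one backcross and selfing to near fixation), shared across
#' environments. Each trait value is the sum of planted marker effects,
#' an environment intercept, and Gaussian residual noise. Effects are
#' specified as target population correlations `r`, converted to slopes
#' via `beta = r / sqrt(1 - r^2) * resid_sd / sd_genotype`.
#'
#' @param n_lines Number of lines (default 180).
#' @param n_markers Number of markers (default 20).
#' @param environments Environment names (default four field tests).
#' @param traits Trait vocabulary present in the phenotype table.
#' @param effects Tibble with columns `marker_id`, `trait`, `r` (target
#'   correlation); default a single marker with `r = 0.30` on FL.
#' @param donor_freq Donor-allele frequency (default 0.25).
#' @param resid_sd Residual standard deviation (default 1).
#' @param env_sd SD of environment intercepts (default 0.5).
#' @param seed Seed (mandatory).
#' @return A list with `genotype` (long 0/1 table), `phenotype` (long
#'   table) and `truth` (effects with the implied slope `beta`).
#' @export
gen_bil <- function(n_lines = 180, n_markers = 20,
                    environments = c("15_Anyang", "16_Anyang", "16_Xinjiang", "15-16_Hainan"),
                    traits = c("FL", "FS", "FE", "FU", "MIC"),
                    effects = tibble(marker_id = "M01", trait = "FL", r = 0.30),
                    donor_freq = 0.25, resid_sd = 1, env_sd = 0.5, seed) {
  stopifnot(all(effects$trait %in% traits), all(abs(effects$r) < 1))
  withr::with_seed(substream_seed(seed, "bil"), {
    markers <- sprintf("M%02d", seq_len(n_markers))
    stopifnot(all(effects$marker_id %in% markers))
    lines <- sprintf("BIL%03d", seq_len(n_lines))
    g <- matrix(
      stats::rbinom(n_lines * n_markers, 1, donor_freq),
      nrow = n_lines, dimnames = list(lines, markers)
    )
    sd_g <- sqrt(donor_freq * (1 - donor_freq))
    truth <- mutate(effects, beta = .data$r / sqrt(1 - .data$r^2) * resid_sd / sd_g)
    pheno <- tidyr::expand_grid(environment = environments, trait = traits) |>
      purrr::pmap(function(environment, trait) {
        eff <- filter(truth, .data$trait == !!trait)
        signal <- rep(0, n_lines)
        for (k in seq_len(nrow(eff))) {
          signal <- signal + eff$beta[k] * g[, eff$marker_id[k]]
        }
        tibble(
          line_id = lines, environment = environment, trait = trait,
          value = signal + stats::rnorm(1, 0, env_sd) +
            stats::rnorm(n_lines, 0, resid_sd)
        )
      }) |>
      bind_rows()
    genotype <- as_tibble(as.data.frame.table(g, stringsAsFactors = FALSE)) |>
      rename(line_id = "Var1", marker_id = "Var2", genotype = "Freq") |>
      arrange(.data$marker_id, .data$line_id)
    list(genotype = genotype, phenotype = pheno, truth = truth)
  })
}

#' Generate a synthetic multi-assembly allele matrix
#'
#' Constructs allele vectors that satisfy the classification rule for
#' the intended class (rule-consistent construction), using the default
#' column roles of [table1_roles()].
#'
#' @param n_sites Number of sites (default 30).
#' @param class_probs Mixture over `interspecific`, `parentA_specific`
#'   and `parentB_specific`.
#' @param seed Seed (mandatory).
#' @return A list with `sites` (allele-matrix tibble) and `truth`
#'   (tibble `site_id`, `class`).
#' @export
gen_allele_matrix <- function(n_sites = 30,
                              class_probs = c(interspecific = 0.7,
                                              parentA_specific = 0.15,
                                              parentB_specific = 0.15),
                              seed) {
  withr::with_seed(substream_seed(seed, "allele_matrix"), {
    classes <- sample(names(class_probs), n_sites, replace = TRUE, prob = class_probs)
    bases <- c("A", "C", "G", "T")
    rows <- purrr::imap(classes, function(cls, i) {
      xy <- sample(bases, 2)
      x <- xy[1]
      y <- xy[2]
      r <- switch(cls,
        interspecific = list(a = c(x, x), pa = x, pb = y, own = y, other = c(y, y)),
        parentA_specific = list(a = c(x, x), pa = y, pb = x, own = x, other = c(x, x)),
        parentB_specific = list(a = c(x, x), pa = x, pb = y, own = y, other = c(x, x))
      )
      tibble(
        gene_id = sprintf("GENE%03d", (i + 1) %/% 2),
        site_id = sprintf("S%03d", i),
        tm1_nau = r$a[1], tm1_jgi = r$a[2], ccri36 = r$pa,
        hai7124 = r$pb, hai7124_zju = r$own,
        xinhai21_nau = r$other[1], x3_79_hau = r$other[2]
      )
    })
    list(
      sites = bind_rows(rows),
      truth = tibble(site_id = sprintf("S%03d", seq_len(n_sites)), class = classes)
    )
  })
}

#' Generate synthetic ortholog groups with planted loss scenarios
#'
#' For each requested scenario, presence/absence patterns are sampled
#' uniformly from the patterns carrying that label, and present slots
#' are filled with generated gene ids.
#'
#' @param scenario_counts Named integer vector over the scenario labels
#'   (see [classify_scenarios()]).
#' @param seed Seed (mandatory).
#' @return A list with `groups` (six-slot tibble) and `truth` (tibble
#'   `group_id`, `scenario`).
#' @export
gen_ortholog_groups <- function(scenario_counts = c(RETAINED_ALL = 20,
                                                    LOSS_ONE_SUBGENOME_AD1 = 3,
                                                    LOSS_ONE_SUBGENOME_AD2 = 5),
                                seed) {
  stopifnot(all(names(scenario_counts) %in% SCENARIO_LEVELS))
  patterns <- all_presence_patterns()
  withr::with_seed(substream_seed(seed, "ortholog"), {
    scen <- rep(names(scenario_counts), times = scenario_counts)
    rows <- purrr::imap(scen, function(cls, i) {
      cand <- patterns$pattern[patterns$scenario == cls]
      p <- cand[[sample(length(cand), 1)]]
      ids <- ifelse(p, paste0(toupper(ORTHOLOG_SLOTS), "_g", i), NA_character_)
      out <- as.list(setNames(ids, ORTHOLOG_SLOTS))
      out$group_id <- sprintf("OG%03d", i)
      as_tibble(out)
    })
    groups <- bind_rows(rows) |> select("group_id", dplyr::all_of(ORTHOLOG_SLOTS))
    list(
      groups = groups,
      truth = tibble(group_id = groups$group_id, scenario = scen)
    )
  })
}

# all 63 non-empty presence patterns with their scenario labels
all_presence_patterns <- function() {
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 6)))
  colnames(grid) <- ORTHOLOG_SLOTS
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  tibble(
    pattern = lapply(seq_len(nrow(grid)), function(i) grid[i, ]),
    scenario = vapply(
      seq_len(nrow(grid)),
      function(i) scenario_label(grid[i, ]), character(1)
    )
  )
}

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

#' Simulate coding-sequence pairs under a known dN/dS
#'
#' Each pair starts from a random sense-codon ancestor; the second copy
#' accumulates proposed single-base changes, rejecting changes to stop
#' codons, accepting synonymous changes always and nonsynonymous changes
#' with probability `omega`, so the realised nonsynonymous/synonymous
#' rate ratio is `omega`.
#'
#' @param n_pairs Number of pairs (default 200).
#' @param n_codons Codons per sequence (default 100).
#' @param omega Generating dN/dS (default 0.2).
#' @param n_events Proposed mutation events per pair (default 60).
#' @param seed Seed (mandatory).
#' @return A tibble with columns `pair_id`, `cds_a`, `cds_b`, plus the
#'   per-pair truth counts `n_syn_events` and `n_nonsyn_events` of
#'   accepted substitutions.
#' @export
gen_codon_pairs <- function(n_pairs = 200, n_codons = 100, omega = 0.2,
                            n_events = 60, seed) {
  withr::with_seed(substream_seed(seed, "codon"), {
    rows <- purrr::map(seq_len(n_pairs), function(i) {
      codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
      cds_a <- paste(codons, collapse = "")
      derived <- codons
      n_syn <- 0L
      n_non <- 0L
      for (e in seq_len(n_events)) {
        ci <- sample(n_codons, 1)
        pos <- sample(3, 1)
        old <- substr(derived[ci], pos, pos)
        new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        cand <- derived[ci]
        substr(cand, pos, pos) <- new
        if (GENETIC_CODE[[cand]] == "*") next
        syn <- GENETIC_CODE[[cand]] == GENETIC_CODE[[derived[ci]]]
        if (syn) {
          derived[ci] <- cand
          n_syn <- n_syn + 1L
        } else if (stats::runif(1) < omega) {
          derived[ci] <- cand
          n_non <- n_non + 1L
        }
      }
      tibble(
        pair_id = sprintf("pair%03d", i),
        cds_a = cds_a, cds_b = paste(derived, collapse = ""),
        n_syn_events = n_syn, n_nonsyn_events = n_non
      )
    })
    bind_rows(rows)
  })
}
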