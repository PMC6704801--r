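present_all <- stats::setNames(rep(TRUE, 6), SLOTS)

test_that("scenario classification handles the anchor patterns", {
  g <- pattern_group(present_all)
  expect_equal(classify_scenarios(g)$scenario, "RETAINED_ALL")

  # diploid progenitor lost while both tetraploid descendants keep the gene
  p <- present_all
  p["d5"] <- FALSE
  expect_equal(classify_scenarios(pattern_group(p))$scenario, "LOSS_DIPLOID_ONLY")

  p <- present_all
  p["dt_ad1"] <- FALSE
  expect_equal(classify_scenarios(pattern_group(p))$scenario, "LOSS_ONE_SUBGENOME_AD1")

  p <- present_all
  p[c("at_ad2", "dt_ad2")] <- FALSE
  expect_equal(classify_scenarios(pattern_group(p))$scenario, "LOSS_BOTH_SUBGENOMES_AD2")

  p <- present_all
  p[c("a2", "at_ad1")] <- FALSE
  expect_equal(
    classify_scenarios(pattern_group(p))$scenario,
    "LOSS_SUBGENOME_AND_PROGENITOR"
  )

  none <- stats::setNames(rep(FALSE, 6), SLOTS)
  expect_error(classify_scenarios(pattern_group(none)), "all slots absent")
})

test_that("all 63 presence patterns map to exactly one label and match the oracle", {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), 6))
  names(grid) <- SLOTS
  grid <- grid[rowSums(grid) > 0, ]
  groups <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    pattern_group(unlist(grid[i, ]), id = paste0("g", i))
  }))
  got <- classify_scenarios(groups)$scenario
  levels8 <- c(
    "RETAINED_ALL", "LOSS_ONE_SUBGENOME_AD1", "LOSS_ONE_SUBGENOME_AD2",
    "LOSS_BOTH_SUBGENOMES_AD1", "LOSS_BOTH_SUBGENOMES_AD2",
    "LOSS_DIPLOID_ONLY", "LOSS_SUBGENOME_AND_PROGENITOR", "OTHER"
  )
  expect_true(all(got %in% levels8))
  want <- vapply(
    seq_len(nrow(grid)), function(i) oracle_scenario(unlist(grid[i, ])),
    character(1)
  )
  expect_equal(got, want)
})

test_that("loss summaries count planted losses and never double-count", {
  gen <- gen_ortholog_groups(
    scenario_counts = c(
      RETAINED_ALL = 12, LOSS_ONE_SUBGENOME_AD1 = 3, LOSS_ONE_SUBGENOME_AD2 = 5
    ),
    seed = 11
  )
  ls <- count_losses(gen$groups)
  expect_equal(ls$species$lost_groups, c(3L, 5L))
  expect_equal(sum(ls$scenarios$n), nrow(gen$groups))
  gl <- generics::glance(ls)
  expect_equal(gl$lost_ad1, 3L)
  expect_equal(gl$lost_ad2, 5L)

  all_ret <- gen_ortholog_groups(scenario_counts = c(RETAINED_ALL = 6), seed = 2)
  expect_equal(count_losses(all_ret$groups)$species$lost_groups, c(0L, 0L))

  p <- present_all
  p[c("at_ad1", "dt_ad1")] <- FALSE
  both <- pattern_group(p)
  ls2 <- count_losses(both)
  expect_equal(ls2$species$lost_groups, c(1L, 0L))
  expect_equal(classify_scenarios(both)$scenario, "LOSS_BOTH_SUBGENOMES_AD1")
})

test_that("identical coding sequences give zero divergence and no selection call", {
  res <- ng86_dnds("ATGGCT", "ATGGCT")
  expect_equal(res$Nd, 0)
  expect_equal(res$Sd, 0)
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_equal(res$selection, "undefined")
  expect_true(is.na(res$omega))
})

test_that("site and difference counting match hand enumeration for TTT/TTA", {
  # among TTT's nine single-base mutants only TTC is synonymous
  res <- ng86_dnds("TTT", "TTA")
  s_ttt <- oracle_syn_sites("TTT")
  expect_equal(s_ttt, 1 / 3)
  expect_equal(res$Sd, 0)
  expect_equal(res$Nd, 1)
  # per-sequence site averages: TTT has 1/3, TTA has 2/3 synonymous sites
  expect_equal(res$S, (1 / 3 + 2 / 3) / 2)
  expect_equal(res$N + res$S, 3)
})

test_that("ng86 is symmetric and rejects malformed input", {
  a <- "ATGAAACCCGGG"
  b <- "ATGAAGCCTGGA"
  expect_equal(
    suppressWarnings(ng86_dnds(a, b)),
    suppressWarnings(ng86_dnds(b, a))
  )
  expect_error(ng86_dnds("ATG", "ATGAAA"), "length")
  expect_error(ng86_dnds("ATGA", "ATGC"), "multiple of 3")
  expect_error(ng86_dnds("ATGTAAAAA", "ATGTACAAA"), "stop codon at codon 2")
})

test_that("ng86 agrees with the exhaustive pathway oracle on random codon pairs", {
  sense <- names(GC)[GC != "*"]
  withr::with_seed(31, {
    for (i in 1:150) {
      ca <- sample(sense, 1)
      cb <- sample(sense, 1)
      res <- suppressWarnings(ng86_dnds(ca, cb))
      want <- oracle_ng86(ca, cb)
      expect_equal(res$S, want$S, tolerance = 1e-12)
      expect_equal(res$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(res$Nd, want$Nd, tolerance = 1e-12)
    }
  })
})

test_that("simulated purifying selection is recovered", {
  pairs <- gen_codon_pairs(n_pairs = 60, n_codons = 100, omega = 0.2, seed = 5)
  res <- dnds_pairs(pairs)
  expect_lt(median(res$omega, na.rm = TRUE), 1)
  expect_gte(mean(res$selection == "purifying"), 0.95)
  # dS sits in the correctable range for this divergence
  expect_true(all(res$pS < 3 / 4))
})

test_that("estimated synonymous divergence tracks the generating process", {
  pairs <- gen_codon_pairs(n_pairs = 200, n_codons = 100, omega = 0.2, seed = 5)
  res <- dnds_pairs(pairs)
  # every replicate stays in the Jukes-Cantor correctable range
  expect_true(all(res$pS < 3 / 4))
  # truth: accepted synonymous substitutions per synonymous site (site
  # counts are exact arithmetic on the sequences, not estimates); the mean
  # estimate must sit within three standard errors of the mean truth,
  # taking the replicate spread of the estimator as its standard error
  ds_true <- pairs$n_syn_events / res$S
  expect_lt(abs(mean(res$dS) - mean(ds_true)), 3 * stats::sd(res$dS))
})

test_that("subgenome asymmetry summaries are computable", {
  df <- tibble::tibble(
    subgenome = rep(c("At", "Dt"), each = 4),
    omega = c(0.3, 0.5, 0.4, NA, 0.2, 0.25, 0.3, 0.1)
  )
  out <- subgenome_asymmetry(df)
  expect_equal(out$n, c(3L, 4L))
  expect_equal(out$median_omega[out$subgenome == "At"], 0.4)
})

test_that("reciprocal best hits pair up mutually nearest sequences", {
  a <- tibble::tibble(id = c("a1", "a2"), seq = c("AAAA", "CCCC"))
  b <- tibble::tibble(id = c("b1", "b2"), seq = c("AAAT", "CCCG"))
  out <- rbh_pairs(a, b)
  expect_equal(out$id_b[out$id_a == "a1"], "b1")
  expect_equal(out$id_b[out$id_a == "a2"], "b2")
})
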