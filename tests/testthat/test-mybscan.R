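consensus <- myb_consensus()
seed_aln <- gen_repeat_family(n_repeats = 30, sub_rate = 0.1, seed = 1)
profile <- build_profile(seed_aln)

test_that("build_profile favours observed residues and zeroes uniform columns", {
  two <- build_profile(c("WAW", "WAW"))
  for (p in 1:3) {
    obs <- substr("WAW", p, p)
    expect_equal(names(which.max(two$pssm[p, ])), obs)
  }
  # a column carrying every residue at its background frequency is
  # uninformative: log-odds are exactly zero under a uniform background
  uniform_col <- build_profile(paste0(AA20 <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  ), "W"))
  expect_equal(unname(uniform_col$pssm[1, ]), rep(0, 20), tolerance = 1e-12)

  expect_error(build_profile(c("WA", "WAW")), "unequal")
  expect_error(build_profile("WAW"), "at least 2")
})

test_that("the generating consensus outscores shuffled windows", {
  score_of <- function(s) {
    scan_repeats(
      tibble::tibble(id = "x", seq = s), profile,
      score_threshold = -Inf
    )$score[1]
  }
  cons_score <- score_of(consensus)
  null95 <- calibrate_threshold(consensus, profile,
    n_shuffles = 1000, q = 0.95, seed = 2
  )
  expect_gt(cons_score, null95)
})

test_that("a repeat-free random protein yields no hits at the null threshold", {
  rand <- withr::with_seed(4, {
    paste(
      sample(c(
        "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
      ), 300, replace = TRUE),
      collapse = ""
    )
  })
  thr <- calibrate_threshold(rand, profile, n_shuffles = 1000, q = 0.999, seed = 5)
  hits <- scan_repeats(
    tibble::tibble(id = "r", seq = rand), profile,
    score_threshold = thr
  )
  expect_equal(nrow(hits), 0)
})

test_that("planted tandem repeats are recovered at their offsets", {
  flank <- strrep("A", 30)
  two <- paste0(flank, consensus, strrep("G", 5), consensus, flank)
  hits <- scan_repeats(tibble::tibble(id = "p2", seq = two), profile)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start, c(30L, 30L + 53L + 5L))
  expect_true(all(hits$cluster == 1L))

  three <- paste0(flank, strrep(paste0(consensus, strrep("G", 8)), 3), flank)
  hits3 <- scan_repeats(tibble::tibble(id = "p3", seq = three), profile)
  calls <- classify_family(hits3)
  expect_equal(calls$n_repeats, 3)
  expect_equal(calls$subfamily, "3R")
})

test_that("scan output never overlaps and ignores the protein id", {
  prot <- gen_proteome(n_proteins = 20, family_fraction = 0.5, seed = 7)
  hits <- scan_repeats(prot$proteins, profile)
  by_prot <- split(hits, hits$protein_id)
  for (h in by_prot) {
    h <- h[order(h$start), ]
    if (nrow(h) > 1) expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
  }
  renamed <- dplyr::mutate(prot$proteins, id = paste0("other_", id))
  hits2 <- scan_repeats(renamed, profile)
  expect_equal(hits2[c("start", "end", "score")], hits[c("start", "end", "score")])
})

test_that("proteins shorter than the repeat length yield empty results", {
  short <- tibble::tibble(id = "s", seq = "MKWQ")
  expect_equal(nrow(scan_repeats(short, profile)), 0)
})

test_that("distant repeat clusters are split and the largest defines the call", {
  far <- paste0(
    strrep("A", 10), consensus, strrep("G", 100),
    consensus, strrep("G", 8), consensus, strrep("A", 10)
  )
  hits <- scan_repeats(tibble::tibble(id = "f", seq = far), profile, max_gap = 30)
  expect_equal(sort(unique(hits$cluster)), c(1L, 2L))
  calls <- classify_family(hits)
  expect_equal(calls$n_repeats, 2) # the pair, not all three
  expect_equal(calls$subfamily, "R2R3")
})

test_that("subfamily is a pure function of repeat count", {
  fake_repeats <- function(k) {
    if (k == 0) {
      return(tibble::tibble(
        protein_id = character(), start = integer(), end = integer(),
        score = numeric(), repeat_index = integer(), cluster = integer()
      ))
    }
    tibble::tibble(
      protein_id = "p", start = (0:(k - 1)) * 60L, end = (0:(k - 1)) * 60L + 53L,
      score = 100, repeat_index = seq_len(k), cluster = 1L
    )
  }
  expected <- c("none", "1R", "R2R3", "3R", "4R", "4R", "4R")
  for (k in 0:6) {
    calls <- classify_family(fake_repeats(k), protein_ids = "p")
    expect_equal(calls$subfamily, expected[k + 1], info = paste("k =", k))
    expect_equal(calls$n_repeats, k)
  }
})

test_that("logo statistics hit the entropy bounds and report modal residues", {
  allw <- logo_stats(rep(strrep("W", 5), 8))
  expect_equal(allw$ic, rep(log2(20), 5))
  expect_equal(allw$modal_residue, rep("W", 5))

  AA <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  unif <- logo_stats(paste0(AA, "W"))
  expect_equal(unif$ic[1], 0)
  expect_equal(unif$ic[2], log2(20))

  # degraded first tryptophan column: 60% F / 30% W / 10% L
  col <- c(rep("F", 6), rep("W", 3), "L")
  aln <- paste0(col, strrep("A", 3))
  cp <- logo_stats(aln)
  expect_equal(cp$modal_residue[1], "F")
  expect_equal(cp$modal_freq[1], 0.6)

  expect_error(logo_stats(character(0)), "empty")
})

test_that("information content is bounded on random alignments", {
  withr::with_seed(11, {
    AA <- c(
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
    )
    for (rep in 1:20) {
      aln <- vapply(
        1:6, function(i) paste(sample(AA, 10, replace = TRUE), collapse = ""),
        character(1)
      )
      cp <- logo_stats(aln)
      expect_true(all(cp$ic >= -1e-12 & cp$ic <= log2(20) + 1e-12))
      f <- attr(cp, "freq")
      expect_equal(unname(rowSums(f)), rep(1, nrow(f)))
    }
  })
})

test_that("profile objects expose tidy and glance views", {
  td <- generics::tidy(profile)
  expect_equal(nrow(td), 53 * 20)
  gl <- generics::glance(profile)
  expect_equal(gl$length, 53)
  expect_true(gl$score_threshold < gl$max_score)
})
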