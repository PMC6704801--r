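test_that("coding-change calls follow the standard genetic code", {
  expect_equal(call_nonsynonymous("GGT", 2, "C"), "synonymous")
  expect_equal(call_nonsynonymous("TTT", 2, "A"), "nonsynonymous")
  expect_equal(call_nonsynonymous("TGG", 1, "A"), "stop_gained")
  expect_equal(call_nonsynonymous("TAA", 1, "C"), "stop_lost")
  expect_equal(call_nonsynonymous("GNT", 2, "C"), "unclassifiable")
  expect_error(call_nonsynonymous("GGT", 2, "T"), "equals reference")
  expect_error(call_nonsynonymous("GGT", 3, "A"), "offset")
})

make_site <- function(tm1_nau, tm1_jgi, ccri36, hai7124, zju, xinhai, hau,
                      id = "s1") {
  tibble::tibble(
    gene_id = "g", site_id = id,
    tm1_nau = tm1_nau, tm1_jgi = tm1_jgi, ccri36 = ccri36,
    hai7124 = hai7124, hai7124_zju = zju,
    xinhai21_nau = xinhai, x3_79_hau = hau
  )
}

test_that("snp classification reproduces the four worked allele patterns", {
  # canonical interspecific: each parent matches its species' assemblies
  s <- make_site("C", "C", "C", "A", "A", "A", "A")
  expect_equal(classify_snp_sites(s)$snp_class, "interspecific")
  # recurrent-parent-specific: CCRI 36 differs from both TM-1 assemblies
  s <- make_site("G", "G", "A", "G", "G", "G", "G")
  expect_equal(classify_snp_sites(s)$snp_class, "parentA_specific")
  # donor-parent-specific: Hai 7124 confirmed by its own assembly, absent
  # from the other donor-species assemblies
  s <- make_site("T", "T", "T", "G", "G", "T", "T")
  expect_equal(classify_snp_sites(s)$snp_class, "parentB_specific")
  # irregular: one TM-1 assembly disagrees and one donor assembly shares
  # the donor allele -> still interspecific
  s <- make_site("G", "A", "G", "A", "G", "G", "G")
  expect_equal(classify_snp_sites(s)$snp_class, "interspecific")
  s <- make_site("G", "G", "G", "A", "A", "A", "G")
  expect_equal(classify_snp_sites(s)$snp_class, "interspecific")
})

test_that("equal, missing or doubly specific parents are handled", {
  expect_equal(
    classify_snp_sites(make_site("A", "A", "A", "A", "A", "A", "A"))$snp_class,
    "unclassifiable"
  )
  expect_equal(
    classify_snp_sites(make_site("A", "A", "N", "G", "G", "G", "G"))$snp_class,
    "unclassifiable"
  )
  # both parent-specific conditions hold at once
  expect_equal(
    classify_snp_sites(make_site("A", "A", "C", "G", "G", "T", "T"))$snp_class,
    "conflicting"
  )
})

test_that("the packaged allele matrix reproduces the published SNP types", {
  sites <- read_table(table1_fixture_path(), "allele_matrix")
  cls <- classify_snp_sites(sites)
  printed <- c(
    interspecific = "Interspecific",
    parentA_specific = "CCRI 36-specific",
    parentB_specific = "Hai 7124-specific"
  )
  expect_equal(unname(printed[cls$snp_class]), cls$snp_type)
  expect_equal(sum(cls$snp_class == "interspecific"), 20)
  expect_equal(sum(cls$snp_class == "parentA_specific"), 3)
  expect_equal(sum(cls$snp_class == "parentB_specific"), 4)
  expect_equal(sum(cls$snp_class == "conflicting"), 0)
})

geno4 <- tibble::tibble(
  line_id = paste0("L", 1:4), marker_id = "M1", genotype = c(0, 0, 1, 1)
)
pheno4 <- tibble::tibble(
  line_id = paste0("L", 1:4), environment = "E1", trait = "FL",
  value = c(1, 1, 3, 3)
)

test_that("perfect separation gives r = 1 and constants give undefined rows", {
  res <- associate_markers(geno4, pheno4)
  expect_equal(res$r, 1)
  expect_equal(res$n, 4L)

  flat <- dplyr::mutate(pheno4, value = 2)
  res2 <- associate_markers(geno4, flat)
  expect_true(is.na(res2$r))
  expect_true(is.na(res2$p))

  const_g <- dplyr::mutate(geno4, genotype = 1)
  res3 <- associate_markers(const_g, pheno4)
  expect_true(is.na(res3$r))
})

test_that("swapping genotype labels flips the correlation sign only", {
  pheno <- dplyr::mutate(pheno4, value = c(1.2, 0.8, 2.9, 3.3))
  a <- associate_markers(geno4, pheno)
  b <- associate_markers(dplyr::mutate(geno4, genotype = 1 - genotype), pheno)
  expect_equal(a$r, -b$r)
  expect_equal(a$p, b$p)
})

test_that("stars, stability and pairwise deletion behave as documented", {
  gen <- gen_bil(
    n_markers = 3, traits = "FL",
    effects = tibble::tibble(marker_id = "M01", trait = "FL", r = 0.5),
    seed = 91
  )
  res <- associate_markers(gen$genotype, gen$phenotype)
  m1 <- dplyr::filter(res, marker_id == "M01")
  expect_equal(nrow(m1), 4) # one row per environment
  expect_true(all(m1$stars == "**"))
  expect_equal(unique(m1$stability), 4L)
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))

  # missing phenotype rows are excluded pairwise
  gen$phenotype$value[1:10] <- NA
  res2 <- associate_markers(gen$genotype, gen$phenotype)
  expect_true(any(res2$n < 180))
  expect_true(all(res2$n >= 170))
})

test_that("p-values match the closed-form t transform", {
  gen <- gen_bil(n_markers = 2, traits = "FL", environments = "E1",
                 effects = tibble::tibble(marker_id = "M01", trait = "FL", r = 0.3),
                 seed = 93)
  res <- associate_markers(gen$genotype, gen$phenotype)
  joined <- dplyr::inner_join(gen$genotype, gen$phenotype, by = "line_id")
  for (m in c("M01", "M02")) {
    sub <- dplyr::filter(joined, marker_id == m)
    ct <- stats::cor.test(sub$genotype, sub$value)
    row <- dplyr::filter(res, marker_id == m)
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("fold changes obey the 2^-ddCt identities", {
  ct <- tibble::tibble(
    sample = rep(c("cal", "s1", "s2", "s3"), each = 2),
    gene = rep(c("target", "ref"), 4),
    ct = c(
      20, 18, # cal: dCt 2
      18, 18, # s1: dCt 0 -> ddCt -2 -> fold 4
      23, 21, # s2: dCt 2 -> ddCt 0 -> fold 1
      21, 18 # s3: dCt 3 -> ddCt 1 -> fold 0.5
    )
  )
  res <- ddct(ct, reference_gene = "ref", calibrator_sample = "cal")
  expect_equal(res$fold[res$sample == "s1"], 4)
  expect_equal(res$fold[res$sample == "s2"], 1)
  expect_equal(res$fold[res$sample == "s3"], 0.5)
  expect_equal(res$fold[res$sample == "cal"], 1)
  # exact inverse identity for every row
  expect_equal(res$fold * 2^res$delta_delta_ct, rep(1, nrow(res)))
})

test_that("ddct averages replicates and names samples missing the reference", {
  ct <- tibble::tibble(
    sample = c("cal", "cal", "cal", "s1", "s1"),
    gene = c("target", "target", "ref", "target", "ref"),
    ct = c(19, 21, 18, 18, 18)
  )
  res <- ddct(ct, "ref", "cal")
  expect_equal(res$delta_ct[res$sample == "cal"], 2) # mean(19,21) - 18

  bad <- tibble::tibble(
    sample = c("cal", "cal", "s9"), gene = c("target", "ref", "target"),
    ct = c(20, 18, 22)
  )
  expect_error(ddct(bad, "ref", "cal"), "s9")
})

test_that("expression concordance follows the association sign", {
  expr <- tibble::tibble(
    stage = rep(c("10DPA", "20DPA", "25DPA"), 2),
    allele = rep(c("B", "A"), each = 3),
    value = c(2, 3, 4, 5, 6, 7)
  )
  neg <- expression_concordance("-", expr)
  expect_true(neg$concordant)
  expect_setequal(neg$supporting_stages[[1]], c("10DPA", "20DPA", "25DPA"))

  pos <- expression_concordance("+", expr)
  expect_false(pos$concordant)

  # donor allele higher only at the elongation stage still supports "+"
  expr2 <- dplyr::mutate(expr, value = c(9, 3, 4, 5, 6, 7))
  pos2 <- expression_concordance("+", expr2)
  expect_true(pos2$concordant)
  expect_equal(pos2$supporting_stages[[1]], "10DPA")
  expect_false(expression_concordance("+", expr2, strict = TRUE)$concordant)

  no_shared <- tibble::tibble(
    stage = c("10DPA", "20DPA"), allele = c("A", "B"), value = c(1, 2)
  )
  expect_error(expression_concordance("-", no_shared), "no shared")
  expect_error(expression_concordance("x", expr), "sign")
})
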