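#' Classify a coding SNP as synonymous or nonsynonymous
#'
#' Substitutes the alternative base into the reference codon and compares
#' the translations under the standard genetic code.
#'
#' @param ref_codon Character vector of reference codons (3 bases).
#' @param offset Integer vector of in-codon offsets (0, 1 or 2; 0-based).
#' @param alt_base Character vector of alternative bases, each different
#'   from the reference base at `offset`.
#' @return Character vector over `synonymous`, `nonsynonymous`,
#'   `stop_gained`, `stop_lost`, or `unclassifiable` for codons
#'   containing `N`.
#' @export
#' @examples
#' call_nonsynonymous("GGT", 2, "C") # fourfold-degenerate -> synonymous
#' call_nonsynonymous("TGG", 1, "A") # Trp -> stop
call_nonsynonymous <- function(ref_codon, offset, alt_base) {
  n <- max(length(ref_codon), length(offset), length(alt_base))
  ref_codon <- toupper(rep_len(ref_codon, n))
  offset <- rep_len(offset, n)
  alt_base <- toupper(rep_len(alt_base, n))
  if (any(!offset %in% 0:2)) abort("offset must be 0, 1 or 2")
  if (any(nchar(ref_codon) != 3)) abort("ref_codon must be 3 bases")
  vapply(seq_len(n), function(i) {
    codon <- ref_codon[i]
    ref_base <- substr(codon, offset[i] + 1, offset[i] + 1)
    if (alt_base[i] == ref_base) {
      abort(paste0("alt base equals reference base at offset ", offset[i]))
    }
    if (grepl("N", codon) || alt_base[i] == "N") return("unclassifiable")
    if (grepl("[^ACGT]", codon) || !alt_base[i] %in% c("A", "C", "G", "T")) {
      abort(paste0("invalid codon or base: ", codon, " / ", alt_base[i]))
    }
    alt_codon <- codon
    substr(alt_codon, offset[i] + 1, offset[i] + 1) <- alt_base[i]
    aa_ref <- GENETIC_CODE[[codon]]
    aa_alt <- GENETIC_CODE[[alt_codon]]
    if (aa_ref == aa_alt) {
      "synonymous"
    } else if (aa_alt == "*") {
      "stop_gained"
    } else if (aa_ref == "*") "stop_lost" else "nonsynonymous"
  }, character(1))
}

#' Classify SNP sites against a multi-assembly allele matrix
#'
#' Labels each site by comparing the two parental alleles with the
#' independent assemblies of both species. With missing alleles coded
#' `N`, the rule is applied in order: (1) equal or missing parental
#' alleles are `unclassifiable`; (2) `parentA_specific` if the
#' species-A parent differs from every species-A reference assembly;
#' (3) `parentB_specific` if the species-B parent matches its own
#' assembly and differs from every other species-B assembly; (4) both
#' (2) and (3) holding is `conflicting`; (5) everything else is
#' `interspecific`. The own-assembly confirmation in (3) is what keeps a
#' site where one species-A reference disagrees (or one species-B
#' assembly shares the donor allele) in the interspecific class.
#'
#' @param sites An allele-matrix table (see [read_table()] with
#'   `kind = "allele_matrix"`).
#' @param roles Role map naming the allele columns (see
#'   [table1_roles()]).
#' @return `sites` with an added `snp_class` column over
#'   `interspecific`, `parentA_specific`, `parentB_specific`,
#'   `conflicting`, `unclassifiable`.
#' @export
classify_snp_sites <- function(sites, roles = table1_roles()) {
  sites <- validate_table(sites, "allele_matrix", roles = roles)
  pa <- sites[[roles$speciesA_parent]]
  pb <- sites[[roles$speciesB_parent]]
  own <- sites[[roles$speciesB_own]]
  a_refs <- as.matrix(sites[roles$speciesA_refs])
  b_other <- as.matrix(sites[roles$speciesB_other])
  n <- nrow(sites)
  cls <- vapply(seq_len(n), function(i) {
    if (pa[i] == "N" || pb[i] == "N") return("unclassifiable")
    if (pa[i] == pb[i]) return("unclassifiable")
    a_informative <- a_refs[i, ][a_refs[i, ] != "N"]
    b_informative <- b_other[i, ][b_other[i, ] != "N"]
    is_pa <- all(pa[i] != a_informative)
    is_pb <- own[i] != "N" && pb[i] == own[i] && all(pb[i] != b_informative)
    if (is_pa && is_pb) return("conflicting")
    if (is_pa) return("parentA_specific")
    if (is_pb) return("parentB_specific")
    "interspecific"
  }, character(1))
  mutate(sites, snp_class = cls)
}

#' Marker-trait correlation analysis in a BIL population
#'
#' Point-biserial Pearson correlation between the 0/1 donor-allele
#' genotype and each quantitative trait, per environment, with the
#' two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom. Missing genotypes or phenotypes are
#' excluded pairwise. Significance stars follow the per-test convention
#' (`*` for `p < alpha1`, `**` for `p < alpha2`, no multiplicity
#' adjustment by default); `stability` counts, per marker x trait, the
#' environments significant at `alpha1`. Constant genotype or phenotype
#' yields an `undefined` row (`r` and `p` are `NA`) rather than an
#' error.
#'
#' @param genotype Long genotype table (`line_id`, `marker_id`,
#'   `genotype` in 0/1/NA; 1 = donor allele).
#' @param phenotype Long phenotype table (`line_id`, `environment`,
#'   `trait`, `value`).
#' @param alpha1,alpha2 Star thresholds (defaults 0.05 and 0.01).
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`), applied within each environment
#'   x trait before starring. Default `"none"`.
#' @return A tibble with columns `marker_id`, `trait`, `environment`,
#'   `n`, `r`, `p`, `stars`, `stability`.
#' @export
associate_markers <- function(genotype, phenotype, alpha1 = 0.05, alpha2 = 0.01,
                              adjust = "none") {
  genotype <- validate_table(genotype, "genotype")
  phenotype <- validate_table(phenotype, "phenotype")
  joined <- dplyr::inner_join(
    genotype, phenotype,
    by = "line_id", relationship = "many-to-many"
  ) |>
    filter(!is.na(.data$genotype), !is.na(.data$value))
  res <- joined |>
    group_by(.data$marker_id, .data$trait, .data$environment) |>
    summarise(
      n = n(),
      r = if (n() >= 3 && sd(.data$genotype) > 0 && sd(.data$value) > 0) {
        cor(.data$genotype, .data$value)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(
      tstat = .data$r * sqrt(.data$n - 2) / sqrt(pmax(1 - .data$r^2, 0)),
      p = 2 * pt(-abs(.data$tstat), df = .data$n - 2)
    ) |>
    select(-"tstat")
  if (adjust != "none") {
    res <- res |>
      group_by(.data$trait, .data$environment) |>
      mutate(p = stats::p.adjust(.data$p, method = adjust)) |>
      ungroup()
  }
  res |>
    mutate(stars = dplyr::case_when(
      is.na(.data$p) ~ NA_character_,
      .data$p < alpha2 ~ "**",
      .data$p < alpha1 ~ "*",
      TRUE ~ "none"
    )) |>
    group_by(.data$marker_id, .data$trait) |>
    mutate(stability = sum(.data$p < alpha1, na.rm = TRUE)) |>
    ungroup() |>
    arrange(.data$marker_id, .data$trait, .data$environment)
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical/biological replicate Ct values are averaged per sample x
#' gene before differencing. For each target gene and sample,
#' `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt_sample - dCt_calibrator`, and the fold change is
#' `2^-ddCt` (so `ddCt = 0` gives fold 1).
#'
#' @param ct A Ct table (`sample`, `gene`, `ct`; replicate measurements
#'   as repeated rows).
#' @param reference_gene Name of the reference (housekeeping) gene.
#' @param calibrator_sample Name of the calibrator sample.
#' @return A tibble with columns `gene`, `sample`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
ddct <- function(ct, reference_gene, calibrator_sample) {
  ct <- validate_table(ct, "ct")
  means <- ct |>
    group_by(.data$sample, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  refs <- filter(means, .data$gene == reference_gene) |>
    select("sample", ref_ct = "ct")
  targets <- filter(means, .data$gene != reference_gene)
  no_ref <- setdiff(unique(targets$sample), refs$sample)
  if (length(no_ref) > 0) {
    abort(paste0(
      "missing reference-gene Ct for sample(s): ", paste(no_ref, collapse = ", ")
    ))
  }
  dct <- targets |>
    left_join(refs, by = "sample") |>
    mutate(delta_ct = .data$ct - .data$ref_ct)
  cal <- filter(dct, .data$sample == calibrator_sample) |>
    select("gene", cal_delta_ct = "delta_ct")
  no_cal <- setdiff(unique(dct$gene), cal$gene)
  if (length(no_cal) > 0) {
    abort(paste0(
      "missing calibrator sample '", calibrator_sample, "' for gene(s): ",
      paste(no_cal, collapse = ", ")
    ))
  }
  dct |>
    left_join(cal, by = "gene") |>
    mutate(
      delta_delta_ct = .data$delta_ct - .data$cal_delta_ct,
      fold = 2^(-.data$delta_delta_ct)
    ) |>
    select("gene", "sample", "delta_ct", "delta_delta_ct", "fold") |>
    arrange(.data$gene, .data$sample)
}

#' Concordance between an association sign and allele-pair expression
#'
#' For a marker whose donor (species-B) allele is negatively correlated
#' with a trait, concordance requires the species-B allele to be
#' expressed below the species-A allele in at least one shared
#' developmental stage; for a positive correlation the ordering
#' reverses. With `strict = TRUE`, every shared stage must support the
#' sign.
#'
#' @param sign Association sign, `"+"` or `"-"`.
#' @param expression Long expression table with columns `stage`,
#'   `allele` (`"A"` or `"B"`) and `value`.
#' @param strict Require all shared stages to support the sign
#'   (default `FALSE`: at least one).
#' @return A one-row tibble: `sign`, `concordant`, `n_stages`,
#'   `supporting_stages` (list-column).
#' @export
expression_concordance <- function(sign, expression, strict = FALSE) {
  if (!sign %in% c("+", "-")) abort("sign must be '+' or '-'")
  wide <- expression |>
    filter(.data$allele %in% c("A", "B")) |>
    group_by(.data$stage, .data$allele) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "value") |>
    filter(!is.na(.data$A), !is.na(.data$B))
  if (nrow(wide) == 0) abort("no shared expression stages between the two alleles")
  support <- if (sign == "-") wide$B < wide$A else wide$B > wide$A
  concordant <- if (strict) all(support) else any(support)
  tibble(
    sign = sign,
    concordant = concordant,
    n_stages = nrow(wide),
    supporting_stages = list(wide$stage[support])
  )
}

#' Association result overview plot
#'
#' Tile plot of correlation coefficients per marker x trait and
#' environment, with significance stars overlaid.
#'
#' @param assoc An [associate_markers()] result.
#' @return A ggplot object.
#' @export
plot_associations <- function(assoc) {
  ggplot2::ggplot(
    assoc,
    ggplot2::aes(x = .data$environment, y = .data$marker_id, fill = .data$r)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      data = filter(assoc, .data$stars %in% c("*", "**")),
      ggplot2::aes(label = .data$stars), size = 3
    ) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
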