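---
title: "Methods: from MYB repeats to fiber-trait associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MYB repeats to fiber-trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberfam)
library(dplyr)
```

fiberfam traces a plant transcription-factor gene family — the R2R3-MYB
family of cotton (*Gossypium*) — from protein sequence to quantitative
fiber traits. This vignette documents the models and procedures each stage
implements, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where a rule had to be fixed.

## Repeat scanning and subfamily classification

MYB DNA-binding domains consist of up to four imperfect tandem repeats of
roughly 53 amino acids, each folding into a helix-turn-helix. Genes are
classified by repeat count: 1R, R2R3 (two repeats; the dominant plant
subfamily), 3R, and 4R.

`build_profile()` estimates a log-odds position-specific scoring matrix
(PSSM) from a gap-free seed alignment of repeats:

$$\mathrm{pssm}[p, r] = \log_2 \frac{(c_{p,r} + \lambda\, b_r) / (n + \lambda)}{b_r}$$

with counts $c_{p,r}$, background frequencies $b_r$, and pseudocount
multiplier $\lambda = 0.5$ (enough to avoid $-\infty$ on small seeds
without washing out signal). The default background is uniform over the
20 residues, which makes an uninformative column score exactly 0 bits.

`scan_repeats()` scores every length-$L$ window ($L = 53$, the canonical
repeat length; indels inside a repeat are absorbed by imperfect-match
scoring rather than modelled with insert states) and keeps windows at or
above a bit-score threshold by greedy non-overlapping selection,
descending score with ties to the leftmost start — fully deterministic.
Windows are never scored past either terminus, so a partial repeat
hanging off the end of a protein is not called. Two threshold routes
exist:

* the default, 25% of the maximum attainable window score, a fixed and
  deterministic rule that sits far above the score distribution of
  background windows and far below that of genuine repeats at ~10%
  divergence from the consensus;
* `calibrate_threshold()`, an empirical null built from per-shuffle
  *maximum* window scores; the maximum (rather than the per-window
  distribution) is used so that a threshold at the $q$-th quantile leaves
  a whole repeat-free protein hit-free with probability about $q$.

Adjacent repeats more than `max_gap = 30` residues apart are split into
separate tandem clusters, and only the largest cluster defines the
repeat count — R2 and R3 are adjacent within the domain, so a distant
isolated hit should not promote an R2R3 gene to 3R. `classify_family()`
is then a pure function of that count (0 → none, 1 → 1R, 2 → R2R3,
3 → 3R, ≥4 → 4R; the label caps at 4R).

`logo_stats()` summarises repeat conservation per column: information
content $IC_p = \log_2 20 - H_p$ with $H_p$ the Shannon entropy of the
observed column frequencies, no small-sample correction, plus the modal
residue — the statistic behind sequence-logo displays such as the
diagnostic replacement of the first R3 tryptophan by phenylalanine.

## Distances, trees and subgroup assignment

Pairwise distances are uncorrected p-distances on a supplied domain
alignment (alignment construction is out of scope; columns with gaps or
ambiguity codes are dropped pairwise). `nj_tree()` applies Saitou–Nei
neighbor joining (via `ape::nj`) and then clamps any negative
branch-length estimate to zero, transferring the deficit to its sister
branch so path lengths around the node are preserved; additive inputs
never trigger the clamp, and the suite verifies exact recovery of
generating trees against a brute-force topology search. Bootstrap
supports (`nj_bootstrap()`) are available behind a seeded flag but feed
nothing downstream.

Subgroup labels are copied from the nearest annotated reference
(`assign_subgroup()`), with ties broken by lexicographic reference id and
a distance cutoff (default 0.6 on p-distance) beyond which a query is
called lineage-specific ("G-S"): queries that have no sufficiently close
annotated relative should not inherit a label. The published 13-clade
partition of the family tree is display-level grouping with no stated
rule, so it is deliberately not re-derived.

## Ortholog loss scenarios and dN/dS

An ortholog group spans six genome roles: diploid progenitors A2 and D5
and the A/D subgenome copies of the two allotetraploids (At/Dt of AD1 =
*G. hirsutum*, At/Dt of AD2 = *G. barbadense*). The scenario taxonomy is
a fixed decision table over the $2^6 - 1$ presence patterns
(`classify_scenarios()`): retained-in-all; loss of exactly one subgenome
copy; loss of both copies of one tetraploid; diploid-only loss (all four
tetraploid copies present); loss of a subgenome copy together with its
progenitor; everything else `OTHER`. The published figure defines these
scenarios graphically, so the mapping is declared here as an explicit
rule and guarded by an exhaustive enumeration oracle in the tests.
`count_losses()` counts a group as a lost pair for a tetraploid when at
least one of its two subgenome slots is empty — groups, not genes, are
counted, and a group missing both copies counts once; counting genes
instead would double such groups.

`ng86_dnds()` implements Nei–Gojobori (1986) counting: per-codon
synonymous site fractions (mutations to stop codons count as
nonsynonymous, so sites always total 3 per codon and $N + S = 3 \times$
codons), averaged over the two sequences; observed differences averaged
over all minimal mutational pathways at multi-hit codons, excluding
pathways through stop codons (if every pathway hits a stop, the codon
contributes its raw differences as nonsynonymous); Jukes–Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined with a
warning when $p \ge 3/4$; and $\omega = dN/dS$ with the selection call
purifying/neutral/positive for $\omega$ below/at/above 1 and undefined
when $dS = 0$ (including identical sequences — never a 0/0 crash). NG86
replaces likelihood codon models deliberately: it is closed-form,
deterministic, and exhaustively checkable against a pathway-enumeration
oracle, and the downstream inference used here depends only on the
position of $\omega$ relative to 1. `subgenome_asymmetry()` reports the
median $\omega$ per subgenome, the statistic used to describe the faster
evolution of the A subgenome; no numeric value is claimed for it.

## QTL hotspots and co-localization

A hotspot is a region where at least `min_count = 4` QTL for the *same*
trait cluster within a `window = 20` cM span — the published rule.
`detect_hotspots()` anchors a candidate window at every QTL peak,
keeps windows holding ≥ `min_count` peaks, merges overlapping kept
windows of one trait (a merged hotspot may span more than 20 cM), and
reports the min–max range of member peaks. The rule is applied to peak
positions; when a QTL carries only a support interval its midpoint is
used (interval-based membership would need a containment convention the
source never states, and is left as the documented alternative).
Cross-trait windows are never merged, though their physical intervals
may overlap. Ids follow the `FL_Hotspot_c5` pattern with an ordinal
suffix when a trait has several hotspots on one chromosome.

Physical anchoring (`anchor_to_bp()`) interpolates cM → bp
piecewise-linearly between flanking marker anchors, clamping outside the
anchored range. Because real genetic maps contain local inversions,
anchors are first reduced per chromosome to the longest subsequence
jointly increasing in cM and bp (dropped markers are reported; an error
is raised only when fewer than two anchors survive). This makes the
interpolation monotone non-decreasing by construction.

All intervals are half-open on 0-based coordinates internally (GFF3
input/output converts to and from 1-based inclusive), so
`colocalize()`'s overlap test `gene.start < hs.hi && hs.lo < gene.end`
is unambiguous: a gene that merely abuts a hotspot boundary does not
co-localize. Genes on chromosomes absent from the anchor map (e.g.
scaffold-placed genes) are reported as unplaced and excluded rather than
rejected.

## SNP classification, association and expression concordance

The multi-assembly SNP rule distinguishes true interspecific variants
from accession-specific ones using seven allele sources: two reference
assemblies of the recurrent species (TM-1 by NAU and JGI), the two BIL
parents (CCRI 36, Hai 7124), the donor parent's own assembly (Hai 7124
by ZJU), and two further donor-species assemblies (Xinhai 21, 3-79). In
order: equal or missing parental alleles are unclassifiable; the site is
recurrent-parent-specific if CCRI 36 differs from *every* TM-1 assembly;
donor-parent-specific if Hai 7124 matches its own assembly *and* differs
from every other donor-species assembly; both at once is conflicting;
anything else is interspecific. The own-assembly confirmation is the
load-bearing choice: it keeps a site where one TM-1 assembly disagrees,
or where another donor accession shares the donor allele, in the
interspecific class — exactly the behaviour of the published 27-site
table, which the test suite reproduces row for row (20 interspecific in
14 genes, 3 CCRI 36-specific, 4 Hai 7124-specific).

`associate_markers()` computes the point-biserial Pearson correlation
between a 0/1 donor-allele genotype (1 = Hai 7124 allele, matching the
published sign convention) and each trait per environment, with the
two-sided p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$. Missing values
are dropped pairwise; line means per environment are the phenotype unit.
No multiplicity adjustment is applied by default — the published stars
are per-test at 0.05/0.01 — but a Benjamini–Hochberg option exists
(`adjust = "BH"`). Stability counts the environments significant at the
0.05 level, mirroring "repeated in four environments". Heterozygous
residual calls in a BC1F7 population are expected to be rare and should
be coded missing upstream. Constant genotypes or phenotypes yield an
undefined row, not an error.

`ddct()` implements relative qPCR quantification:
$\Delta Ct = Ct_{target} - Ct_{reference}$, $\Delta\Delta Ct$ against a
calibrator sample, fold change $2^{-\Delta\Delta Ct}$; replicates are
averaged before differencing. `expression_concordance()` encodes the
interpretation rule for allele pairs: a negatively associated donor
allele should be the lower-expressed copy in at least one shared
developmental stage (10/20/25 days post-anthesis in the motivating
data), and conversely for positive associations; a strict all-stages
variant is available.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its seed (each draws from its own
named substream, so adding a generator never shifts another's output)
and returns a truth table sufficient to score recovery.

* `gen_proteome()`: 200 proteins, 30% carrying 1–4 planted repeats
  (heavily favouring two, the R2R3 architecture) sampled from a fixed
  53-residue consensus at 10% per-position substitution — the "imperfect
  repeat" divergence level; background proteins are i.i.d. residues.
  Not emulated: compositional bias, low-complexity regions, homologous
  non-MYB helix-turn-helix domains; passing recovery tests therefore
  bounds performance on idealised, not real, proteomes.
* `gen_qtl_map()`: 13 chromosomes of 200 cM, five planted same-trait
  clusters (sizes 4–8, spans 5–15 cM, each on its own trait ×
  chromosome), 50 background singletons capped at three per trait ×
  chromosome and kept a full window away from same-trait clusters, so
  the truth table alone determines which hotspots exist. Anchors every
  10 cM with monotone jittered physical spacing. Not emulated:
  recombination-rate heterogeneity, shared markers between studies, or
  linkage disequilibrium structure.
* `gen_bil()`: 180 lines, four environments, donor-allele frequency
  0.25 (one backcross halves the donor share; selfing to BC1F7 fixes
  it), independent markers, trait = planted effects + environment
  intercept (SD 0.5) + unit-SD residual. Target correlations are
  converted to slopes via $\beta = r/\sqrt{1-r^2} \cdot \sigma / s_g$.
  Not emulated: linkage between markers (the real map has ~740 kb LD
  decay), genotype × environment interaction, segregation distortion.
* `gen_allele_matrix()` and `gen_ortholog_groups()` construct records
  rule-consistently for a requested class mixture or scenario count, so
  downstream recovery is exact by design; they test plumbing and
  invariants, not statistical power.
* `gen_codon_pairs()`: proposal–acceptance evolution at a target
  $\omega$ (synonymous proposals always accepted, nonsynonymous with
  probability $\omega$, stops rejected), 100 codons and 60 proposals per
  pair (~10% divergence, safely inside the Jukes–Cantor range), with
  accepted substitution counts recorded as truth.

## Numerical choices and problem sizes

Tie-breaks are deterministic everywhere: leftmost window on equal scan
scores, lexicographic reference id on equidistant subgroup references,
sorted output ordering for hotspots and co-localizations. Degenerate
inputs produce typed results rather than crashes where a result is
meaningful (short proteins → no repeats; constant genotype → undefined
association; identical CDS → undefined selection) and early errors
where it is not (empty alignments, all-absent ortholog groups,
non-monotone anchor sets reduced below two anchors).

The test suite runs the statistical checks at desk scale, chosen to keep
the full suite under a minute while leaving comfortable statistical
margins: 200-protein proteomes for scan sensitivity/specificity, 1,000
null markers for type-I calibration (binomial tolerance 0.035–0.065 at
$\alpha = 0.05$), 200 replicates for association power and for dN/dS
recovery, 20 random additive matrices against the brute-force NJ oracle,
and the complete $61 \times 61$ sense-codon table against the pathway
oracle.

## Known limitations

The scanner has no insert/delete states, so a repeat with a genuine
internal indel scores as several mismatches; profile-HMM E-values are
not computed. NG86 ignores transition/transversion bias and codon-usage
bias, which biases $dS$ slightly at higher divergence. Hotspot detection
inherits whatever positional error the source QTL carry, and peak-based
membership can split a trait's support interval across windows.
Genome-scale published counts (family sizes per genome, 48 hotspots, 86
co-localized genes, 17/48 lost pairs) depend on external genome and QTL
databases and are intentionally outside the desk-scale test surface.
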