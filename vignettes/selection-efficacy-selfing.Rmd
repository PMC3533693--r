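---
title: "Measuring the efficacy of selection across mating systems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the efficacy of selection across mating systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`selcub` tests whether transitions from outcrossing to self-fertilization
relax natural selection, using two complementary signals measured on a
four-genotype comparative transcriptome: the accumulation of deleterious
non-synonymous changes, and the erosion of selected codon-usage bias. This
vignette explains the models, the defaults, the numerical decisions, and
what the synthetic-data validation does and does not demonstrate.

## The measurement model

### Polarization

The design is a three-genotype ingroup (one outcrosser, two selfers) plus a
selfing outgroup genotype. We treat the outgroup state of each codon column
as the ancestral state (parsimony) and place derived states onto a star
topology over an ancestral branch: a derived codon shared by *all* ingroup
genotypes is a single change on the ancestral branch; a derived codon in a
strict subset is one change on each carrying terminal branch. No resolved
ingroup topology is assumed, because the quantities of interest are
per-genotype derived-change counts, not a tree.

Assumptions worth stating: (i) no ancestral polymorphism or multiple hits at
the same site along different branches (violations add symmetric noise
across lineages, since no lineage is expected to be more saturated than
another); (ii) the outgroup is homozygous where used — columns with an
ambiguous or heterozygous outgroup are skipped rather than guessed.

Heterozygous genotypes are unphased, encoded with two-base IUPAC codes. A
codon with *h* heterozygous positions is expanded into its `2^h` consistent
phasings at equal weight `2^-h` — a phase-agnostic expectation. The
published procedure — averaging counts over the two unphased haploid
sequences — does not
define the phasing of codons with two or more heterozygous sites; the
equal-weight expansion reduces to it exactly for the (overwhelmingly
common) single-het codon and is the natural generalization otherwise.
When a derived state is carried with different weights by different
genotypes, the weight shared by all (the minimum) goes to the ancestral
branch and each genotype keeps its residual — again reducing to the plain
rule for homozygous data.

Multi-position codon differences are decomposed over all minimal mutational
paths that avoid stop codons, with equal path weights (the Nei–Gojobori
convention); a change whose every path crosses a stop is excluded and
counted in the exclusion log. Codons containing `N` or 3/4-base ambiguity
codes are excluded for that genotype only; gap columns are excluded for all.
Terminal stop codons are stripped on input; an internal definite stop
invalidates the locus.

### Site counting and diversity

Potential synonymous/non-synonymous sites use Nei–Gojobori fractional
counting: each codon position contributes one site split by the fraction of
its non-stop single-base changes that are synonymous, so syn + nonsyn = 3
per codon. The published table does not state its site-counting method;
Nei–Gojobori is the field default and is what we use.

Watterson's θ_W = S/(a_n·L) is computed per locus and site class and
reported as an across-locus mean with SD. `n` counts *haplotypes*: the
default is 6 (three diploid ingroup genotypes), configurable, since a
genotype-level count of 3 is equally defensible and the published analysis
does not say which was used. Divergent sites K are sites where the outgroup
allele is absent from the ingroup allele set. Variable sites are classified
synonymous/non-synonymous in the outgroup codon context. Pairwise
differences weight heterozygous sites by allele frequencies (0.5/0.5), which
is what produces half-integer totals.

### Codon-usage bias

RSCU is the codon count divided by its synonymous-family mean; families
with zero counts are flagged undefined, never silently zero. ΔRSCU
contrasts mean per-gene RSCU between the top and bottom expression deciles
(default quantile 0.1 of the cross-genotype mean expression; per-genotype
expression gives the same partitions in practice and is available). The
per-codon test is a one-way ANOVA whose replicates are *per-gene* RSCU
values; the alternative (per-codon-occurrence replicates) pseudo-replicates
sites within genes and is not offered. Genes lacking a codon's amino acid
are excluded from that codon's test.

**Multiple testing.** Optimal-codon calls are BH-adjusted across the 61
codons by default (`p_adjust = "none"` reproduces the unadjusted published
procedure). The package's own neutral-limit requirement forced this choice:
with 61 correlated tests per genotype and four genotype tables that are
nearly copies of one another (they share the ancestral sequence and the
expression partition), an unadjusted α = 0.05 plants at least one false
"optimal" codon in most *neutral* datasets, and a method that manufactures
codon-bias signal from noise cannot be used to compare bias across
genotypes. Under BH the neutral consensus set is empty in ≥95% of
replicates (tested), while genuine planted signals — whose p-values are
many orders of magnitude below α — are unaffected.

The consensus optimal set intersects the per-genotype sets and keeps, per
amino acid, the codon with the greatest mean ΔRSCU (alphabetical
tie-break, for determinism). The per-genotype union and the one-per-amino-
acid consensus are distinct outputs, as the published analysis reports one
count for the former (24) and uses the latter (18). Fop divides the
(weighted) count of consensus codons by the count of codons in degenerate
families — Met, Trp and stops excluded from the denominator, the
conventional definition, stated here because it is often left implicit.
ΔRSCU⁺ is the mean of a genotype's positive ΔRSCU values; its inferential
layer (genotype and mating-system ANOVAs, Tukey–Kramer, selfers-combined t)
runs on log-transformed values.

### Deleterious-change classification

The classifier is an explicitly simplified constraint method, not a
re-implementation of MAPP: no tree weighting of homolog sequences and no
published score calibration. Each homolog-alignment column gives per-scale
means and SDs over six physicochemical scales (Kyte–Doolittle hydropathy;
Grantham polarity; net charge; Zamyatnin side-chain volume; Chou–Fasman
helix and sheet propensities — all hard-coded with provenance in
`default_property_scales()`). A candidate amino acid's deviation is
`D(a) = Σ_p ((s_p(a) − μ_p) / max(σ_p, floor_p))²`, compared against
τ = the 95th percentile of χ² with df = number of scales. The σ-floor
(default 0.1 × the scale's SD across the 20 amino acids) prevents
zero-variance columns from dividing by zero; it deliberately keeps
invariant columns *strict* — at a perfectly conserved column essentially
only the observed residue is compatible, which is the behaviour a
constraint method should have there. The corollary, verified in the test
suite, is that at weakly constrained (free-drifting) columns the classifier
still flags roughly a quarter of candidate residues: constraint methods
over-call at poorly constrained sites, and results at such positions should
be read accordingly. Both τ and the floor are configuration, and externally
computed good/bad tables (e.g. from full MAPP) can replace the internal
profiles entirely.

Loci enter the deleterious analysis only with ≥5 homologs and mean identity
to the focal sequence strictly >60%. Two modes mirror the published design:
polarized (label each derived non-synonymous change) and polymorphic-site
(label each genotype's allele at ingroup amino-acid polymorphisms,
sidestepping ancestral-state error).

### Statistics

χ² homogeneity tests are plain Pearson without continuity correction;
fractional counts from heterozygote averaging are used as-is (with a logged
caveat; a strict-integer path is available by excluding heterozygous
changes). Standard degrees of freedom are always used — (r−1)(c−1) — even
though the published report mixes 1 and 2 DF for structurally identical 2×2
contrasts; recomputing the published 2×3 deleterious-count test with plain
Pearson also gives 11.52 rather than the printed 8.15 (the printed p is
consistent with the printed statistic, so the original test construction
differed in some unstated way; ours is the textbook one). Backward
elimination in the Fop model drops, at each step, the non-significant
droppable term with the largest p (ties by name), making the elimination
path deterministic; marginality is respected via `drop1`.

## The synthetic-data generator

The generator is the package's ground truth, not a fixture: it emulates the
statistical structure the analysis assumes and plants known effects.

* **Selection via fixation weights.** Mutation proposals (Poisson per
  branch, transition:transversion bias κ = 2) are accepted with probability
  proportional to the Kimura relative fixation rate f(ΔS) = ΔS/(1−e^(−ΔS)).
  This generates the rate asymmetries the analysis measures without
  simulating explicit Wright–Fisher populations, which would be orders of
  magnitude slower and add nothing the pipeline can see.
* **Codon bias.** One preferred codon per degenerate amino acid (G/C-ending
  where available, mirroring plant optimal codons), ancestral sequences at
  codon equilibrium π ∝ exp(S_g·1[preferred]), S_g = S_max · F(E_g) with F
  the expression CDF — bias concentrated in highly expressed genes, which
  is exactly the contrast ΔRSCU exploits. Default S_max = 2.
* **Deleterious changes.** A non-synonymous proposal carries a
  Gamma-distributed cost (shape 0.6, mean 2, times ν) when it violates the
  planted constraint: the derived residue is incompatible with the column
  consensus at a constrained position (constrained fraction 0.7, Bernoulli
  p_del = 0.8 given violation). Coupling the fitness cost to the planted
  physicochemical constraint is essential: if costs were assigned to random
  non-synonymous changes, the constraint classifier's label would be
  statistically independent of fitness, and no mating-system contrast in
  *measured* deleterious fractions could exist even in principle.
* **Efficacy multipliers.** Every selective effect on a branch is scaled by
  ν: 1.0 on the outgroup, ancestral and outcrosser branches, 0.2 on the two
  selfing terminal branches. This is the planted "reduced efficacy of
  selection", the recovery of which is the package's headline validation.
* **Heterozygosity** is injected post-hoc at independent sites (one per
  codon, never creating a stop phase) at the observed per-genotype rates
  (9.8×10⁻⁴ outcrosser, 1.8×10⁻⁴ and 0.8×10⁻⁴ selfers, 0 outgroup) —
  appropriate because the pipeline treats heterozygotes as unphased anyway.
* **Branch lengths** (expected proposals per codon): 0.2 outgroup, 0.1
  ancestral, 0.12 terminals. The terminal length is a designed power
  choice: the outcrosser's higher heterozygosity *dilutes* its measured
  ΔRSCU⁺ (random het alleles pull usage toward uniformity), an effect that
  at very short terminal branches is the same size as the selfers' planted
  erosion signal. At 0.12 the planted contrast dominates the dilution. This
  interplay is itself a caution for real data: H_obs differences between
  mating systems bias ΔRSCU⁺ contrasts toward the null or beyond.
* **Problem sizes.** Default study conditions are 2000 genes × 200 codons
  (per-branch validation replicates run at this scale); neutral-null
  replicates run at 600 genes × 120 codons, where the false-signal
  properties being tested do not depend on scale.

Every accepted change is recorded in a ledger (branch, locus, codon, from,
to, class, bias, deleterious, order); replaying the ledger from the root
reproduces each tip byte-identically, and with single-hit codons, an exact
outgroup and no heterozygotes the pipeline's branch counts equal the ledger
exactly. Both properties are asserted in the test suite.

**What passing these tests shows — and does not.** The generator matches the
analysis' assumption set by construction: free recombination between loci,
no linkage or hitchhiking, no demography, independent het sites, a star
ingroup topology, homolog columns that are either strictly conserved or
free. Recovery of planted effects therefore validates the *measurement
machinery*, not the biological assumptions; on real data, ancestral
polymorphism, shared derived states from incomplete lineage sorting,
expression-estimation noise and alignment error all add structure the
generator deliberately omits.

## Degenerate inputs and tie-breaks

* Ratios with zero denominators (P_N/P_S, U2P/P2U, deleterious fractions,
  Fop, GC3s) are NA with an undefined flag, never 0.
* Expression partitions break ties by gene id; an all-tied table is flagged
  degenerate.
* ANOVA with zero within-group variance but distinct means reports F = ∞,
  p = 0, flagged degenerate (arising, e.g., for codons used exclusively in
  one expression class).
* Codon indices are 0-based internally via integer codes 1–64; all reports
  are 1-based.
* All randomness flows from the single mandatory seed in `sim_config()`;
  the analysis itself is deterministic.

## Limitations

* The constraint classifier is a stand-in: absolute deleterious fractions
  depend strongly on τ, the σ-floor and the scale set, and should be
  compared *across genotypes within a run*, not across studies. Plug in
  real MAPP output for absolute calibration.
* Fractional χ² counts from heterozygote averaging mildly overstate the
  effective sample size; with heterozygosity this low the effect is
  negligible, and the heterozygote-excluded mode exists for sensitivity
  analysis.
* U2P/P2U on the ancestral branch conflates changes on that branch with
  changes along the outgroup's own terminal history (a single outgroup
  cannot separate them); the same caveat applies to the published design.
* ΔRSCU⁺ inherits selection bias from conditioning on positive ΔRSCU; it is
  used only comparatively, between genotypes measured identically.
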