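---
title: "Methods: detecting and characterizing neo-sex chromosome evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing neo-sex chromosome evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a Y chromosome fuses to an autosome, the autosomal arm becomes a
neo-sex chromosome pair: the copy transmitted through males (the neo-Y)
stops recombining with its homolog (the neo-X) and begins its own
evolutionary trajectory — accumulating nucleotide differences from the
neo-X, possibly degenerating, and potentially becoming a hotspot for
divergence between incipient species. `neosexscan` implements the standard
resequencing toolkit for interrogating such a system: sex-differential read
depth for degeneration, heterozygosity scans for X–Y divergence, stratified
genotype-pattern rules for assigning variants to the X or Y lineage,
counting-based dN/dS for coding consequences, and expression-bias
enrichment — all validated against a synthetic-data generator with exact
per-site truth.

The sampling design the defaults encode is five focal-species males, five
focal-species females, one sister-species male, five sister-species females
and one outgroup female; all rules are expressed in terms of these roles and
work for any counts the rules' quantifiers admit.

# Coverage analysis

Depth is handled in fixed-width bins (default 10 kb; bin size 1 reproduces
per-position semantics). Every statistic derived from coverage —
chromosome means, window differences, mask denominators — is a mean or
count over intervals, computed from per-bin prefix sums. Normalization
divides a sample's depth by its total mapped read count, making tracks
comparable across libraries; chromosome means are taken over covered
(depth > 0) positions only, because zero depth marks repeat-masked or
unmappable sequence whose inclusion would dilute the signal (the
full-length mean is reported alongside since both conventions exist).

Degeneration is a chromosome-scale hypothesis: a hemizygous (Y-deleted)
region halves male depth but leaves females untouched. Each candidate
chromosome is tested per sample with a Grubbs outlier test against the
autosomes, `G = |x_c - mean| / sd` with the two-sided p-value from the
closed-form t relation `t^2 = n(n-2)G^2 / ((n-1)^2 - nG^2)`,
`p = min(1, 2n P(T_{n-2} > t))`. A candidate is called *degenerate* only
when every male is an individually significant low outlier and no female is
significant. The default screening level is `alpha = 0.01`: the decisive
published outliers in this setting are reported at P < 0.001, several
chromosomes are screened per genome, and 0.01 is the conventional
conservative choice. The 500-kb / 100-kb male−female window scan localizes
the deleted span; `locate_coverage_deficit()` takes the run of windows
below the midpoint between the chromosome's baseline (median) and a robust
deficit level (the median of the depressed windows), then refines each edge
by interpolating the threshold crossing between adjacent window values —
window means are piecewise linear in the overlap with the deleted span, so
the crossing plus half a window estimates the edge with sub-step error.
Validation overlays the five male-female pair tracks the sampling design
provides (averaging the pairwise differences), which brings the median
boundary error to ~20 kb against the 100-kb step.

# Site masks and heterozygosity scans

Heterozygosity estimates are biased by depth in both directions: low depth
under-calls heterozygotes, and very high depth signals collapsed duplicates
whose paralogous variation masquerades as heterozygosity. Positions are
therefore usable only when **every** role sample's depth lies within the
mask bounds — strict (20, 200) for heterozygosity and X/Y-specific SNP
analyses, loose (10, 500) for the remaining analyses. The bounds are
inclusive: depth 19 is masked, 20 and 200 are kept. Tightening bounds never
unmasks a position, and the strict-usable set is a subset of the
loose-usable set (tested as an invariant). Which samples gate the mask is a
configuration choice; the default gates on all role samples jointly, the
conservative reading.

Window values are heterozygous-site counts divided by usable base pairs;
windows with no usable positions are flagged and excluded from downstream
summaries. The genome-wide SNP rate counts homozygous-alt sites as 1 and
heterozygous sites as 0.5 per the standard allele-dose convention.

The fusion gradient partitions the neo-sex chromosome into 1-kb right-open
bins and fits a binomial logistic regression (IRLS, tolerance 1e-8, max 100
iterations) of per-bin heterozygous proportion on the bin midpoint's
distance from the fusion end. Negative β means decline away from the
fusion. For the exponentially decaying generator truth
`p(d) = p_max exp(-d/s)` with small `p`, the logit is ~ `log p`, so the
fitted slope converges to approximately `-1/s`; tests compare the estimate
against the probability-limit slope obtained by fitting the noise-free
expected counts, not against `-1/s` itself, since the logit and log links
differ at second order. Complete separation is flagged on the fit rather
than reported as a finite slope.

# Diagnostic SNP patterns

With a non-recombining neo-Y shared by all sampled males, X–Y divergent
sites show fixed, fully stratified genotype configurations:

* **X-specific** — other-species females homozygous for one allele, focal
  females homozygous for the other, all focal males heterozygous;
* **Y-specific** — both female groups homozygous for the same allele, all
  focal males heterozygous;
* **shared** (on both X and Y) — focal males and females homozygous for one
  allele, other-species females for the other.

Eligibility requires complete non-missing genotypes for every role sample
and a mask pass; everything else is `unclassified` — missingness is never
imputed and quorums are never relaxed, because the published rules
quantify over *all* sampled individuals. The categories partition the
eligible sites by construction (tested as an invariant). Fixed differences
and within-species polymorphism use the two species' female panels: a
fixed difference has all females of each species homozygous for different
alleles; a species is polymorphic at a site when at least one of its
females is heterozygous or carries a divergent homozygote.

# Codon-level analyses

PAML-style maximum-likelihood codon models are replaced by Nei–Gojobori
(NG86) counting. At the divergences this pipeline targets (~1.5% between
species, Ks ≤ 0.1) counting and ML agree closely and the downstream
inferences are rank and ratio comparisons; outputs record
`method = "NG86-two-ratio"`. Conventions:

* per-codon synonymous site fractions from the standard code, with
  mutations to stop codons counted as nonsynonymous — this keeps
  `N + S = 3 × n_codons` exactly;
* codons differing at multiple positions are averaged over all orderings of
  single-nucleotide steps, excluding orderings passing through a stop
  codon (with a guarded fallback to all orderings, unreachable for sense
  pairs at ≤ 2 differences);
* proportions are Jukes–Cantor corrected, `d = -3/4 log(1 - 4p/3)`;
  `p ≥ 3/4`, `Ks = 0`, or empty branches yield undefined-flagged values
  rather than drops, and summaries report both conventions;
* no transition/transversion weighting (plain NG86).

Virtual X/Y haplotypes for a male are built by substituting homozygous-alt
calls into both copies and assigning each heterozygous site's alt allele to
one haplotype by an independent fair coin under a seed; consensus haploid
sequences resolve heterozygotes the same way and always equal one of the
two virtual haplotypes. The two-ratio model assigns substitutions among
focal, sister and outgroup sequences by parsimony (the odd sequence's
branch; outgroup-odd changes belong to the background), reconstructs the
per-codon ancestral codon, counts per-branch (Nd, Sd) by pathway averaging
against it, and uses the ancestral sequence's site totals. Codons with
three alleles at a position, ambiguity, or stops are excluded and counted.

A counting estimator of ω = (Nd/N)/(Sd/S) carries O(1/Sd) upward bias from
the reciprocal of a small count (plus conditioning on Sd > 0). Validation
therefore uses genes long enough to keep Sd ≈ 20–30 (500–800 codons at
Ks ≈ 0.05), where the bias is a few percent; this is a property of any
ratio-of-counts estimator, not of the implementation.

# The synthetic-data generator

`simulate_dataset()` emulates the study conditions: 20 autosomes of 2 Mb
(scaled down from ~20-Mb chromosomes; chromosome count, not length, drives
the outlier tests), a 20-Mb ancestral sex chromosome with a 6-Mb deleted
span at male depth factor 0.5, and an 18-Mb neo-sex chromosome whose X–Y
divergent sites arise at per-bp probability `p_max exp(-d/scale)` with
`p_max = 0.01` and `scale = 5 Mb` (a logistic decay is available; the
published pattern is a monotone decline without a stated functional form,
and the exponential is the minimal one-parameter choice). Fixed
inter-species differences and within-species polymorphism arise at
5×10⁻⁴/bp (divergence between the two species in this system is ~1%, about
half fixed; polymorphism is scaled to remain desk-sized), with focal
polymorphism on the neo-sex chromosome reduced by factor 0.4. Outgroup
divergence is 5×10⁻³/bp (the real outgroup is ~5% diverged; one order
scaled down). Depth is Gamma-distributed per bin around a per-sample mean
drawn within ±20% of 50× (the published per-fish coverages span 40–74×),
with 2% of bins zeroed as repeat-masked, shared across samples.

Polymorphic sites draw derived-allele counts from a neutral-like 1/i
spectrum and scatter copies over chromosome slots. Configurations that
would exactly reproduce an X-/Y-specific/shared diagnostic pattern
(probability ~10⁻⁴ per site) are resampled so that every truth label maps
to a unique observable pattern; real data offer no such guarantee — which
is precisely why the field calls these categories *putative* — so exact
precision/recall on synthetic truth validates the machinery, not the
biological error rate. On the ancestral chromosome's deleted span, male
heterozygous polymorphisms are re-called homozygous at halved depth,
matching how mapped hemizygous data present. Focal-species fixed
differences on the neo-sex chromosome are labelled `shared` (they are
exactly the shared-by-X-and-Y class).

Coding variants choose their effect class *first* — nonsynonymous weighted
by the category's dN/dS against the gene's opportunity counts — then draw a
uniform (position, allele) change of that class within the gene, so the
realized nonsynonymous fraction is `ωN/(ωN+S)` in expectation. The default
per-category ω (Y-specific 0.35, X-specific and shared 0.2) are calibrated
from the published nonsynonymous SNP proportions (0.511, 0.381, 0.386) via
that identity with opportunity ratio N/S ≈ 3. Intergenic reference sequence
is uniform filler; no computed statistic depends on intergenic content.
Gene density defaults to 20 genes per chromosome (scaled from ~1,100 per
linkage group on the real array); enrichment power simulations use 300 per
chromosome for stable per-chromosome proportions.

What the generator does *not* emulate: linkage disequilibrium and
recombination maps, genotype-calling error, alignment artifacts, GC or
mappability bias beyond the zeroed bins, and indels (the pipeline's rules
exclude indel regions upstream). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to real-data artifacts.

# Expression analyses

Normalization follows the literal three-step array procedure: divide each
array by its 75th percentile (linear-interpolation quantile), log2,
then divide each probe by its median log value. The third step is
numerically fragile when the median is near zero — the quotient's sign and
scale become unstable — so probes with |median| < 0.05 are excluded and
counted rather than silently distorted; this is fidelity to the stated
procedure with a guarded failure mode, and the bias *calls* (which depend
only on per-gene F tests) are insensitive to it. Per-gene bias calling is a
one-way ANOVA across groups (pooled-variance t-test for two groups,
F = t²), computed row-vectorized and verified against `oneway.test`
exactly; the default threshold is the conventional P < 0.01, and null
simulations confirm the false-positive rate matches alpha. Tissue-specific
sets are presence-in-gonad-and-absence-in-brain, with presence calls from a
one-sided t-test against background signals (P < 0.001) or an externally
supplied boolean table. Enrichment per chromosome reuses the same Grubbs
machinery as the coverage screen. Upstream heterozygosity windows are
strand-aware (5′ of the TSS; 10-kb default with a 3-kb variant).

# Numerical and design notes

* Windows start at 1, 1+step, … while a full window fits; a chromosome
  shorter than the window yields one truncated window flagged `partial`.
  BED output is 0-based half-open; all internal coordinates are 1-based
  inclusive.
* Sliding scans with step = window tile the genome and their
  denominator-weighted mean reconstructs the chromosome value exactly
  (tested).
* Assembly-layout remapping (for reference chromosomes with misoriented
  supercontigs) is an involution on inverted blocks, `p -> start+end-p`;
  positions outside all blocks are unplaced and excluded from scans.
* Exact Mann-Whitney enumeration is used for tie-free samples with
  min(n, m) ≤ 8, midrank normal approximation with tie correction
  otherwise; Fisher tests are two-sided by summing tables no more probable
  than the observed one; Grubbs is two-sided (both depleted coverage and
  elevated heterozygosity directions occur).
* No multiple-testing correction is applied anywhere; raw p-values are
  reported, matching the screening character of the analyses.
* Validation problem sizes: 61×61 codon pairs exhaustively; 200 genes per
  Ka/Ks recovery condition; 100 replicates × 200 genes for the two-ratio
  rank check; 100 replicates each for deletion detection (21 × 20-Mb
  chromosomes) and gradient recovery (18-Mb chromosome, 1-kb bins); a 1e5
  replicate Monte-Carlo null for Grubbs calibration.

# Known limitations

The two-ratio counting model approximates but does not reproduce ML branch
models; at divergences approaching saturation the Jukes–Cantor correction
and parsimony assignment both degrade. The deficit localizer assumes a
single dominant deficit region per chromosome. The expression model treats
arrays as independent and carries no probe-sequence bias. The generator's
truth guarantees are exact only because collision configurations are
resampled; quantitative error rates on real data require error-aware
simulation outside the present scope.
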