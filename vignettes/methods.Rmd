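---
title: "Methods: multiregion clonality, subtyping, phylogenies and signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiregion clonality, subtyping, phylogenies and signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastroITH)
```

# The problem

Bulk sequencing of a single tumor biopsy conflates two very different kinds
of mutation: truncal (clonal) events present in every tumor cell, and
regionally restricted (subclonal or private) events acquired during
progression. Multiregion designs sequence several spatially separated
biopsies per tumor (here 2–6, separated by > 3 cm, on a targeted panel at a
few hundred-fold depth) precisely to separate the two. This package
implements the downstream analysis of such a design for gastric cancer:
clonality classification with rescue of censored calls, TCGA molecular
subtype assignment, clonal phylogenies, clonality-stratified mutational
signature refitting, rule-based pathogenicity/druggability annotation and
cohort statistics — each stage validated against an independent oracle or a
simulator with known ground truth.

# Clonality classification

Per-biopsy calls are merged on the normalized variant identity
(chrom, pos, ref, alt); indels are treated exactly like SNVs. With $k$ of
$n$ tumor biopsies carrying a variant:

* CLONAL if $k = n \ge 2$;
* SUBCLONAL if $1 < k < n$;
* PRIVATE if $k = 1$ and $n \ge 2$;
* NONE otherwise.

NONE is the label for aberrant cases. In this data model only two exist — a
variant with no presence left after merging, and patients with a single
tumor biopsy, for whom clonality is simply unassessable — so NONE is defined
as exactly those. NONE-labelled variants are excluded from all percentage
denominators. The classifier is tested against an exhaustive enumeration of
every presence vector up to $n = 6$.

## Forced-call rescue

Apparent absence of a mutation in one biopsy is often pseudoheterogeneity:
the variant is present but its allele fraction is pushed below the caller's
sensitivity by allele-specific imbalance, heterogeneous amplification or low
regional purity. When at least one sister biopsy carries a call, each absent
biopsy is re-examined against four gates, all exposed in `rescue_params()`:

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 20 | reads | below this the biopsy is *unevaluable*, never rescued |
| `min_alt_reads` | 3 | reads | minimum mutant evidence |
| `min_vaf` | 0.01 | fraction | guards against mutant reads diluted by depth |
| `max_binomial_p` | 0.01 | probability | upper tail $P(X \ge \mathrm{alt} \mid \mathrm{depth}, e)$ with per-base error $e$ = `error_rate` = 0.001 |

The binomial gate asks whether sequencing error alone could plausibly
produce the observed mutant reads; at 336× and $e = 10^{-3}$, 4 mutant reads
in 200 give a tail probability near $6\times10^{-5}$ and are rescued, while
1–2 reads are not. The thresholds are deliberately conservative at panel
depth; they are not published values, which is why every one is a parameter.
Rescue runs before classification (it exists to correct clonality), is
monotone in its thresholds, and never removes a called presence.

# Molecular subtype assignment

The TCGA gastric scheme is a priority cascade, applied to patient-level
evidence:

1. **EBV** if the EBV on-target read fraction $\ge$ `ebv_min` ($10^{-4}$ —
   the panel carries EBV sequence, so true positives sit orders of magnitude
   above index-hopping bleed-through);
2. else **MSI** if the MSI score $\ge$ `msi_min` (3.5, the conventional
   MSIsensor cutoff, in units of percent unstable loci);
3. else **CIN** if the CNV-altered panel fraction $\ge$ `cin_min` (0.20 at
   $|\log_2| \ge 0.3$);
4. else **GS**.

The MSI score is a simplified MSIsensor: per microsatellite locus, tumor and
normal repeat-length histograms are compared with a chi-square homogeneity
test on the $2 \times L$ table, adjacent length bins pooled left-to-right
until every expected cell is at least 1 (p = 1 if a single pooled bin
remains); loci with both histograms under `min_locus_coverage` (20 reads)
are unassessable, at least 20 assessable loci are required, p-values are
Benjamini–Hochberg adjusted across loci within the tumor–normal pair, and
the score is 100 × unstable/assessable. The CNV-altered fraction is the
interval union (via GenomicRanges) of qualifying segments intersected with
the panel, so overlapping segments are never double-counted.

Two choices here were genuinely open. How per-biopsy evidence combines into
one patient call is not standardized; the package takes the maximum EBV
fraction, the maximum MSI score and the mean altered fraction — maxima
because one EBV-positive or MSI-high region is biologically decisive, the
mean for CNV because chromosomal instability is a genome-wide property. And
the CIN/GS boundary (0.20) has no published reference rule; it is the
weakest link for real-data concordance and is exposed as a parameter for
sensitivity analysis.

# Clonal phylogenies

Each distinct nonempty biopsy presence bitmask becomes a candidate edge with
length equal to its mutation count. A set of patterns admits a perfect
phylogeny exactly when every pair of bitmasks is nested or disjoint.
Conflicts are resolved greedily: sort by descending count, ties by smaller
bitmask integer (a deterministic, biopsy-order-based tie-break), accept a
pattern iff compatible with everything accepted. With at most 6 biopsies a
patient has at most 63 patterns and usually far fewer; the greedy is
transparent, and the test suite compares it against a brute-force
maximum-count search on realistic instances (tree-consistent majority plus
small conflicting noise patterns), requiring at least 90% of the optimum and
logging any instance below that. Dropped patterns are returned and written
to a conflict report, never silently discarded.

The tree is the Hasse diagram of bitmask containment rooted at the full
mask: the trunk carries the clonal count (inserted at length 0 when no
clonal mutations exist), every biopsy appears as a leaf (length 0 when it
has no private mutations), and the sum of edge lengths equals the number of
retained mutations. Newick output writes the trunk as the root branch
length; `ape` is used in tests as the round-trip oracle. There is no single
standard algorithm for drawing such trees from presence data, so this
construction is the package's own, chosen for exact count conservation and
auditability.

# Mutational signatures

Spectra are counted over the standard 96 pyrimidine-centered trinucleotide
substitution classes in COSMIC lexicographic order; purine-reference records
are reverse-complemented at binning time (contexts are stored on the
reference strand, so there is a single canonicalization point). Non-SNVs and
missing contexts are skipped and counted; a context whose middle base
contradicts the reference allele is a validation error.

Refitting follows the forward-selection scheme of deconstructSigs-style
tools: starting from zero weights, each iteration line-searches every
catalog signature's single weight on $[0, 1]$ (Brent/golden-section via
`optimize`, absolute tolerance $10^{-5}$, endpoints checked explicitly)
against the sum of squared errors between the re-normalized reconstruction
and the observed frequencies, and adopts the best signature; ties break by
catalog order. Iteration stops when the best decrease in reconstruction
error — the *root* of the SSE, the scale on which such tools state their
stopping threshold — falls below `tol` ($10^{-3}$). Stopping on raw SSE at
this threshold would terminate after one or two signatures, since SSEs of
frequency vectors live at $10^{-3}$ and below; the error scale is the
interpretation under which the published default is meaningful, and the
monotone non-increase of SSE is asserted inside the fitter. Weights below
`cutoff` (0.06, the conventional reporting floor) are zeroed and survivors
renormalized to 1; spectra under `min_mutations` (20) are refused, and in
stratified fits such cells are reported as "insufficient" rather than
fitted.

Stratified analysis pools mutations across patients within each
(group, clonality-stratum) cell before fitting, because stratum-level
statements ("clonal mutations in this subtype were dominated by …") are the
scientific target; per-patient fits remain available by grouping on patient
id. No opportunity-renormalization (exome vs genome context abundance) is
applied: catalog and spectrum are treated as directly comparable, a
documented limitation.

**The bundled catalog is synthetic.** The gastric-relevant COSMIC v3.2
subset used in this field (SBS1, 3, 4, 5, 6, 10b, 15, 18, 21, 24, 26) is
licensed reference data that is not redistributed here;
`synthetic_signature_catalog()` builds deterministic stand-ins with the same
names and qualitatively similar shapes (SBS1 peaked at [C>T]G, SBS4 loading
C>A, a featureless SBS3, MMR-deficiency-like C>T/T>C subsets, …), each
placing 80% of its mass on a characteristic context set and the remainder
uniformly. Tests and the simulator run against it; real analyses should
load the published catalog with `read_signature_catalog()`. One behavior
worth knowing either way: a featureless (flat) signature can absorb
multinomial sampling noise in small spectra — at a few thousand mutations a
flat signature may pick up weight near the 6% cutoff that vanishes as the
pool grows — so stratum fits should pool thousands of mutations where
possible.

# Cohort statistics

Percentages and reported means are rounded half-away-from-zero
(`round_half_up`), matching how such tables are printed; raw values are
always returned alongside. "Advanced stage" means AJCC III or IV, with
known-stage patients as the default denominator (an all-patients variant is
exposed). The two-sample *t* defaults to the pooled-variance Student form
(Welch optional) and drops missing values with a count. One documented
discrepancy: on the bundled clinical table, the Colombian versus
Mexico-plus-US age comparison reproduces the reported group means (54.6 vs
66.9 years), but a pooled Student *t* yields p ≈ 0.009, not the p = 0.020
previously quoted for this cohort, and no simple regrouping of the printed
ages re-derives that value; the implementation reports what it computes
rather than tuning the grouping to match.

The Freeman–Halton test generalizes Fisher's exact test to r×c tables: the
p-value is the total conditional probability, over all tables with the
observed margins, of tables whose probability does not exceed the observed
table's (probability-ordering rule; equality admitted within a relative
slack of $10^{-12}$ in log space, so ties count as they should). Full
enumeration is used up to total n = 40; above that, margin-preserving
Monte Carlo with base R's Patefield sampler (`r2dtable`, default $10^6$
draws, chunked, fixed seed). The 2×2 case is cross-checked against
`fisher.test` in the suite, and enumeration against Monte Carlo within
three binomial standard errors.

# The synthetic cohort generator

The generator is the package's test instrument: it emulates the study
conditions and carries full ground truth, so every downstream stage has a
recovery-based test. Defaults are the study conditions and are set once:

* subtype mix 2:4:12:14 over EBV/MSI/CIN/GS (the observed 32-patient
  cohort); 2–6 biopsies per patient;
* mean mutation burden per patient: MSI 170, EBV 25, CIN 26, GS 22
  (Poisson); clonal fraction EBV 0.34, MSI 0.36, CIN 0.27, GS 0.27, the
  nonclonal remainder split subclonal:private as 16:52 (the cohort-wide
  split; the per-subtype split is not reported anywhere, so the cohort
  ratio is the neutral extrapolation); subclonal carrier subsets uniform
  over sizes 2 to n−1;
* diploid VAF model: expected VAF = purity × CCF / 2, purity uniform on
  (0.3, 0.7), CCF 1 in carrier biopsies (no multiplicity or copy-number
  distortion of VAF — the simplest model that creates the censoring the
  rescue targets); depth Poisson(336); carrier alt reads
  Binomial(depth, VAF); non-carrier biopsies carry error reads
  Binomial(depth, 0.001);
* pseudoheterogeneity: each carrier biopsy's expected VAF is suppressed by
  a factor of 0.1 with probability 0.15, modelling allele-specific
  imbalance/heterogeneous amplification. Without this, a 336× panel never
  censors a purity-0.3 clonal variant and there would be nothing for the
  rescue to do; with it, suppressed sites carry a handful of mutant reads
  that sit below the caller threshold but above the rescue gates;
* caller emulation: a carried variant is emitted once it has at least
  `caller_min_alt` = 8 supporting reads. The emulated caller knows carrier
  status, so it models sensitivity censoring only, never false positives;
  error reads still appear in the emitted read counts, where the rescue
  gates must reject them. Setting `caller_min_alt = 0` therefore yields
  perfect observation, the no-censoring oracle used in tests;
* evidence channels, chosen once to be well separated from the decision
  thresholds: MSI patients shift 20% of 100 microsatellite loci by 3
  repeat units (score ≈ 20 vs cutoff 3.5; 100 loci keep the null
  false-positive score safely below the cutoff); CIN biopsies carry
  segments at $|\log_2| \ge 0.58$ covering 40% of the panel (vs cutoff
  0.20 at 0.3); EBV patients have read fraction $10^{-2}$ vs $10^{-6}$
  bleed-through (cutoff $10^{-4}$);
* a deterministic synthetic panel: 375 targets of 10 kb (3.75 targeted
  Mbp) and 150 genes with right-skewed CDS lengths of 0.5–12 kbp.

All draws consume a single stream seeded from `seed`, in a fixed documented
order (per patient: subtype, biopsy count, purities, mutation count, then
per mutation label/subset/context/effect/position and per-biopsy reads,
then CNV, MSI, EBV evidence), so identical configurations are
byte-identical.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (no FASTQ/BAM, no mapping or
strand bias), germline contamination and panel-of-normals filtering,
copy-number-driven VAF distortion and multiplicity, caller false positives,
inter-locus correlation in microsatellite instability, and real signature
flat-vs-peaked confusability (the synthetic catalog is better conditioned
than COSMIC). Recovery results on it are evidence of implementation
correctness, not of field performance.

# Problem sizes and runtime

The test suite and the acceptance script run on desk-scale inputs chosen to
keep the full suite around a minute: cohorts of 8–32 patients for
end-to-end runs, 200 patients for the binomial-rate property, spectra of
10,000 mutations for refit recovery (each fit takes seconds), brute-force
parsimony oracles on up to 12 patterns, and exact Fisher enumeration up to
n = 40. Every statistic derived from the bundled 32-patient clinical table
recomputes in well under a second.

# Known limitations

* No CCF or subclone inference (no clustering of VAFs); clonality is purely
  presence/absence after rescue.
* The CIN/GS threshold is a package choice, not a published rule; treat
  CIN/GS concordance on real data with care.
* Signature refitting inherits forward selection's known behaviors:
  greedy order dependence, flat-signature noise absorption in small
  spectra, and no context-opportunity renormalization.
* The tree construction is a stand-in for an undescribed original method;
  it is exact on conflict-free data and conservative (auditable drops)
  otherwise.
* "Complete deletion / wild-type allele loss" requires an explicit upstream
  LOH flag; the package never infers LOH from segment data.
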