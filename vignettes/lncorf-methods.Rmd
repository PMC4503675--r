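---
title: "Models and methods behind lncorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncorf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lncorf` implements a trilogy of analyses about genes born *de novo* from
ancestral lncRNAs: how they **emerge** (ORF dating from cross-species codon
alignments), why they are **retained** (neutral ORF lifespan driven by GC
content), and whether they are under **selection** (population-genetic
contrasts between coding and matched non-coding sequence). This vignette is
the package's own account of the models, the parameters that matter, the
numerical choices, and what the synthetic data can and cannot show.

## Coordinates and formats

All internal coordinates are 0-based half-open (the BED convention); VCF
positions are converted at the file boundary and back on write. A single
convention removes the off-by-one ambiguity that otherwise creeps into
region intersection and codon placement. Multi-allelic VCF records are
decomposed into biallelic records that downstream statistics treat
independently; genotypes on the non-focal alternative allele become missing
for that record. Missing genotypes reduce the chromosome count *n* of that
site only. Sites whose ancestral-allele annotation (`AA=`) matches neither
observed allele are flagged `unpolarizable` and excluded from spectra but
counted and reported — never silently dropped.

## Emergence

An outgroup ORF is assessed from a codon-level pairwise alignment in query
(human) codon coordinates. Disruptions are premature stop codons in the
subject and indels whose length is not a multiple of 3. The ORF is absent
when at least one disruption exists and the longest run of query codons
between consecutive disruptions is *strictly* below 70% of the query ORF
length; the quality filter (coverage > 0.70, identity > 0.50) is likewise
strict, so boundary values fail. The 70% rule is measured between
disruptions in query codons; we rejected the alternative reading (longest
ORF in any frame of the subject) because the rule is expressed relative to
the query ORF length.

A *common ancestral disabler* is a disruption of identical kind at the same
query-codon position in at least two ORF-absent outgroups (`min_species`
argument, default 2 — "multiple species"). Sharing marks the disruption as
ancestral by parsimony, distinguishing newly originated genes from old
genes dying independently in several lineages.

Age assignment uses Dollo parsimony on a dated tree (default
`(((((human,chimp),gorilla),orangutan),macaque),mouse)` with splits at 6, 9,
16, 25 and 90 My): one gain at the most recent common ancestor of all
ORF-present species, losses for absent species inside that clade. When an
independent-gains scenario has exactly the same event count the assignment
is flagged `ambiguous` (e.g. human+chimp+orangutan present, gorilla absent:
one gain + one loss vs two gains). Both label styles are reported: the
origin-clade label (`H-C-G-O`) and the present-species list (`H-C-O`),
because published catalogs use the latter when a species inside the clade
is absent or unsampled.

Merged dN/dS uses counting-method (NG86-style) fractional site counts, with
pathway-averaged difference counting and a per-class Jukes–Cantor
correction. Mutations creating stop codons are nonsynonymous (nonsense)
throughout — in site counting, in difference counting, and in polymorphism
classification — so divergence and polymorphism use one consistent
convention, and the neutral expectation of both dN/dS and
$\pi_N/\pi_S$ is 1.

## Retention

The lifespan simulator is event-driven (implemented in C++ for speed):
waiting times are exponential with total rate $L(\mu+\nu)$, each event
picks a site uniformly, point substitutions update the sequence (transition
weighted by $\kappa$, default 1 = uniform), and interruption is declared
when a non-terminal codon becomes a stop or a frameshifting indel lands in
the ORF. Loss of the terminal stop codon is *not* an interruption,
mirroring the identification rule, which names only frame-disrupting indels
and premature stops. Defaults: $\mu = 1.25\times10^{-9}$ and
$\nu = 0.1\times10^{-9}$ per site per year, 20,000 replicates, horizon
$10^{10}$ years with censoring (the censored fraction is reported, and the
half-life is flagged undefined when it reaches 0.5). Indels default to
fixed length 1 (always frameshifting); a geometric-length option (mean 3,
in-frame indels harmless) exists but is off because only an aggregate indel
rate is defined. Insertions are composition-neutral by construction since
interruption is decided before any sequence effect matters.

Two deliberate modelling notes. First, because the sequence is updated
after every event, the interruption hazard is *not* constant: a 3-codon toy
ORF starting at TGG (two stop-creating changes) drifts toward codons with
fewer stop neighbours, and its median interruption time sits ~16% above
the constant-hazard value $\ln 2 / (9\nu + 2\mu/3)$. The first-event
approximation is the $t=0$ hazard, not the process. Second, the survival
formula $p = \lambda e^{-\lambda}$, $\lambda = (1/2)^{T/t_{1/2}}$, is
implemented verbatim as a *minimal* probability; at $T = 0$ it evaluates to
$e^{-1}$, not 1, and we do not reinterpret it.

## Selection

Per-site diversity uses the unbiased heterozygosity
$\pi = \sum_s 2p_s(1-p_s)\,n/(n-1) / L$ and
$\theta_w = S/(a_n L)$. $\pi_N/\pi_S$ divides class diversities by the
fractional NG86 site counts of the reference CDS, the normalization under
which neutrality gives 1; the alternative (variant-count normalization) was
rejected for exactly that reason. Spectra are unfolded (ancestral alleles
from the input annotation), pooled across genes, bootstrap-resampled over
sites (default $B = 1000$; percentile CIs and standard deviations
reported), and projected down hypergeometrically when a site was genotyped
in more chromosomes than the spectrum's *n*. The rare-variant excess test
is a one-sided two-proportion z-test (no continuity correction) on the
singleton class. The exon/intron Monte Carlo test places the observed
variant count uniformly by length (10,000 replicates) and reports the
deficit tail with the $(k+1)/(N+1)$ estimator so p is never 0. Monte Carlo
and bootstrap seeds are explicit arguments everywhere.

## The synthetic-data generator

The generator defines the study conditions the tests run under.

**Sequences.** I.i.d. bases with $P(G)+P(C)$ equal to the GC target; ORFs
start with ATG, have internal stops resampled, and end with a stop. At
3 kb+ the realized GC is within ±0.02 of target.

**Orthologs.** The ancestor sits at the root of the dated tree;
substitutions accrue per branch as Poisson events. Indels enter only as
injected disablers, so the codon register is shared across tips and the
emitted alignments are exact — the full indel model lives in the lifespan
simulator, where it is the object of study. Injected disabler codons are
protected from later substitution so every descendant carries the disabler
at the same aligned position (root-to-tip paths are 90 My; without
protection a three-base stop codon would be overwritten in roughly a
quarter of tips and the construction would no longer mean what it says).
Three gene archetypes are built: *de novo-like* (neutral evolution
everywhere, one ancestral disabler injected at the root and reverted on the
human branch, whose ORF is then enforced — the ORF-creating mutations),
*dying decoys* (purifying-constrained background evolution plus
lineage-specific disablers at distinct positions), and *conserved controls*
(constrained, no disablers). Decoys and controls are constrained because
their biological referents are genes under selection until recently; it
also keeps end-to-end classification a test of the rules rather than of
background stop-codon coincidences at 90 My divergences — the neutral
regime, where such coincidences are real, is exercised separately by the
emergence property tests on de novo-like genes.

**Polymorphism.** Derived-allele counts are drawn from the Wright–Fisher
diffusion expectation
$F_i(\gamma) \propto \int_0^1 \binom{n}{i} q^i (1-q)^{n-i}
\frac{1-e^{-2\gamma(1-q)}}{(1-e^{-2\gamma})\,q(1-q)}\,dq$, which reduces to
the $1/i$ law at $\gamma = 0$; segregating-site counts per class are
Poisson with the neutral expectation scaled by
$\sum_i F_i(\gamma)/\sum_i F_i(0)$. Coding variants are placed on real
(position, alternative allele) pairs whose classification matches the
class, so the pipeline's own classifier reproduces the truth. Neutral
expected counts are tied to NG86 site counts for coding classes and to bp
lengths for noncoding classes, which makes the exon/intron null uniform and
the neutral $\pi_N/\pi_S$ centre on 1 by construction rather than by
tuning.

**Panels.** The two presets fix the contrast the selection stage is about:
`selection-strong` (human-like; $n = 134$ chromosomes = 67 diploid
individuals, $\gamma = -10$ on nonsynonymous sites) and `neutral-only`
(macaque-like; $n = 164$ = 82 animals, fully neutral). The panel locus
pools 30 kb of GC-0.57 CDS (≈ 64 genes × ~155 codons), 20 kb UTR and
120 kb intron at a neutral density of 0.02 segregating sites per bp —
pooled-panel scale set a priori so that each arm of the qualitative triad
($\pi_N/\pi_S < 1$, exonic deficit, rare-nonsynonymous excess) has ample
power per replicate under $\gamma = -10$, where diversity at nonsynonymous
sites falls to roughly a quarter of neutral.

**What passing tests do not show.** The generator has no linkage,
demography, CpG hypermutability, rate heterogeneity, alignment error or
expression-level confounding; branch lengths and rates are exact. Passing
the recovery suites therefore shows the *estimators and decision rules* are
correct under their stated models, not that real data meet those models.

## Problem sizes and determinism

The test suite runs the simulator contracts at their native sizes (20,000
lifespan replicates, 10,000 Monte Carlo placements, 1,000 bootstrap
replicates, 50 seeded panel replicates for the selection triad, 100 seeded
end-to-end bundles at reduced panel scale); everything completes in a few
minutes on one core. All generators are bit-reproducible under a fixed
seed; `run_pipeline()` reruns byte-identically, and fixture bundles carry
an md5 manifest.

## Known limitations

* Codon alignments are consumed, not produced; alignment error is outside
  the model.
* Pseudo-site classification on non-coding orthologs uses the pseudo-CDS
  register implied by the codon alignment; orthologs with internal indels
  relative to the query are classified only up to that register.
* The in-frame option of the geometric indel model ignores the sequence
  content of the indel itself.
* `assign_age` treats unscored species (failed alignment filter) as
  missing rather than absent, so ages can only be as precise as the set of
  assessable outgroups.
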