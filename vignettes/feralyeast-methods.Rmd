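---
title: "Methods: windowed ancestry, introgression and aneuploidy analysis of spontaneous-ferment yeast"
author: "feralyeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed ancestry, introgression and aneuploidy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feralyeast)
```

# Scope and model of the data

`feralyeast` analyses *Saccharomyces cerevisiae* genomes sampled from
spontaneous (uninoculated) grape ferments. The central scientific
questions it addresses are: which commercial or wild lineages contributed
which parts of each genome (mosaic ancestry), where divergent
non-domesticated ancestry has introgressed, and how unstable the genomes
are at the whole-chromosome level (aneuploidy and copy number).

Inputs are diploid genotypes at biallelic SNPs (VCF with per-genotype GQ
and DP), a BED repeat mask, per-window newick trees with
haplotype-labelled leaves (tree inference itself is out of scope and
consumed as input), per-site read depth, and FASTA/FASTQ for the k-mer
species screen. Coordinates are 0-based half-open internally; VCF
positions are converted on read and back on write, and BED needs no
conversion.

# Genotype quality control

Per-genotype filtering sets calls with `GQ <= 20` **or** `DP <= 6` to
missing; both bounds are inclusive. Sites with strictly more than 80% of
genotypes missing are removed (a site at exactly 80% is kept); samples
need mean depth at least 6 and strictly more than 80% of sites genotyped.
These boundary semantics are implemented literally in one place
(`load_genotypes()`, `filter_sites()`, `filter_samples()`) and pinned by
exact tests. Multiallelic records are dropped with a logged count, not
decomposed: every downstream statistic is defined on bialleles.

Two heterozygosity thresholds appear in this workflow by design: a
permissive `< 0.5%` screen identifies broadly homozygous isolates, while
a strict `<= 0.05%` variant selects the near-homozygous painting set.
Both are exposed as plain parameters (`het_screen` in `run_config()`);
the default is the permissive 0.005, and callers tighten it when
assembling a painting cohort. No attempt is made to reconcile the two —
they serve different steps.

# Windowed statistics

Windows are tiled (step = size) or sliding, with starts $s = k\,
\mathrm{step}$ satisfying $s < L - \mathrm{size} + \mathrm{step}$; a
trailing short window is kept but flagged `partial` so callers can drop
it, and masked sites never enter a window's site list. Supported painting
sizes are 10/15/20/25 kb with 25 kb the default (the larger window gives
the most stable identity-by-state estimates); admixture scans use 10 kb
tiles.

Within-population diversity uses the unbiased per-site form
$\pi = 2 p (1-p)\, n/(n-1)$ with $n$ the non-missing haplotype count;
divergence is $d_{XY} = p_A(1-p_B) + p_B(1-p_A)$; and the ancestral
distance is $d_a = d_{XY} - (\pi_A + \pi_B)/2$, which may be legitimately
negative and is reported as-is. When invariant genotyped sites are not
available the averaging denominator is the count of usable variant sites
and the result carries a `variant_sites` mode flag. One consequence of
using the unbiased $\pi$ together with the plain $d_{XY}$ is that a
population compared against itself gives $d_a = -\pi/n$ rather than
exactly zero; the tests pin this closed form rather than pretending the
identity holds at finite sample size.

Identity by state is computed on the dosage scale, $1 - |g_A - g_B|/2$,
averaged over co-genotyped sites, with the missing fraction reported so
windows above 20% missing can be discarded. The coancestry coefficient is
the correlation of panel-frequency-centred dosages; because centring
frequencies are estimated from the panel itself, an average pair is
biased to $-1/(n-1)$, and the estimate is rescaled by that expectation so
self-comparisons score exactly 1 and unrelated pairs centre on 0.

## The fd introgression statistic

`fd_window()` polarizes each site on the outgroup major allele (a site
with outgroup frequency exactly 0.5 is uninformative and skipped), then
computes numerator $S = \sum_s (1-p_1) p_2 p_3 (1-p_O) - p_1 (1-p_2) p_3
(1-p_O)$ and a denominator in which $p_D = \max(p_2, p_3)$ replaces both
$p_2$ and $p_3$ — the dynamic-donor form, which bounds the ratio by the
value expected under complete introgression. Windows with $S \le 0$
return 0 by default (the published recommendation for the statistic);
`clamp = FALSE` returns `NA` instead. The "hat" sometimes attached to
this estimator is read simply as its windowed form.

A structural point the test suite documents: under a *symmetric*
four-population null (star phylogeny, equal drift everywhere) the clamped
window estimator has positive mean of order
$0.4/(0.56\sqrt{n_\mathrm{sites}})$ — about 0.05 at 200 sites per
window — because numerator noise and the max-based denominator scale
together. The meaningful null is the control design actually used in
practice: recipient and sister drawn from the same large,
well-sampled pool (so the numerator's $p_2 - p_1$ noise is tiny) against
a genuinely diverged candidate donor (so the denominator is large). Under
that design the no-admixture mean is below 0.01 with maxima around 0.06,
and that is the property the suite asserts at 500 windows × 200 sites
with populations of 120/120/30/20 diploids.

# Lineage collapsing and chromosome painting

The reference panel is collapsed into near-clonal lineages by
average-linkage clustering on $1 - \mathrm{IBS}$, descending from the
root. A node is kept as one lineage only if (a) the permutation Z-score
of its observed between-subcluster mean dissimilarity — against random
regroupings of the whole panel at the same subcluster sizes — is below 3,
and (b) its minimum internal pairwise IBS is at least 0.99. The original
procedure inspected the dendrogram manually with the same two cutoffs;
making the rule algorithmic means lineage counts on real panels may
differ slightly from a manual reading. The permutation uses sample
labels: the operation's input is the IBS matrix alone, from which
site-level resampling is not recoverable.

Painting assigns each window of a near-homozygous query to the lineage
with the *maximum* member IBS (a lineage matches if any member matches —
robust to one divergent member of a near-clonal cluster), provided the
score reaches 0.98; otherwise the window is `UNASSIGNED`, which is
exactly how divergent, unsampled ancestry manifests. Windows with more
than 20% query missingness are `TOO_MISSING`. Ties break
lexicographically on lineage id and are flagged. Raising the cutoff can
only shrink the assigned set (a tested monotonicity). The d_a-based clade
assignment (`assign_clade_da()`) works analogously with argmin over
clades.

# Local-tree incongruence and admixture blocks

For each 10 kb window tree, a tested haplotype is classified after
pruning to {test} ∪ source ∪ MO ∪ WRP (rooting on designated outgroup
leaves first when needed; a window whose tree cannot be rooted is
`UNRESOLVED`):

* `INCONGRUENT` — test + source span a clade excluding all MO/WRP leaves,
  and test + MO + WRP is *not* a clade;
* `CONGRUENT` — test + MO + WRP form a clade excluding the source;
* `UNRESOLVED` — anything else.

Zero-length internal branches are not collapsed (no collapse threshold is
applied by default). The window's admixture allele frequency is the
fraction of resolved population haplotypes called incongruent; haplotypes
missing from a tree, and unresolved calls, leave the denominator, and a
window with no resolved call is blank. Fixed blocks are maximal runs of
AF = 1 of length ≥ 3 windows, with one window trimmed from each end
because breakpoint windows can mix ancestries; `min_run > 2 * trim` is
enforced so trimming can never empty a block. Combined evidence is the
union of fd hits (at a threshold defaulting to the 99th percentile of a
control fd track) and topology hits (AF > 0).

# Aneuploidy and genome instability

Per-chromosome depth is compared to the pooled depth of all *other*
chromosomes with a two-sided Mann–Whitney test. The effect size is the
rank-biserial correlation $r = 2W/(n_1 n_2) - 1$ (ties half-weighted),
signed so positive means deeper than background; $|r| \ge 0.5$ — a
"large" effect — calls a gain or loss by sign. The copy-number proxy is
the Hodges–Lehmann location shift, the median of all pairwise
differences, computed *exactly* by order-statistic selection (bisection
on the pair-count function, $O((n_1+n_2)\log\mathrm{range})$ per probe) —
no pair matrix is materialized, so full-genome site counts are feasible;
an optional per-group subsampling cap changes the rank-biserial by less
than 0.02 at $10^4$ retained sites (tested). Shifts are normalized by the
median depth of chromosomes called 2N (falling back, flagged, to the
genome-wide median), so a clean $k$-copy chromosome sits at normalized
shift $(k-2)/2$: 0.5 per duplicated chromosome.

Instability is quantified by regressing each polysome's normalized shift
on the mean shift of the isolate's other polysomes (Gaussian
identity-link fit, per chromosome stratum and pooled; isolates with a
single polysome contribute nothing). Admixed and feral groups are
compared on per-isolate mean polysome shift with a one-sided
Mann–Whitney test, exact up to a combined n of 50.

## Simulation designs

Baseline per-site depth is Normal(mean = 30, sd = 10) — matching ~30×
sequencing — times $(1 + \mathrm{shift})$, rounded and floored at 0, with
per-chromosome site counts proportional to the 16 S288C chromosome
lengths (`default_site_counts()`; the empirical per-chromosome site table
the original analysis sampled is not available, and length-proportional
counts are the natural stand-in). Background aneuploid chromosomes are
selected with weights proportional to inverse chromosome size
(`aneuploidy_selection_weights()`): empirically, gain frequency is
strongly anti-correlated with chromosome length, with chromosomes 1, 3,
6 and 9 dominating. This weighting matters quantitatively: under uniform
selection the worst-case co-occurrence bias below rises from ~12% to
~20%, because larger background chromosomes contribute more contaminated
sites to the comparison pool.

Three designs are implemented:

* **Whole-chromosome power** (`simulate_power_grid()`): focal scalings
  −1…1 by 0.1 (0N–4N) with 0–5 co-occurring background 3N chromosomes.
  At 3N the call rate is ≥ 99%; at 2N false calls are < 1%.
* **Segmental robustness** (`simulate_segmental_grid()`): a signed
  fraction (−0.5…0.5) of the focal chromosome at 1.5× or 0.5×. Even
  half-chromosome events rarely (< 10%) trigger whole-chromosome calls,
  which is the desired behaviour — the rule targets true aneuploidies.
* **Co-occurrence bias** (`simulate_cooccurrence()`): background
  polysomes at normalized shifts 0–3 (2N–8N) for 0–5 chromosomes, a
  foreground chromosome at true shift 0–5 (up to 12N). With no
  co-occurring polysomes the estimator is unbiased; contamination of the
  background pool by high-copy polysomes biases the estimate downward, to
  about 12% in the worst cell (5 polysomes at 8N, 12N foreground).
  Within a replicate, one simulated layout (baseline draws, foreground
  choice, nested background selection) is shared across all grid cells,
  so cell-to-cell comparisons are paired and the monotone response
  surface is visible at modest replicate counts; the acceptance test
  allows 1.5 percentage points of Monte-Carlo slack on that
  monotonicity.

Exact integer copy-number calling is deliberately out of scope; the
normalized 10 kb / 2 kb sliding median track (`normalized_depth_track()`)
supports visual comparison against theoretical gridlines at $1 + 0.5k$.

# k-mer species assignment

Canonical 31-mers (lexicographic minimum of a k-mer and its reverse
complement, A < C < G < T; windows containing non-ACGT characters are
skipped) are collected per species reference, and any k-mer present in
more than one reference is removed, leaving pairwise-disjoint unique
marker sets. Read profiles keep canonical 31-mers observed more than 4
times (≥ 5). Assignment proportions are over *distinct* matched k-mers by
default — a choice made because observation-weighted proportions would
conflate abundance with genomic content — with a count-weighted mode
behind a flag. Unmatched k-mers are excluded from the denominator and
reported separately; a sample with no matches is `UNCLASSIFIED`.

# Synthetic data and what passing tests mean

The generators produce: a reference panel with Balding–Nichols
drift-structured clade frequencies (ancestral frequencies Uniform(0.05,
0.95), clade frequencies Beta-distributed around them at drift $F$),
near-clonal lineages whose founders are homozygous diploids (one
haplotype doubled — the painting substrate is near-homozygous by
construction) and whose members differ by a per-site clone mutation rate;
window-mosaic queries whose donor lineage follows a Markov chain
(switching probability per window), optionally overwritten in blocks by a
divergent unsampled donor; local trees with congruent, introgressed or
deliberately unresolvable topologies; and Normal-model depth profiles.
Heterozygosity, when requested, is injected per site at a target rate on
top of the mosaic rather than by pairing two independent haplotype
mosaics — the simpler mechanism with the same marginal effect on the
heterozygosity screen, which is all the pipeline consumes.

These emulate the statistical structure the methods assume — drift,
clonality, window-level mosaicism, depth noise — but not read-level
error, alignment artefacts, repeat-driven coverage pathologies, LD decay
within windows, or realistic coalescent variance in tree shapes. Passing
the suite therefore demonstrates correctness of the computations and
recoverability of truth under the stated models, not performance on any
particular sequencing run.

Problem sizes in the test and acceptance runs are desk-scale by choice:
genomes of 8,000–16,000 simulated depth sites, 20–100 replicates per
claim, panels of a dozen isolates and thousands of SNPs, 200–500 windows
per scan. The headline quantities (the 0.5 shift-per-duplication
calibration and the ~12% worst-case co-occurrence bias) are averaged over
20 replicate genomes of 16,000 sites.

# Numerical and degenerate-input conventions

Ties in argmax/argmin assignments break lexicographically and are
flagged. Identical constant depth groups return a degenerate, flagged
zero-effect result. An all-zero chromosome (complete loss) yields
rank-biserial −1 against a strictly positive background. Windows with no
informative sites are undefined rather than zero. The Hodges–Lehmann
bisection is exact for integer depths; the real-valued fallback converges
to $10^{-12}$ relative tolerance and both are pinned against the literal
median-of-all-pairs oracle. All generators are deterministic given their
seed, and every stochastic pipeline step takes an explicit seed.
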