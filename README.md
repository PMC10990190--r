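# feralyeast

Windowed population-genomic analysis of *Saccharomyces cerevisiae* from
spontaneous (uninoculated) grape ferments: who contributed which pieces of
these mosaic genomes, where divergent wild ancestry has introgressed, and
how unstable the genomes are at the chromosome level.

Commercial wine starter yeasts escape into vineyards, recombine, and pick
up non-domesticated ancestry — feralization. Dissecting that process from
short-read data needs four bespoke computations that this package
implements as a tested, reusable pipeline over synthetic data with known
truth:

* **Identity-by-state chromosome painting** — collapse a wine reference
  panel into near-clonal lineages (average-linkage clustering on
  1 − IBS with a permutation Z-score < 3 and minimum within-lineage IBS
  ≥ 0.99), then assign each 25 kb window of a near-homozygous query to the
  lineage with maximal member IBS at a 0.98 cutoff; windows matching no
  sampled lineage are left unassigned — the signature of divergent,
  unsampled ancestry. Windowed Nei's π, d_XY and
  d_a = d_XY − (π_A + π_B)/2 support clade-level assignment.
* **Introgression scanning** — the windowed fd ABBA-BABA estimator
  (outgroup-polarized, dynamic-donor denominator with
  p_D = max(p₂, p₃), non-positive numerators clamped to 0) combined with
  local-tree subtree incongruence: a haplotype is incongruent when it
  forms a clade with the candidate source population while breaking
  monophyly with the Mediterranean Oak + wine panel anchor. Windows where
  every resolved haplotype is incongruent (allele frequency 1) in runs of
  ≥ 3 are fixed admixture blocks, trimmed by one breakpoint window at
  each end.
* **Aneuploidy and genome instability from read depth** — per chromosome,
  a Mann–Whitney test of per-site depth against all other chromosomes;
  calls require a large rank-biserial effect (|r| ≥ 0.5 with
  r = 2W/(n₁n₂) − 1); relative copy number is the Hodges–Lehmann location
  shift (exact median of all pairwise differences, computed by
  order-statistic bisection) divided by the 2N median — 0.5 per duplicated
  chromosome. Includes the three a priori simulation studies (detection
  power, segmental-event robustness, co-occurring-polysome bias), an
  instability regression (polysome shift ~ mean background polysome
  shift) and the admixed-vs-feral one-sided comparison.
* **Exact k-mer species assignment** — canonical 31-mers unique to each
  *sensu stricto Saccharomyces* reference, matched exactly against read
  profiles filtered at > 4 observations.

A synthetic-data module generates every input the pipeline consumes —
drift-structured panels (Balding–Nichols), window-mosaic recombinants with
optional introgressed blocks, local trees, Normal(30, 10) depth profiles —
with truth tables, so each analysis is verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort (six mosaic isolates painted against a 12-isolate,
6-lineage panel; 40-window tree scan; 28-isolate depth cohort):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_qc_genotypes.R
Rscript analysis/03_paint_ancestry.R
Rscript analysis/04_scan_introgression.R
Rscript analysis/05_aneuploidy_instability.R
Rscript analysis/06_power_simulations.R
Rscript analysis/07_classify_species.R
```

Output highlights (tables land in `results/`):

```
panel collapsed into 6 lineages (truth: 6)
  MOS01: 21/24 windows assigned (accuracy 1.00), 3 unassigned (3 truly introgressed)
fd scan: mean fd 0.690 in truly introgressed windows vs 0.0354 elsewhere
topology scan: sensitivity 1.00, specificity 1.00
fixed admixture blocks after trimming: 2
calls: 84 gains, 0 losses (100.0% gains)
instability regression (pooled): slope 0.70, r^2 0.34 over 84 polysomes
admixed > feral polysome copy number: one-sided p = 0.0065 (exact test, n = 12 vs 16)
pure sample: 100.0% of matched 31-mers assign to S. cerevisiae
50/50 mixture: 49.9% / 50.1% (cerevisiae/paradoxus)
```

Reading the numbers: every painted window lands on its true donor lineage
while the windows copied from an unsampled divergent donor fail the 0.98
IBS cutoff, exactly as admixture loci should; the fd and topology tracks
flag the planted introgression with no false windows; depth-based calls
recover the planted polysomes, and isolates simulated with higher latent
instability show correlated polysome copy numbers (the regression slope)
and a significantly higher group mean.

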