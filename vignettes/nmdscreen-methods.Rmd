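---
title: "Ratiometric screening for NMD inhibitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric screening for NMD inhibitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscreen)
library(dplyr)
```

## The assay this package models

Nonsense-mediated decay (NMD) degrades mRNAs carrying premature termination
codons, which keeps truncating-mutant transcripts — frameshift indels and
nonsense mutations — at a fraction of their wild-type counterparts'
abundance. A small molecule that inhibits NMD de-represses those transcripts,
and that de-repression can be read out by sequencing.

`nmdscreen` implements the computational side of a pooled, plate-based
screen built on that idea, plus the downstream transcriptome-level analysis
of an inhibitor's effect:

1. **Screen arm.** A pool of isogenic knockout clones — by default two
   *STAG2* frameshift clones and one *TP53* clone, mixed in equal ratio — is
   treated with one compound per well of a 96-well plate. Targeted amplicons
   over each clone-specific mutation are PCR-amplified with primers that
   embed an 8 nt plate barcode and a 10 nt well barcode, pooled, and
   sequenced as 150 nt single-end reads. Reads are demultiplexed by the two
   barcodes, classified as mutant or wild-type for each amplicon, and
   summarized per well as a *mutant allele fraction* (MAF). Because each
   clone's wild-type partners in the pool provide an internal reference, the
   statistic is ratiometric: global transcription effects and toxicity
   cancel out.
2. **Recovery arm.** For a cancer cell line treated with an inhibitor and
   profiled by RNA-seq in treated/control duplicates, each somatic variant's
   mutant and wild-type read counts at the variant site are compared between
   conditions: a heterozygous variant with adequate coverage whose MAF rises
   at least two-fold is called *recovered*. Recovery rates are stratified by
   mutation class and compared by a two-proportion chi-squared test.

## The corrected MAF

For mutant allele $a$ with $m$ mutant and $w$ wild-type reads in a well, the
raw fraction is $\mathrm{MAF} = m / (m + w)$. A mutation carried by $n_a$
of the pool's $N$ lines at zygosity dosage $\delta_a$ (0.5 heterozygous, 1
homozygous or hemizygous) can never approach 1 even under complete NMD
blockade; its ceiling under equal per-cell expression is the *expected
maximum fraction*

$$ e_a = \frac{n_a \, \delta_a}{N}. $$

The **corrected MAF** is $\mathrm{MAF} / e_a$, which corrects for the number
of cell lines and for heterozygous mutations so one threshold can serve all
reporters. With the default pool (three lines, one full-dosage carrier per
allele), $e_a = 1/3$ for every reporter. The exact ceiling of the corrected
statistic additionally depends on how many wild-type copies of the gene the
*other* lines contribute: the package derives that wild-type dosage from the
pool design as $W_g = N - \sum_{a' \in g} n_{a'} \delta_{a'}$, and the
analytic expectation used by the simulator is

$$ \mathbb{E}[\mathrm{MAF}_a] =
   \frac{n_a \delta_a \theta}{n_a \delta_a \theta + W_g}, $$

where $\theta$ is the mutant allele's *escape ratio* — its transcript output
relative to an unsuppressed allele. Baseline $\theta_0$ encodes how hard NMD
suppresses the reporter (defaults 1/20 for *STAG2*, 1/6 for *TP53*,
matching the 20-fold and 6-fold transcript suppression observed for these
knockouts), and an inhibitor multiplies $\theta_0$ by its effect $f$.

## Null model and hit rule

Vehicle (DMSO) control wells — six per plate, alongside two emetine positive
controls — are pooled **across all plates** and summarized per allele by
their mean $\mu$ and sample standard deviation $\sigma$ ($n-1$
denominator). The hit threshold is $T = \mu + k\sigma$ with $k = 5$ by
default; a single fixed threshold (such as the 0.46 a full-scale screen of
this design reported) can be imposed instead. A compound is a **hit** only
when the corrected MAF of *every* reporter allele strictly exceeds its
threshold — "greater than", so boundary equality is not a hit — and the well
is clean: no missing or low-coverage allele, and a plate that passed QC.
The conjunction over three independent reporters is what makes $k = 5$
essentially false-positive-free: a one-sided Gaussian tail of
$2.9\times10^{-7}$ per allele, cubed.

Plate QC re-expresses the screen's emetine check on the sequencing readout
itself: a plate passes when its mean positive-control corrected MAF is at
least $q = 2$ times its mean negative-control corrected MAF (emetine's
effect ran three- to fourfold in the assay this models, so $q = 2$ leaves
headroom without passing dead plates). A zero negative-control mean with
positive signal passes (ratio $+\infty$); a plate missing usable controls
fails with a reason. Controls on failed plates are excluded from the pooled
null — the conservative choice; the alternative is a configuration switch
away.

Other numerical policies worth stating explicitly:

* **Missing, never zero.** A zero-depth allele has an undefined MAF and is
  propagated as `NA`; it disqualifies its well from hit calling rather than
  counting as 0.
* **Low coverage.** Alleles with fewer than `min_depth = 200` reads (the
  default; configurable) are excluded from null fitting and disqualify
  their wells. Ratio estimates below a few hundred reads are too unstable
  for a 5-SD rule.
* **Barcode ties.** Demultiplexing assigns the unique barcode within
  `max_mismatches = 1`; ties or no match leave the axis unassigned, and a
  read is only counted when both axes resolve. Because manifests are
  validated to have pairwise Hamming distance $> 2 \times$ the tolerance,
  any read whose true barcode gained at most one substitution is provably
  assigned to its true well, and ties cannot occur within a valid manifest.
* **Diagnostic windows.** Allele classification is exact substring
  containment of a window spanning the clone-specific edit ±10 nt, searched
  on both strands. Exact matching keeps classification unambiguous and
  fast; the cost is that a sequencing error inside the window leaves a read
  unclassified (roughly 2–4% of reads at an error rate of $10^{-3}$) —
  reads are lost, not misassigned, which biases depth slightly but not the
  ratio. Panels are validated so that no allele's window occurs in any
  other allele's sequence, so error-free reads can never be ambiguous.

## The recovery stage

A variant enters the analysis only if it is heterozygous and covered by at
least five reads (mutant + wild-type) at the site in **all four** samples —
both treated and both control replicates; the boundary is inclusive.
Per-sample MAFs are averaged across the two replicates of each condition
(arithmetic mean of fractions, treating replicates as equal units, rather
than pooling counts), and the fold change
$FC = \overline{\mathrm{MAF}}_{treated} / \overline{\mathrm{MAF}}_{control}$
is compared against the recovery threshold $r = 2$, inclusive — "at least
two-fold". When the control MAF is exactly zero, a pseudocount of 0.5 is
added to the mutant and wild-type counts of all four samples before
recomputing, which keeps $FC$ finite while preserving ordering.

The MAF denominator is mutant over total ($m/(m+w)$) everywhere, for
boundedness; the mutant-over-wild-type variant ($m/w$) that some variant
callers report is available as a configuration switch
(`maf_denominator = "wildtype"`) since the two conventions differ only
monotonically. Each variant is treated as an independent unit; there is no
gene-level collapsing. Which variants are "predicted to undergo NMD" is
accepted as an input annotation column — the package does not predict NMD
sensitivity from transcript structure.

The two-proportion test is the closed-form $2\times2$ chi-squared

$$ \chi^2 = \frac{N\,(\max(0, |ad - bc| - N/2))^2}{r_1 r_2 c_1 c_2}, $$

with the Yates $N/2$ term dropped when continuity correction is off and
capped so the corrected statistic can never go negative; the p-value uses 1
degree of freedom. It agrees with `stats::prop.test()`, which the test
suite uses as an independent cross-check rather than as the implementation.

## What the simulators emulate — and what they do not

`simulate_screen()` generates the exact file formats the pipeline consumes
(FASTQ lanes, barcode TSV + YAML, panel FASTA + window TSV, plate map CSV)
plus a truth manifest sufficient to recompute every expectation
analytically. Its generative model: per-well depth is negative-binomial
(default mean 56,753 — the per-well average of the screen this models — and
size 20, moderate overdispersion); each read draws an allele with
probability proportional to its transcript dosage in the pool (wild-type
dosage $W_g$, mutant dosage $n_a \delta_a \theta_0 f$); the read is the
allele's amplicon flanked by the well's two barcodes; substitution errors
are i.i.d. at rate $10^{-3}$. Emetine wells get effect $f = 3.5$ (the
middle of the three- to fourfold range observed). Outputs are
byte-reproducible for a fixed seed, and read ids carry the true
(plate, well, allele) so truth is recoverable per read.

Deliberately **not** modelled: indel sequencing errors (an optional stress
mode for the exact-window design choice would add them), quality-score
structure (qualities are flat; the optional mean-quality filter exists but
the modelled assay used none), PCR duplicates and chimeras, cross-well
contamination, and line-to-line expression differences (all lines express
each gene equally per cell; NMD acts multiplicatively through $\theta$).
Passing tests on this synthetic data therefore demonstrate the *pipeline's*
correctness — demultiplexing, counting, the statistics, the calling rules —
not robustness to every artifact of real sequencing.

`simulate_variant_table()` draws, per variant, a control MAF $q$ from a
class-specific Beta (defaults: Beta(3, 27), mean 0.1, for the
NMD-suppressed heterozygous classes — between the 6- and 20-fold
suppression the reporter genes showed; Beta(20, 20) for neutral SNVs and
control SNPs), independent per-sample site depths (negative binomial, mean
150, size 5 — typical exonic coverage spread at a few gigabases per
sample), control counts $\mathrm{Bin}(d, q)$ and treated counts
$\mathrm{Bin}(d, \min(1, qf))$ with the class's true fold $f$
(`control_snp` pinned at $f = 1$). Saturation events ($qf > 1$) are
recorded in the truth table.

## Problem sizes and observed behaviour

The test suite exercises, among others: a 96-well error-free plate at
10,000 reads per well (every read demultiplexes to its true well, and every
≤1-substitution barcode variant of a full 33-plate manifest resolves
correctly); a four-plate screen at 20,000 reads per well with inhibitors
spiked at $f \in \{3, 5, 10\}$ (the called hit set equals the spiked set
exactly, with no false positives); 10,000 null wells at full screen depth
in each of five seeds (zero hits at $k = 5$); and pooled variant tables of
~2,000 passing variants (recovery sensitivity ≈ 0.96 at $f = 3$ with ≥50×
coverage, false-recovery ≈ 0 for $f = 1$ SNPs at ≥100×, and ≥95% of fold
changes within ±20% of truth at 1000×). Streaming results are checked
exactly against quadratic-time brute-force recounts, and every scalar
statistic against independent hand recomputation at $10^{-12}$ relative
tolerance. Sensitivity at the $f = 3$, depth ≥ 50 operating point is
estimated pooled across five seeds: individual 400-variant tables estimate
a ≈0.96 true sensitivity with ±1.5% sampling noise, and the pooled
estimate is the meaningful measure of the rule.

## Known limitations

* Classification is exact-match: platforms with frequent indel errors
  would lose more reads than the substitution-only model suggests, and the
  window design assumes the clone edits are the only variation inside the
  windows.
* The corrected MAF's interpretation as "fraction of maximum blockade"
  assumes equal line mixing and equal per-cell expression; unequal pools
  shift the ceiling, though the control-calibrated threshold absorbs this
  for hit calling.
* The null model is Gaussian-on-corrected-MAF; at very low depth the
  binomial skew makes $\mu + 5\sigma$ conservative rather than exact,
  which is the safe direction for a screen.
* The recovery fold change has no shrinkage: at minimal depth (5 reads) it
  is noisy, exactly as in the procedure it reimplements; the depth filter,
  not the estimator, is the guard.
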