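---
title: "Sizing repeat tracts and quantifying somatic instability with strgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing repeat tracts and quantifying somatic instability with strgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strgain)
```

## The measurement problem

Expanded CAG tracts at disease loci (HTT exon 1, ATXN3 exon 10) are
somatically unstable: in certain cell types the inherited mutant tract
keeps gaining repeat units over a lifetime. Deep sequencing of PCR
amplicons spanning the tract, from sorted nuclei of a single cell type,
yields one read per molecule; the distribution of repeat counts across
reads is the quantitative readout of that instability. `strgain`
implements the computation from raw single-end FASTQ to cohort-level
statistics. This vignette explains the model behind each stage, the
tunable parameters and their defaults, the behaviour of the synthetic-data
generator, and the design decisions that were genuinely open.

## Locus model and the reference ladder

An amplicon locus is described declaratively (`locus_template()`): a fixed
upstream flank (primer-proximal), a 3-nt repeat unit whose uninterrupted
copy number $i$ is the quantity of interest, an ordered list of fixed
*cassettes* between the tract and the downstream flank, and the ladder
bounds $[i_{\min}, i_{\max}]$. For canonical HTT exon 1 the cassettes are
the CAA-CAG interruption, a CCG-CCA spacer, the CCG (polyproline) tract
and a CCT run. Two conventions matter:

* **Only the uninterrupted tract is counted.** Interruption codons live in
  cassettes and never contribute to $i$.
* **The ladder ceiling is 113 units.** A 400-nt read must cover the
  upstream flank, the tract and a minimum post-tract anchor; beyond
  ~113 units the tract is no longer reliably sizeable from a single-end
  read, so the ladder stops there and longer molecules are (correctly)
  unassignable.

The shipped HTT/ATXN3 templates carry *synthetic placeholder flanks*: the
algorithm only requires that flanks be fixed and known, so users of a real
assay substitute their own flank and cassette sequences via arguments or a
YAML locus config (`read_locus_config()`). Ladders regenerate
deterministically from the template (`build_ladder()`), serialize to
multi-FASTA, and record ids (`HTT_ex1_CAG044`) parse back to $i$.

## Read classification

Each read is scored against every ladder member with a **semi-global
(infix) edit distance**: the read aligns end to end, the reference may be
entered and left anywhere, mismatches and gaps cost 1, `N` in a read
mismatches everything, and both orientations are tried. A read is counted
for member $i$ only if that member's cost is (a) uniquely minimal with a
margin of at least `delta` over every other repeat index and (b) at most
`ceiling(max_error_frac × read length)`. Everything else is left
unassigned with an explicit reason (`tie`, `max_error`, `too_short`,
`invalid_chars`).

Parameter defaults, and why:

| parameter | default | units | role |
|---|---|---|---|
| `delta` | 1 | edits | uniqueness margin; ties are *never* broken arbitrarily because a deterministic tie-break would bias $R_i$ by ±1 unit |
| `max_error_frac` | 0.10 | fraction of read length | accepts sequencing error while rejecting off-target molecules |
| `min_post_anchor` | 12 | nt | a read must extend at least this far past the tract; realizes the single-end detection ceiling |
| `min_reads` | 200 | reads | floor for allele calling and structure detection |

Base qualities are intentionally ignored: the classification is a
whole-read distance, and the simulator writes constant qualities for the
same reason.

Implementation: distances are computed exactly for **every** ladder member
with the bit-parallel Myers dynamic program (the algorithm family behind
edlib), organised around the ladder's shared structure — all members share
the prefix `flank + unit^i` column-wise, so one sweep over that trunk
serves the whole ladder and each member resumes into the shared post-tract
suffix from its own column. This is a deduplicated form of the exhaustive
scan, not a heuristic; the test suite proves equality with an independent
exhaustive oracle (Biostrings `pairwiseAlignment` in global-local mode,
whose score with match 0 / mismatch −1 / gap −1 is minus the infix edit
distance) on a randomized 1,000-read battery that includes substitutions,
indels, truncations and reverse-complemented reads.

## Progenitor-allele calling and tract structure

The inherited normal ($N$) and mutant progenitor ($M$) lengths are defined
as the two modes of the histogram in a **non-expanding** cell type
(glia-like samples carry the `allele_reference` role in the manifest; the
pipeline propagates the resulting call to every sample of the same
donor and locus, because expanding cell types may retain no unexpanded
mode at all). Mode finding is deliberately simple and auditable: strict
local maxima on raw counts (optional 3-point smoothing, off by default),
the two tallest maxima at least `min_separation = 5` units apart, the
secondary mode at least `prominence_frac = 0.05` of the primary. A
single qualifying mode is an *error*, not a silent guess — homozygosity
and absent mutant alleles must be resolved by the analyst.

Tract structure (presence of the interruption cassette, CCG-tract length)
is detected automatically from assigned reads by approximate matching
(≤1 mismatch per cassette, modal signature across reads), replacing the
manual read inspection a human would otherwise perform. If the modal
structure differs from the template the sample is flagged atypical, the
template is rebuilt (`apply_structure()`), the ladder regenerated and the
reads re-sized (`resize_if_atypical()`). When a second structure exceeds
30% of reads the call is flagged as two conflicting structural alleles
and both are reported with frequencies — per-allele re-laddering is the
analyst's decision, never an automatic choice.

## Instability statistics

With $R_i$ the read count at repeat index $i$ and the ladder ceiling at
113:

$$\mathrm{RoSE}_{\mathrm{normal}} = \frac{R_{N+1}+R_{N+2}+R_{N+3}}{R_N},
\qquad
\mathrm{RoSE}_{\mathrm{mutant}} = \frac{\sum_{i=M+1}^{113} R_i}{R_M},$$

$$\mathrm{MSLG} = \frac{\sum_{i=M}^{113} R_i \, i}{\sum_{i=M}^{113} R_i} - M
\quad \text{(repeat units).}$$

The supports are exactly these; reads falling strictly between $N+3$ and
$M$ belong to neither formula and are reported only as a QC count
(`n_intermediate_reads`). Contractions of the mutant allele ($i < M$) are
not measured — the MSLG support starts at $M$ — and this is a documented
limitation rather than something the package silently extends. All three
statistics are scale-invariant; the normalization of histograms to 1,000
reads (`normalize_histogram()`) exists purely for display and keeps real
values (rounding, if any, happens in rendering). A statistic whose
denominator is empty ($R_N = 0$, $R_M = 0$, no mutant-range reads) raises
a classed error that the pipeline records as a per-sample failure.

## Cohort comparisons

Per-donor statistics are compared across cell types with classical
fixed-effects one-way ANOVA (unequal group sizes allowed; a Welch variant
exists behind `welch = TRUE` but is off by default since the classical
test is the one the multiple-comparison procedure is defined around).
Pairwise contrasts use the pooled within-group mean square from the ANOVA
(the conventional post-hoc construction) and are adjusted by the
**Holm–Šidák step-down**: sort raw p ascending, adjust the $k$-th to
$1-(1-p_{(k)})^{m-k+1}$, enforce monotonicity, cap at 1, return in input
order. `stats::p.adjust()` does not offer this method, so it is
implemented from the closed form and property-tested (monotone, ≥ raw,
permutation-equivariant, non-idempotent). The **ratio paired t-test** for
designated pairs is the paired t-test on log values — a test of unit mean
ratio — whose statistic is invariant to the log base and to common
rescaling. The ANOVA is unpaired: whether donors should be treated as a
blocking factor is not derivable from the named test, and the literal
reading was chosen; pairing is available explicitly through the ratio
paired comparison.

Numerical edge cases are explicit: zero within-group variance with
distinct means reports $F = \infty$ with the p value floored at the
smallest positive double and an underflow flag, never `NaN`.

## The synthetic-data generator

`expansion_model()` + `simulate_sample()` emulate single-end amplicon
sequencing of a two-allele cell population, with truth recorded per read:

1. each molecule draws an allele (mutant fraction `allele_balance`,
   default 0.5);
2. mutant molecules stay at $M$ with probability `p_unexpanded` or gain
   $g \geq 1$ units from a discretized gamma (`gain_mean`, `gain_shape`),
   capped so $M + g \leq 113$;
3. per-molecule PCR stutter shifts the rendered length by
   $\{-2,-1,0,+1\}$ with contraction bias
   ($P(-1)=s$, $P(-2)=s^2/2$, $P(+1)=s/4$; default $s = 0.05$) — applied
   to both alleles, since stutter acts during amplification;
4. the sequence is rendered from the template, i.i.d. substitutions are
   applied at rate `epsilon` (default 0.005), and the read is truncated to
   `read_length` (default 400 nt) from the upstream-primer end.

Cell-type presets encode the biology the cohort generator emulates:
MSN-like samples (`p_unexpanded = 0.10`, gamma gains with mean 24.5,
shape 4) leave only a small fraction of molecules at the inherited
length, put roughly half of all mutant molecules above a gain of 20
units, and have a truth MSLG of ≈22 RU; CHAT-like interneurons behave
comparably; Purkinje-like samples are mildly unstable (truth MSLG ≈5 RU);
glia-like samples are stable (`p_unexpanded = 0.80`, small gains, truth
MSLG < 1 RU) and serve as the `allele_reference`. The stutter model and
its magnitude are conventions — published amplicon assays absorb stutter
into the empirical distribution and do not quantify it at 40–110 CAG
units — which is why $s$ is exposed rather than fixed.

What the simulator deliberately does **not** model: chimeric reads, index
hopping, quality-profiled errors, indel sequencing errors, or
length-dependent PCR efficiency. Passing tests on synthetic data
therefore demonstrate the correctness of the *computation* (sizing,
calling, statistics) under a realistic noise model, not the absence of
wet-lab artifacts in real libraries.

Reproducibility: one global cohort seed derives independent per-sample
streams by hashing the sample id into a 31-bit substream seed, so cohorts
are bitwise reproducible while samples remain independent.

## Pipeline and reporting

`run_cohort()` orchestrates: reference samples are sized first (pooled
when a donor has several), structure-checked and re-laddered if atypical,
the allele call is made, then every sample of the donor is sized and
scored. Any per-sample failure (undefined statistic, missing file,
missing reference) is recorded with its reason and the run continues;
every manifest sample appears exactly once in the stats table or the
failures table. Reports embed the resolved parameters and seed for
provenance. A thin CLI (`inst/cli/strgain`) exposes the same verbs for
shell use with exit codes 0 (success), 2 (partial failures), 1 (fatal).

## Problem sizes and numerical choices

The test suite validates formula exactness to 1e-12 against brute-force
oracles; classifier equality with the exhaustive oracle on 1,000
randomized reads (ladder up to 60 members); perfect sizing of 10,000
error-free reads and ≥99% accuracy at 0.5% substitution error; exact
allele calls on 100 seeded stuttered histograms; MSLG recovery within
0.5 RU of truth at 5,000 reads across 20 seeds; and ANOVA type-I error
calibration on 2,000 null simulations. The acceptance script simulates
five-donor cohorts at 3,000 reads per sample — enough for sub-RU precision
on MSLG while keeping a full run in the order of a minute or two on one
core. Ties in mode finding resolve to the leftmost bin of a plateau
(deterministic); histogram bins are kept over the full ladder grid so
formula supports never silently truncate; and all randomness flows from
user-supplied seeds.

## Known limitations

* Tract lengths above 113 units are invisible by construction; samples
  with very large expansions will under-report MSLG.
* $M$ cannot be estimated from expanding cell types; a non-expanding
  reference sample per donor and locus is a hard requirement.
* Mutant-allele contractions are outside the statistic definitions.
* Structure detection assumes substitution-dominated errors within
  cassettes; indel-heavy chemistry would need the mismatch allowance
  revisited.
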