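# strgain

Somatic instability of trinucleotide repeat tracts, quantified from
single-end amplicon sequencing.

In repeat-expansion disorders such as Huntington's disease (HTT exon 1) and
spinocerebellar ataxia 3 (ATXN3 exon 10), the inherited CAG tract keeps
expanding post-zygotically in selected cell types. Deep amplicon sequencing
of the repeat locus in sorted cell populations turns that biology into a
read-length histogram: each read reports the number of uninterrupted CAG
units in one molecule. `strgain` implements the full quantification around
that idea for researchers studying somatic repeat instability:

- **Ladder sizing.** Reads are classified against a *ladder* of reference
  sequences that differ only in repeat count (up to 113 units, the ceiling
  imposed by a 400-nt read). A read is counted only when exactly one ladder
  member attains the minimal semi-global edit distance; ties are discarded
  rather than broken, so the histogram `R_i` is never biased by ±1 unit.
  The classifier is an exact bit-parallel dynamic program, shared across
  ladder members, and is verified in the test suite against an independent
  alignment oracle.
- **Progenitor-allele calling.** The normal (`N`) and mutant progenitor
  (`M`) lengths are the two modes of the histogram in a *non-expanding*
  reference cell type (glia, granule cells). Atypical tract structures
  (missing CAA-CAG interruption, altered CCG tract) are detected from the
  reads and trigger re-laddering.
- **Instability statistics.** With `R_i` the reads at repeat count `i`:

  - normal-allele RoSE = `(R_{N+1} + R_{N+2} + R_{N+3}) / R_N`
  - mutant-allele RoSE = `Σ_{i=M+1}^{113} R_i / R_M`
  - mean somatic length gain (RU),
    `MSLG = Σ_{i=M}^{113} (R_i · i) / Σ_{i=M}^{113} R_i − M`

- **Cohort comparisons.** One-way ANOVA across cell types with Holm–Šidák
  multiple comparisons, and the ratio paired t-test (paired t on logs) for
  designated pairs.
- **A truth-bearing simulator.** Synthetic amplicon FASTQ with a two-allele
  mixture, a gamma gain distribution, per-molecule PCR stutter and per-base
  substitution error, so every stage is testable against known truth.

Everything is tibble-in / tibble-out and composes with the pipe; results
have `tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

```r
library(strgain)

tpl    <- htt_exon1_template()          # structure-parametric template
ladder <- build_ladder(tpl)             # 113 references, 3 nt apart

# a donor with N = 18, M = 44 whose striatal-neuron-like molecules expand
model <- expansion_model(tpl, N = 18, M = 44, p_unexpanded = 0.10,
                         gain_mean = 24.5, gain_shape = 4,
                         stutter_s = 0.05, epsilon = 0.005)
sim <- simulate_sample(model, n_reads = 5000, seed = 1)

sz <- size_sample(sim$reads$sequence, ladder, sample_id = "MSN_like")
sz
#> <sizing_result> sample MSN_like: 5000 reads, 5000 assigned, 0 unassigned

call <- structure(list(N = 18, M = 44), class = "allele_call")
instability_stats(sz$histogram, call) |>
  dplyr::select(rose_normal, rose_mutant, mslg)
#> # A tibble: 1 × 3
#>   rose_normal rose_mutant  mslg
#>         <dbl>       <dbl> <dbl>
#> 1      0.0105        10.0  22.3
```

About 10 expanded mutant molecules per unexpanded one (`rose_mutant`), and an
average somatic gain of ~22 repeat units (`mslg`) — the signature of a
strongly expanding cell type — while the normal allele stays almost inert
(`rose_normal` ≈ 0.01, PCR stutter only). `autoplot(sz, M = 44)` draws the
length distribution normalized to 1,000 reads; for a whole cohort,
`make_cohort()` + `run_cohort()` produce per-sample statistics, ANOVA +
Holm–Šidák comparisons and a provenance-stamped report
(`write_report()`).

A thin command-line interface with the same verbs
(`ladder`, `simulate`, `size`, `call-alleles`, `stats`, `compare`, `run`)
is installed at `inst/cli/strgain`.

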