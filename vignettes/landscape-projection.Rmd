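---
title: "Projecting compensatory evolution onto a genetic-interaction fitness landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting compensatory evolution onto a genetic-interaction fitness landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicomp)
```

## The question

When a yeast gene is deleted, the fitness loss is often compensated within a
few hundred generations by secondary mutations elsewhere in the genome —
frequently nonsense (truncating) or frameshift mutations that inactivate a
second gene. Genome-scale double-mutant screens measure, for nearly every
gene pair, the fitness of the double deletion alongside both single
deletions. Read as a fitness landscape, such a dataset predicts which
secondary gene losses should be beneficial in a given deletion background.
`epicomp` implements the statistical machinery needed to ask whether
observed compensatory loss-of-function mutations actually fall on the
beneficial part of that landscape, and, independently, whether truncations
accumulate faster than neutrally expected.

## The interaction classifier

For a background (query) deletion $b$ and partner (array) deletion $p$ the
landscape records the single-mutant fitnesses $f_b$, $f_p$, the double-mutant
fitness $f_{bp}$ and its standard deviation $\sigma_{bp}$ (all relative to
wild type = 1). The effect of losing $p$ in background $b$ is

$$\Delta = f_{bp} - f_b,$$

called **beneficial** if $\Delta > k\,\sigma_{bp}$, **deleterious** if
$\Delta < -k\,\sigma_{bp}$, and **neutral** otherwise, with $k = 3$ by
default. Two consequences of this operationalization are worth making
explicit:

* Ties are neutral. The inequalities are strict, so $|\Delta|$ exactly at
  the threshold is *not* significant; with measured fitness values exact
  ties essentially never occur, but the synthetic tests do construct them.
* The reported $\sigma_{bp}$ is used as-is; no pooling of replicate
  measurements or imputation of missing SDs is attempted. Rows lacking a
  fitness or SD are skipped (and counted) on load.

Lookups try the requested $(b, p)$ orientation first and then the reverse,
recomputing $\Delta$ against whichever single mutant plays the background
role; the underlying experiment distinguishes query from array strains, but
the effect definition is symmetric in the pair. A pair stored in neither
orientation is `ABSENT` — a value, not an error, since absence from the
landscape is itself an analysis outcome.

```{r classifier}
classify_interaction(list(fitness_background = 0.8,
                          fitness_double = 0.9, sd_double = 0.02))
```

## Projection and the binomial test

Truncation (nonsense) and frameshift mutations are treated as
loss-of-function; missense and synonymous changes are not. Counting is per
mutated gene per line — two hits in one gene in one evolved line count once —
because per-line gene tallies are the natural unit when lines are sequenced
once at the end of the experiment.

The observed number of beneficial calls among the landscape-represented
loss-of-function genes is compared with the landscape expectation by an
exact binomial test. For the headline case — one beneficial gene among 26
represented, at an expected beneficial probability of 6% — the point
probability $P(X = 1)$ is about 0.33:

```{r binom}
binomial_point_test(1, 26, 0.06)
```

The point probability is reported as the headline number because it is the
quantity that the observed-is-consistent-with-random claim rests on; both
tail probabilities are always returned alongside it, and
`beneficial_excess_test()` exposes the upper tail for directional excess
claims. The expected probability is a single pooled default (0.06,
overridable) even though per-study expectations may differ slightly; the
pooled value is the documented convention, not a fitted parameter. No
multiple-testing machinery is attached — a single pre-specified test is run.

## The nonsense/synonymous rate ratio

Whether truncations accumulate beyond neutral expectation is asked with an
opportunity-normalized rate ratio in the Nei–Gojobori counting style. For
every non-stop codon the nine single-nucleotide neighbors are classified
under the standard nuclear genetic code (stops TAA/TAG/TGA) as synonymous,
nonsense or missense; counts divided by 3 give per-codon site totals, summed
over every codon of the CDS set except the terminal stop. Then

$$\mathrm{dNONSENSE/dS} =
  \frac{n_\mathrm{nonsense} / L_\mathrm{nonsense}}
       {n_\mathrm{synonymous} / L_\mathrm{syn}},$$

where $n$ are observed substitution counts and $L$ the site totals. Under
neutral accumulation the ratio is 1. A ratio $r > 1$ decomposes into a
$1 \times dS$ neutral component and an $(r-1) \times dS$ beneficial excess,
so the implied fraction of nonsense mutations that are genuine drivers is
$(r-1)/r$ — about 72% at $r = 3.6$:

```{r driver}
driver_fraction(3.6)
```

Conventions: frameshifts are loss-of-function for the projection tally but
are excluded from the ratio, which is defined over single-nucleotide
substitutions only; opportunity counting is unweighted (no
transition/transversion bias — a deliberate simplification, exposed as a
future hook); terminal stop codons contribute no opportunities and
mutations mapping to them are rejected. Uncertainty comes from a
nonparametric bootstrap over the observed mutation records (default 1000
replicates, percentile interval). Because the ratio depends on the records
only through their class counts, iid resampling is implemented as a single
multinomial draw over (nonsense, synonymous, other) counts — exactly
equivalent to record-level resampling and much faster. The estimator
requires at least one observed synonymous mutation; it refuses to divide by
zero rather than silently adding a pseudo-count.

## What the synthetic generators emulate

Every stage is testable offline against planted truth:

* `sim_landscape()` plants BENEFICIAL/DELETERIOUS/NEUTRAL labels on all
  background × partner pairs. Single-mutant fitnesses are uniform on
  [0.5, 1] (viable deletion strains); double-mutant fitness is the
  background fitness plus Gaussian noise of SD `sd` plus ±`effect_size` for
  significant pairs. The default planted fractions (0.14/0.19) echo the
  genome-scale census proportions (~2.6M beneficial and ~3.3M deleterious of
  ~18M pairs), and the default effect size is 10×`sd`, far from the 3×SD
  boundary. Fitness values are rounded to 6 decimals — measurement-scale
  precision that also makes the TSV round-trip an exact fixpoint.
* `sim_cds()` builds in-frame CDS records (ATG … stop, no internal stop)
  with a tunable GC fraction, default 0.4 as in the yeast nuclear genome.
* `sim_mutation_spectrum()` samples uniformly over all single-nucleotide
  changes of the CDS set, weighting nonsense-creating changes by a planted
  multiplier — so the multiplier *is* the expected dNONSENSE/dS.
* `sim_evolved_lines()` emulates end-point sequencing of evolved deletion
  lines: each line draws a background gene, loss-of-function hits among its
  partners, and a tunable fraction of hits in genes absent from the
  landscape (reproducing the "28 identified, 12 represented" shape of real
  cohorts).

One subtlety is intrinsic to the noise model: planted-neutral pairs carry
full Gaussian noise, and a 3×SD rule has a two-sided false-positive rate of
about 0.0027. In a synthetic landscape with 850 neutral pairs, two or three
of them are *expected* to cross the threshold. The recovery guarantee is
therefore asymmetric, and the tests assert it that way: significant labels
planted 10 SDs out are recovered exactly, while neutral labels are recovered
up to that irreducible 3-sigma rate (which a dedicated test measures
directly at zero effect size on $10^5$ pairs). Clipping the neutral noise
would have made "exact" recovery trivially true and the false-positive test
meaningless.

What the generators do **not** emulate: clonal interference or fixation
dynamics within lines, correlated errors between pairs sharing a query
strain, heavy-tailed fitness noise, codon-usage bias within genes, and
mutational hotspots. Passing the synthetic suite therefore validates the
statistical machinery, not the biological fidelity of any particular real
dataset.

## Numerical and scale choices

Binomial probabilities come from R's exact `dbinom`/`pbinom` (log-space
internally; no normal approximation at any `n` used here). Landscape lookup
is a keyed binary search on (background, partner). Problem sizes in the test
suite are chosen to keep the full run around 15 s on one core while leaving
planted-truth recovery unambiguous: $10^4$-point classifier grids, $10^5$
pairs for the false-positive rate, spectra of $n = 2000$ mutations with
1000 bootstrap replicates, and 20 replicate neutral calibrations. The
bootstrap-coverage assertions (e.g. the CI covering the planted multiplier)
are themselves ~95%-probability events per replicate; the suite asserts
coverage in 18 of 20 neutral runs rather than all 20 for exactly that
reason.

## End-to-end use

```{r pipeline, eval = FALSE}
sim <- sim_landscape(seed = 1)
lines <- sim_evolved_lines(sim$landscape, sim$truth, seed = 2)
write_landscape(sim$landscape, "landscape.tsv")
write_mutations(lines, "mutations.tsv")
cfg <- pipeline_config("landscape.tsv", "mutations.tsv",
                       k_sd = 3, p_expected = 0.06, seed = 1, out_dir = "out")
run_pipeline(cfg)
```

`run_pipeline()` writes `report.json` (fractions rounded to 3 decimals) and
a prose `report.txt`; runs are byte-identical under a fixed configuration
and seed, every stage logs to standard error, and partial outputs are
removed on failure. A thin command-line wrapper around the same function
ships in `inst/scripts/run_pipeline.R`.

## Limitations

The package deliberately stops short of variant calling, colony-size
fitness measurement, reconstruction of multiplicative-epistasis scores, or
codon-model maximum likelihood: it starts from annotated gene lists and a
fitness table, and its dN/dS-style contrast is a counting estimator over
within-experiment mutation tallies, with no multiple-substitution
correction (inappropriate for divergence-scale data). The full genome-scale
interaction dataset is supported by format (`dialect = "sga-raw"`) but not
bundled.
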