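---
title: "Methods: deep-enzymology analysis of methyltransferase specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-enzymology analysis of methyltransferase specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepenz)
library(dplyr)
```

## The measurement problem

A maintenance DNA methyltransferase such as DNMT1 must methylate
hemimethylated CpG dyads (HM: 5mC on the parental strand) much faster than
unmethylated ones (UM) to copy a methylation pattern through replication,
and its activity on hemihydroxymethylated dyads (OH: 5hmC on the parental
strand) determines whether TET oxidation can drive passive demethylation.
All three specificities depend on the bases flanking the CpG. A
deep-enzymology experiment measures this comprehensively: pools of
double-stranded substrates carrying one CpG in randomized flanks are
methylated *competitively* in one tube, a hairpin linker joins the two
strands of each molecule, bisulfite conversion records the methylation
state of every cytosine, and paired-end sequencing reads out both strands
of each molecule together. `deepenz` implements the complete analysis of
such data, together with a generator that simulates the experiment with
known ground truth so every stage can be validated by parameter recovery.

## The synthetic experiment

`substrate_spec()` describes a 67-bp substrate: a class barcode (C-free, so
bisulfite conversion cannot alter it), C-free constant filler, and a single
CpG inside 10 randomized bases per side. `generate_pool()` draws molecules
with i.i.d. uniform flanks subject to one constraint: no CpG may occur
*outside* the NNCGNN context window. Two bases on either side of the
central CpG are part of the measured context, and 31 of the 256 contexts
(those of the form CGCGNN, NNCGCG and relatives) themselves contain a
second CG — excluding them would make those contexts unmeasurable, so CGs
inside the window are kept while flank CpGs further out are removed by
rejection sampling (the rejection rate is recorded as an attribute). One
consequence of this conditioning, which holds for any library constrained
to limit CpG content, is that flank C/G frequencies sit slightly below
0.25 and A/T slightly above; the test suite checks the realized
distribution against an independent brute-force rejection sampler rather
than against naive uniformity.

Kinetics follow the pseudo-first-order contract: dose `d` is the product
of relative enzyme concentration and incubation time (absolute units are
arbitrary), and each unmethylated CpG cytosine reacts with probability
`plateau * (1 - exp(-k * d))` where `k` is the rate constant of its class
and context. For UM molecules both strands are substrates: the upper
strand reacts with the rate of its own context and the lower strand,
independently, with the rate of the reverse-complement context. This
matches the chemistry (both cytosines of an unmethylated dyad can be
methylated) and is required for consistency with the counting rule below,
which assigns UM lower-strand events to the reverse-complement context; a
model in which only the upper strand reacted would systematically halve
fitted UM rates. Sequential cooperativity (a UM molecule becoming HM
mid-reaction and then reacting faster on the second strand) is not
modeled; at the turnovers used here its effect is negligible relative to
counting noise.

`emit_reads()` applies hairpin-bisulfite chemistry: unmethylated C reads T
with probability `conversion`, 5mC and 5hmC are fully protected (no oxBS
mode), and uniform substitution errors are added at `error_rate`. Defaults
are `conversion = 1`, `error_rate = 0` — the regime in which
reconstruction is provably exact and round-trip tests can demand 100%
identity; realistic values (0.995, 0.001) are a function argument away.
The default hairpin linker is a fixed C-free 8-mer, so conversion cannot
corrupt it.

The built-in ground-truth model (`example_rate_model()`) is deterministic:
per-context rates are products of per-position base multipliers encoding
the qualitative preference pattern seen for DNMT1 (T favored / C
disfavored at −2, C favored / G disfavored at −1, with class-specific +1
and +2 effects), spanning ~10-fold within HM and ~25-fold within OH and
UM. Class geometric means are 1, 1/14 and 1/87 (HM, OH, UM) per unit dose,
the reported average preference magnitudes. These defaults are the study
conditions for all simulations and are not adjusted per analysis.

## Read processing

Reconstruction applies a per-position rule table to the aligned read pair
(read 2 reversed so position *i* of both reads covers the same base pair):
upper C ⇒ original C (protected); upper T over lower G ⇒ converted C;
upper T over lower A ⇒ genuine T; upper G over lower C/T ⇒ original G with
the lower C protected/converted; A over T ⇒ A; anything else is a
contradiction and the position becomes N. Calls at the CpG use the
retained/converted state of each strand's cytosine; records with an N
inside the NNCGNN window are ambiguous and excluded from counts.
Demultiplexing requires an exact barcode match by default (1-mismatch
tolerance behind a flag); reads failing the expected-size filter (±2 bp)
are discarded and counted in the QC report, never silently.

Counting policy: for HM and OH substrates only upper-strand calls count
(the lower strand is pre-modified); for UM substrates each strand
contributes an independent event under its own strand-oriented context
(reverse complement for the lower strand). Whether the original analyses
pooled UM events per strand or per molecule is not documented; both
policies are implemented (`um_policy`), per-strand is the default, and the
two agree in rank ordering on simulated data.

## Kinetic fitting and merging

`fit_monoexponential()` minimizes the read-weighted sum of squares of
`y − plateau·(1 − exp(−k·d))` with `k ≥ 0`, multi-start initialization
(`k₀ ∈ {0.01, 0.1, 1}` plus a log-linearized start) and ties broken by
lowest residual then smallest k. The default plateau is fixed at 1:
with complete conversion and no background subtraction the methylated
fraction can reach 1, and fixing the plateau keeps the per-context problem
one-dimensional and well-conditioned at ~200 reads per dose.
`plateau = "fit"` instead estimates one global plateau per substrate class
from the class-pooled progress curve (absorbing a non-convertible or
inactive substrate fraction) and then fixes it for per-context fits.
Contexts with fewer than 50 reads at a dose lose that dose point;
contexts left with fewer than two distinct doses are flagged
`insufficient-data`, and all-zero contexts return `k = 0` with status
`boundary`.

Each class is probed over its own four-dose schedule placed at
`k·d ≈ 0.25–5.6` of the class geometric-mean rate
(`default_dose_schedule()`), emulating the experimental practice of
sampling slow substrate classes with higher enzyme concentrations and
longer times — rate ratios are only identifiable when each class's
progress curve is actually resolved. `scale_and_merge()` brings replicate
experiments to a common scale via the class-average rates shared with a
reference experiment (geometric mean of per-class factors), making the
merged table exactly invariant to rescaling any single experiment, then
averages per context with SEM = SD/√n. The merged table always enumerates
256 contexts per class, with NA where nothing usable was observed.

## Profiles, specificity, energetics

The o/e profile divides each base's frequency at each flank position among
methylated (or unmethylated) records by its expected frequency, taken from
the class's full read pool (absorbing synthesis bias) or from 0.25
(`expected = "uniform"`, appropriate for synthetic pools). A pseudo-count
of 1 per cell prevents division by zero and is negligible at real depths;
it can be set to 0 for exact small-sample arithmetic. Whether the original
normalization used the full pool or the unmethylated subset is not
documented; the package computes the pool-based form by default and the
unmethylated matrix alongside, so either convention can be read off.

Pairwise specificity tables report per-context ratios with undefined
entries flagged (never dropped), and *both* aggregation conventions — mean
of per-context ratios and ratio of class means — because summary
preferences quoted for such data plausibly mix the two; neither is
privileged. Box summaries use type-7 (linear interpolation) quartiles with
1.5·IQR whiskers clipped to the data. Enzyme variants are compared by a
two-sided paired t-test on natural-log specificity ratios (ratio data,
multiplicative noise); identical inputs yield p = 1 by convention.
`delta_g()` converts a rate ratio to `R·T·ln(ratio)` in kJ/mol at a
default 298 K (no temperature is prescribed by the data; 25 °C is the
conventional reference), and `burial_energy()` multiplies a buried
hydrophobic surface area by an energy-per-area coefficient.

For long multi-CpG substrates, `group_rates()` pools per-site fractions
(read-weighted) within substrate × lower-strand-state groups and fits one
curve per group; the expected group rate from single-site data is the
arithmetic mean of per-context rates over the group's sites — the simplest
expectation consistent with pooled initial-rate behavior, since the exact
formula behind published expectations is not documented (read-weighted
means differ by <2% on simulated data). Sites created by sequence tags can
be dropped via the `include` flag.

## Genomic correlation

`genomic_profile()` averages WGBS methylation per NNCGNN context
(coverage-weighted), keeping upper-strand sites with coverage strictly
greater than 4 by default. The randomization test reassigns the measured
context means to contexts at random, recomputes the correlation with the
preference profile, and converts the observed r to a Z score against the
shuffled mean and SD, with a one-sided upper-tail p (the question asked of
such data is chance exceedance; a two-sided flag exists). Twenty shuffles
mirror the published procedure but make p a Z-extrapolation rather than an
empirical tail — the function flags this and supports ≥10⁴ shuffles for
empirical p-values. The difference test uses the same shuffles for both
correlations, so Δr is exactly antisymmetric under swapping the profiles.

## What the simulations do and do not show

The generator reproduces the design dimensions that drive the statistics:
library size and composition, context-dependent first-order kinetics, dose
design, conversion chemistry, substitution errors, and coverage-dependent
genomic tables. It does not emulate PCR duplicates, quality-score
structure, indels, synthesis bias in flank composition, inter-experiment
scale drift beyond a constant factor, or enzyme processivity on long
substrates. Passing recovery tests therefore demonstrate that the
*analysis* is correct and well-calibrated at realistic depths, not that
real libraries are free of these artifacts. Replicate SEMs in simulation
reflect counting noise only, so they can undercut the ±5–10% reported for
merged wet-lab experiments, which include real inter-experiment
variability.

Problem sizes used by the test suite and the acceptance script — three
replicate experiments of 3 classes × 4 doses × 50,000 reads for parameter
recovery, 10,000 molecules for round-trip exactness, 40,000 molecules per
class for sign-pattern reproduction, 200 seeds for null calibration — were
chosen so each check is decisively powered (recovery attains r > 0.99 and
relative RMSE ≈ 4–7% against a 10%/0.95 requirement) while the whole suite
runs on a laptop in minutes.
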