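---
title: "Scoring translatomes from polysome-profiling arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring translatomes from polysome-profiling arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatome)
```

## The measurement model

Polysome profiling separates a cell's mRNA into a polysome pool P (two or
more ribosomes, actively translated) and a free + monosome pool FM. After
two-color labeling (green/Cy3 for P, red/Cy5 for FM) and competitive
hybridization, the translation efficiency of a transcript is the log ratio

$$M \;=\; \log_2 \frac{\text{P signal}}{\text{FM signal}},$$

and its abundance proxy is $A = \tfrac12 \log_2 (R \cdot G)$. If a
transcript of abundance $a$ engages polysomes with probability $\varphi$,
the two channels measure $a\varphi$ and $a(1-\varphi)$ per unit gain, so

$$M = \log_2 \frac{\varphi}{1 - \varphi}, \qquad
  \varphi = \frac{2^M}{1 + 2^M}.$$

This log-odds link is the backbone of the package: the synthetic-data
generator draws $\varphi$ through it, which makes the analysis statistic
the exact inverse of the generative model and allows sharp recovery tests
(noise-free round trips reproduce every true $M$ to floating-point
precision).

Replicate probes are averaged on the M/A scale after background
correction, and genes are kept only when $A$ exceeds a reliability cutoff
(strictly greater than, reading "above" literally; defaults 4 and 4.5 for
the two bundled presets).

### Background correction

Three methods are provided. `none` passes foregrounds through; `half`
takes $\max(\mathrm{fg} - \mathrm{bg},\ 0.5)$, the conventional positive
floor; `normexp` models the net intensity as a normal background plus an
exponential signal and replaces it with $E[S \mid X = x]$ in the usual
normal-cdf/pdf closed form. Parameters are estimated per channel by moment
matching ($EX = \mu + \alpha$, $\mathrm{Var}\,X = \sigma^2 + \alpha^2$,
third central moment $2\alpha^3$). Moment matching is transparent and
fast, but on intensity distributions with heavier-than-exponential tails
the implied $\sigma^2$ turns negative; the correction then falls back to
`half` with a logged warning rather than fabricating parameters. The
synthetic arrays, whose abundances are log-normal with a wide spread, land
in this regime deliberately - the fallback path is exercised, not hidden.

## Stress translation classes

Given control and stress M values, $\Delta M = M_\mathrm{stress} -
M_\mathrm{control}$, and three classes are called with fixed precedence
I, then R, then S:

* **I (inducible):** $M_\mathrm{control} \le 0$ and $\Delta M \ge 1$ —
  poorly translated messages de-repressed by stress;
* **R (resistant):** $M \ge 0.8$ in both conditions — maintained polysome
  engagement regardless of $\Delta M$;
* **S (sensitive):** $\Delta M \le -0.8$;
* **U** otherwise.

All cutoffs live in `class_thresholds()`. Two decisions here were
genuinely open. First, a transcript falling from $M = 3$ to $M = 1$
satisfies both the R level rule and the S drop rule; R wins because the
class is defined by maintained absolute engagement, and the evaluation
order I > R > S makes that explicit and total (every gene gets exactly one
label). Second, the "changed translation" cutoff used in the
translation-vs-abundance Venn analysis ($|\Delta M| \ge 1$) is kept as a
separate configurable threshold from the S-class cutoff (0.8) rather than
unified, since they play different roles. The coordination report carries
the precedence rule in its metadata.

Calibration markers are placed on the TE distribution with midrank
percentiles, $(r - 0.5)/n \times 100$, which are permutation-stable under
ties.

## Ortholog agreement

Translatomes of two species are joined through an ortholog pair table;
one-to-many mappings are expanded to all combinations (no collapsing rule
is imposed) and pairs are kept only when both genes were measured. Pearson
correlations are computed in abundance strata defined by
$\min(A_a, A_b) \ge$ cutoff — requiring *both* species to clear the
cutoff is the conservative reading when only one threshold is stated.

## Sequence features

Transcripts are split into 5'UTR / CDS / 3'UTR by 0-based half-open CDS
coordinates that include the start and stop codons. Features: region
lengths; G+C percentages with N excluded from numerator and denominator;
the number of AUG triplets lying entirely within the 5'UTR (every
position scanned, overlapping occurrences counted — uAUGs, not uORFs: no
frame or downstream-stop requirement); and whether position $-3$ relative
to the initiator A carries a purine (unknown for 5'UTRs shorter than
3 nt). The group report applies the selection filter $A \ge 5.5$, both
UTRs $\ge 10$ nt, then compares each group against its complement:
two-sided Welch t tests for continuous features (the unequal-variance
form, since group sizes and spreads differ wildly), Fisher exact tests for
the proportion rows (uAUG $\ge k$, purine context) — a deliberate
replacement for t tests on binary indicators, flagged here rather than in
the output. Medians are displayed for lengths, as is conventional for
heavy-tailed length distributions, even though the test compares the full
distributions.

## Base-pair probability profiles

Equilibrium pair probabilities are computed by an inside-outside
partition-function recursion over all nested (pseudoknot-free) structures.
The energy model is intentionally minimal: one Boltzmann weight per pair
type (defaults GC 6, AU 2, GU 1 — order-of-magnitude stability ranking),
no stacking or loop terms, hairpin loops at least 3 nt. The recursion uses
the unambiguous grammar "first base unpaired, or paired to k", giving
$O(n^3)$ inside and outside passes (implemented in C++); probabilities are
exact for the model, verified against exhaustive structure enumeration on
short sequences. Positions are profiled by their marginal pairing
probability $\sum_j p(i,j)$ in windows anchored at the start codon (+1 =
the A of AUG) or stop codon (+1 = its first base), with no offset 0; each
transcript is folded over the window plus a 50-nt flank (truncated at
transcript ends) rather than full length, a tractability decision since
the folding extent is otherwise unspecified. Group contrasts use per-
position Welch t tests at uncorrected $p < 0.05$, with BH-adjusted values
also reported.

Two properties of this model matter for interpretation. Without stacking
terms, a contiguous designed helix is *not* intrinsically favored over the
same pairs scattered across partners, so contrast experiments must control
the competing partner pool (the bundled demonstration keeps its designed
stem the only G/C material). And wobble pairs break reverse-complement
symmetry (GU maps to AC), so that invariant holds only for Watson-Crick
weights. For parity runs against a full thermodynamic folder, sparse BPP
matrices can be imported and exported as plain text.

## Enrichment

Single-selection enrichment is the classical Fisher exact test per gene
set, two-sided by default (depletion is signalled by the odds ratio), after
intersecting sets with the measured background; the p-value is the sum of
hypergeometric point masses not exceeding the observed one, with the
conventional $1 + 10^{-7}$ relative tie tolerance, computed in extended
precision from a log-factorial table. The threshold-free variant scans a
ranked list: partition $k$ of $n_\mathrm{part}$ (default 30, the classical
choice) selects the top $\lceil k n/(n_\mathrm{part}+1) \rceil$ genes,
every set is tested at every partition, and BH adjustment runs across all
(set, partition) pairs with the minimum adjusted p per set reported. BH
was chosen as the adjustment because the field default for this style of
tool is FDR control; the sample odds ratio $(ad)/(bc)$ is reported as-is,
infinite values included.

## The synthetic study

The generator emulates the experiment it is meant to test, not real
biology in full. Per transcript it draws:

* log-normal abundance (log2 mean 8, sd 2);
* a class (default mix S 0.50, R 0.13, I 0.08, rest U), with the
  probability of S rising logistically with standardized log abundance —
  abundant, heavily translated messages are preferentially stress-
  sensitive;
* class-conditional efficiencies: S starts high (control
  $M \sim N(1.2, 0.78)$) and falls by at least 1 log2 unit with an
  exponential tail (mean 1.6) plus an abundance-coupled extra drop; R
  holds both conditions above 1.1; I starts below $-0.35$ and gains at
  least 1.4; U is rejection-sampled to satisfy no rule with margin;
* a stress abundance response for a minority (class-coupled: I 28%,
  R 20%, U 8%, S 4%), nine-tenths upward by at least 1 log2 unit —
  the transcriptional arm of the response;
* features coupled to translation state: uAUG counts with a Poisson rate
  decreasing in control M and elevated in I; longer CDS and UTRs and lower
  G+C for I; a purine at $-3$ with probability ~0.87.

Sequences are then synthesized so the recorded features are *exact*:
the 5'UTR is scrubbed of accidental AUGs (mutating the T, which can never
create a new AUG), the prescribed number of uAUGs is planted at spaced
positions, the $-3$ context base is set last with a local repair pass, and
the CDS is built from non-stop codons between an AUG and a stop. Feature
extraction on synthesized transcripts therefore matches truth exactly,
which is what makes the extraction tests sharp.

**Mass-ratio calibration.** The stated experimental conditions fix the
P:FM total RNA mass ratios (presets: 2:1 control / 1:3 stress for the
human-like line, 1.5:1 / 1:3 for the mouse-like line). The generator
enforces them exactly with a global additive shift of the drawn
efficiencies per condition, solved by `uniroot` on the realized
population. Because every class-conditional draw keeps a 0.2-log2 margin
inside its decision boundary, a shift within the margin cannot flip any
truth label; if a small population needs a larger shift, affected genes
are redrawn directly in the calibrated space and the generator warns. The
stress-side collapse to 1:3 is only reachable because sensitivity and drop
size are abundance-coupled — most of the mRNA *mass* must leave the
polysome pool while only about half of the *genes* cross the S cutoff.
The drop severities and level defaults were set so the calibration shift
is near zero under the presets; they encode, in one place, how severe the
modeled shutdown is.

**Noise.** Each replicate probe (default 3 per gene) receives
multiplicative log-normal noise (sd 0.25 on the natural-log scale) and
additive normal background (mean 40, sd 6); the reported background
columns are noisy local estimates of the true level. Under these defaults
the array pipeline recovers true efficiencies with Pearson $r \approx
0.95$ and calls S/R/I with balanced accuracy $\approx 0.96$; both
quantities are recomputed, not quoted, by the test suite and
`scripts/acceptance.R`.

**What the generator does not emulate** — and hence what passing tests do
not establish about real arrays: probe cross-hybridization and sequence-
dependent probe affinity, spatial artifacts, dye bias and dye-swap
designs, within/between-array normalization effects, biological replicate
variability (conditions share one truth), and the fact that truth classes
sit a margin away from their decision boundaries, which makes class
recovery slightly easier than in boundary-dense real data.

## Problem sizes and numerics

The bundled analyses and checks run at desk scale by choice: 2,000
transcripts per study, 3 probes per gene, ~8,000 ortholog pairs, 60
transcripts per group in folding profiles, windows of ~60 positions with
50-nt flanks. The partition function works in linear space with an
overflow guard (an error suggests shorter windows or smaller weights —
relevant only far beyond the defaults). Exact-test verification sweeps
every 2x2 table with total up to 200 against direct summation; the
comparison is kept at $10^{-12}$ by computing log-factorials in extended
precision and, on the oracle side, blocking grouped cumulative sums so
rounding never crosses groups.

## Known limitations

* The energy model is a teaching-grade pair-weight model; absolute pairing
  probabilities are not thermodynamic predictions, only the positional
  *contrasts* between groups are meaningful, and external BPP matrices can
  be substituted where a full nearest-neighbor model is wanted.
* Moment-based normexp is fragile on heavy-tailed intensity data (by
  design it falls back to `half`); an MLE fit would be sturdier but less
  transparent.
* No dye-bias normalization is applied after background correction, and
  no statistical test is layered on the "changed abundance" cutoff
  ($|\Delta A| \ge 1$) — both mirror the pipeline this package models.
* Stress timepoints are treated as independent pairwise comparisons with
  the control; there is no time-course model.
* The ranked-partition scan tests top-of-list selections; a set
  concentrated at the bottom appears as depletion under the two-sided
  test rather than via bottom partitions.
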