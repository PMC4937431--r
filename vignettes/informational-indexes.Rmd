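---
title: "Informational indexes of genome sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informational indexes of genome sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind **biobits**, the meaning of each
parameter, why the synthetic genome generators are built the way they are,
and the numerical choices the implementation makes. It states methods, not
empirical results; measured behavior lives in the test suite.

## The model

A genome is modelled as a sequence over the alphabet $\{a, c, g, t\}$.
Ambiguity codes and gaps in the input split the sequence into *runs*; words
never span run boundaries, and all indexes are computed over the multiset of
words occurring inside runs. The *effective length* $n$ is the total number
of unambiguous bases.

For a word length $k$, the *dictionary* $D_k$ is the set of distinct
$k$-mers, each with a *multiplicity* (occurrence count, overlaps allowed).
Words of multiplicity 1 are *hapaxes*; the *maximal repeat length* (mrl) is
the largest $k$ at which any repeat exists. The occurrence total is
$W_k = \sum_r \max(0, |r| - k + 1)$ over runs $r$; for a single run this is
the familiar $n - k + 1$.

The *empirical $k$-entropy* is the Shannon entropy of the $k$-mer frequency
distribution,
$E_k = -\sum_{w \in D_k} f_w \log_2 f_w$ with $f_w = \mathrm{mult}(w)/W_k$.
By the equipartition property $E_k \le \log_2 W_k$, with equality exactly
when every word is a hapax.

## The indexes

Write $LG = \log_4 n$ (*logarithmic length*) and $2LG = \log_2 n$ (*double
logarithmic length*), the word-length scale at which random genomes attain
maximal entropy. Because $2LG$ is rarely an integer, $E_{2LG}$ is obtained
by linear interpolation between the bracketing integer word lengths
$k_1 = \lfloor 2LG \rfloor$ and $k_2 = \lceil 2LG \rceil$ with weight
$w = 2LG - k_1$:
$E_{2LG} = (1 - w)\,E_{k_1} + w\,E_{k_2}$. When $2LG$ is an integer the two
collapse and no interpolation occurs.

From $E_{2LG}$ the package derives:

* **entropic component** $EC = E_{2LG} - LG$ and **anti-entropic
  component** $AC = 2LG - E_{2LG}$, which conserve $EC + AC = LG$ by
  construction (verified to $10^{-9}$ in the validity method);
* **anti-entropic fraction** $AF = AC / LG$ and **horizontal eccentricity**
  $EH = 1 - 2\,AF$;
* **lexical index** $LX = W_k / |D_k|$ at $k = 2LG$. The default evaluates
  $LX$ at $k_1$ and $k_2$ and interpolates linearly (`method =
  "interpolate"`); `method = "round"` instead evaluates it once at
  $k = \mathrm{round}(2LG)$. Interpolation is the default because it treats
  $LX$ consistently with $E_{2LG}$; the rounded variant is retained because
  the integer-$k$ bound $\log_2 LX_k \le \log_2 n - E_k$ is a theorem only
  at integer $k$, and the law checker uses the rounded value for that test.
* **biobit** $BB = s \cdot AF^{\gamma} (1 - 2AF)^{\delta}$, with defaults
  $\gamma = 0.5$, $\delta = 3$ and scale $s = LG$ (the `NA` sentinel in
  `BBParams` means "use $LG$"). $\delta = 3$ follows the shape used in the
  literature for the anti-entropic penalty; $\gamma = 0.5$ is a package
  default chosen so that the balance rises steeply from $AF = 0$ and peaks
  at $AF^\* = \gamma / (2\gamma + 2\delta) = 1/14 \approx 0.0714$. Both
  exponents and the scale are configurable everywhere (`BBParams`,
  `--bb-gamma`, `--bb-delta`, `--bb-scale`); results computed under
  non-default exponents are not comparable to defaults and the parameters
  are therefore embedded in every serialized report. For $AF \ge 1/2$ the
  balance term is negative; the implementation uses the signed magnitude
  $\mathrm{sign}(b)\,|b|^{\delta}$ so that super-ordered genomes map to
  $BB \le 0$ rather than to a complex number.

## Random-genome theory

`generateRandomGenome` draws bases iid uniformly (a Bernoullian genome).
Three closed forms are provided:

* `expectedHapaxLength(n)`: the smallest $k$ with $2^k \ge n - k + 1$, the
  length from which a random genome is expected to be repeat-free;
* `maxEntropyBound(n, k)`: the equipartition ceiling $\log_2(n - k + 1)$;
* `randomEntropyGapBound(n)`: the bound
  $\log_2\!\big(n / (n - \lceil \log_2 n \rceil + 1)\big)$ on the gap
  $\log_2 n - E_{\lceil \log_2 n \rceil}$ of a random genome.

One property of the gap deserves a precise statement. By equipartition the
gap can never be *smaller* than the bound: the gap **equals** the bound
exactly when every word at that length is a hapax, and exceeds it otherwise.
For a random genome the deficit caused by chance repeats is tiny but has
positive probability at any realistic length, so the gap should be asserted
as lying in a narrow band *at or above* the bound, not strictly below it.
The unit tests assert the two-sided band; at the equality point a strict
comparison of the two floating-point expressions measures rounding noise
only.

`mrlTrials` reproduces the repeated-trials design for the statistics of
mrl + 1 over seeded random genomes: the master seed deterministically spawns
one sub-seed per (length, trial) up front, so any subset of the table can be
recomputed independently. Sample standard deviation uses the $n - 1$
denominator. The default lengths ($10^3$ to $10^7$) and 100 trials are the
package's study conditions, chosen to keep the full table within minutes on
one CPU; smaller trial counts are an explicitly documented scaled-down mode
with proportionally wider sampling error.

## Engine

All spectra and mrl values come from one suffix structure per genome: a
suffix array built with the SA-IS algorithm over the run-concatenated text
(runs joined by separator symbols), plus a Kasai LCP array *capped* at run
boundaries, so that no reported word spans a boundary. The engine is exact —
no sketching or sampling — and is validated in the tests against naive
string-matching oracles on hundreds of random and structured inputs.

## Genomic laws and perturbations

`verifyLaws` evaluates, for any `InformationalIndexes` object:
L1 $LG < E_{2LG} < 2LG$; L2 $EC > 0$ and $AC > 0$; L3 $EC > AC$; L4
$LX \ge 1$; L5 $\log_2 LX_k \le \log_2 n - E_k$ at $k = \mathrm{round}(2LG)$
(a theorem, checked to $10^{-9}$). L1–L3 are empirical regularities: they
*should* fail on deliberately degenerate inputs such as periodic genomes,
and the report treats failures as data, not errors. Additional named
predicates can be registered via `extraLaws`.

`applyEdits` perturbs a genome with an `EditPlan` of non-overlapping
deletions and window shuffles, all expressed in coordinates of the
*original* genome (0-based), so a plan is a declarative description rather
than a sequential script. Shuffles are seeded by the plan.
`lawSurvivalScan` tabulates indexes and law outcomes across plans,
capturing per-plan errors instead of aborting.

## Fixture generators

The fixture corpus spans the order axis at fixed length: `random` genomes
($AF \approx 0$), `periodic` genomes (maximal order, $AF > 1/2$), and
`block-mixture` genomes that concatenate a periodic block of length
$\mathrm{round}(f \cdot n)$ with a random remainder in a single run. The
ordered fraction $f$ is a modelling dial of this generator only — it does
not correspond to any measured genomic quantity — but sweeping it moves
$AF$ continuously from near 0 to near its maximum, which is what makes the
rise-and-fall shape of the biobit observable on synthetic data. The
generator deliberately does **not** emulate biological genome structure
(no isochores, repeat families, or compositional skew).

## Limitations

* Indexes require $n \ge 4$ (so $LG \ge 1$); the double-logarithmic scale is
  only meaningful for genomes much longer than that.
* Interpolated quantities depend on the bracketing convention; comparisons
  across tools should confirm the same convention.
* The biobit's absolute value depends on $(\gamma, \delta, s)$; only values
  computed under identical parameters are comparable.
* Memory: the suffix structure keeps three integer arrays of the text
  length; a $10^7$-base genome uses on the order of a few hundred MB
  transiently.
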