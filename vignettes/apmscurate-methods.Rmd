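---
title: "Curating AP-MS interactomes with peptide-competition and bait-null controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating AP-MS interactomes with peptide-competition and bait-null controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmscurate)
```

## The problem

An affinity-purification mass-spectrometry (AP-MS) experiment recovers a
bait protein together with everything that co-isolates with it — genuine
binding partners, but also proteins that bind the beads, the antibody, or
abundant cellular machines that end up in every pulldown. Spectral counts
(peptide-spectrum matches, PSMs) give a semi-quantitative measure of how
much of each protein was recovered, but counts alone cannot separate a
specific prey from sticky background.

This package implements a curation strategy built on two orthogonal
negative controls:

* **Peptide competition.** The same immunoprecipitation is repeated in
  the presence of an excess of the antigenic peptide the antibody was
  raised against. The peptide occupies the antibody's binding site, so
  bait-dependent preys drop out while bead background is unchanged.
  Specificity is scored per protein as the ratio of summed PSMs without
  versus with competitor.
* **Genetic null.** The isolation is repeated in cells lacking the bait.
  Anything recovered there is nonspecific by construction and is removed
  from every experimental hit list.

The design is run under two physiological conditions — copper depletion
with the chelator BCS and copper loading with CuCl~2~ — for a
copper-regulated bait. Hits are reconciled across conditions: their union
is the interactome, and the intersection (proteins recovered regardless
of copper status) is the *core* of stable and/or strong interactors.
Finally, the curated interactome is audited against a contaminant
compendium (a CRAPome-style bead proteome): a well-curated specific
interactome should share only a few percent of its members with what
binds beads alone. Flagged proteins are annotated, not removed — the
overlap is a quality check, not a filter (removal is available behind
`drop_contaminants = TRUE`).

## The calling rule

For one condition, PSMs are first summed per protein within each arm
across replicate IPs — counts are additive evidence, and summing before
forming the ratio is more stable than averaging per-replicate ratios
(per-replicate calling remains possible by running conditions as separate
designs). With $a$ the summed count without competitor and $b$ with
competitor, the enrichment ratio is

$$ r = \frac{a + c}{b + c}, $$

with pseudocount $c = 0.5$ by default, and a protein is called when
$r > \tau$ with $\tau = 2$. Two deliberate choices at the edges:

* **Strict inequality.** Exactly 2-fold is a fail by default. The
  comparison can be switched to $\geq$ (`ge = TRUE`); at integer counts
  the difference is confined to exact-doubling ties.
* **Zero in the competition control.** A protein with $b = 0$ and
  $a \geq$ `min_count` (default 2) passes outright with ratio $\infty$:
  repeated observation only when the antibody is free is the strongest
  qualitative evidence this design can produce. With $a$ below
  `min_count` the pseudocount takes over, so a single stray spectrum
  cannot pass on division noise.

Only proteins observed (summed PSM $\geq 1$) in the minus-peptide arm
receive a record; the bait itself is scored like any protein (a sanity
check that the isolation worked) but excluded from the reported
interactome and from enrichment hit lists, because it is the bait, not a
prey.

Null subtraction then removes any hit whose summed PSM across bait-null
samples reaches `null_min_count` (default 2, again avoiding one-hit
removals; set 1 to remove on any evidence). The null arm is treated as a
single minus-peptide isolation. Curation without a null control must be
requested explicitly (`allow_missing_null = TRUE`); silently skipping a
control would be worse than failing.

The contaminant overlap is reported as a percentage of the interactome,
rounded half-up to one decimal. As a desk check, an interactome of 541
proteins sharing 31 members with a 335-protein bead proteome is a 5.7%
overlap:

```{r overlap}
ia <- sprintf("P%03d", 1:541)
beads <- c(ia[1:31], sprintf("C%03d", 1:304))
contaminant_overlap(ia, beads)$percent
```

## Over-representation scoring

Curated hit lists are scored against GMT gene-set collections with the
exact upper-tail hypergeometric test: with $N$ the universe size, $K$ the
set's members inside the universe, $n$ the hit-list size and $k$ the hits
in the set, $p = P(X \geq k)$ for $X \sim \mathrm{Hyper}(N, K, n)$.
Alongside $p$ we report a Benjamini–Hochberg $q$, a Haldane-corrected
odds ratio, the hypergeometric z-score

$$ z = \frac{k - nK/N}{\sqrt{nK(N-K)(N-n)/\left(N^2(N-1)\right)}}, $$

and the ranking statistic $c = z \cdot (-\log_{10} p)$, the combined
score popularised by web enrichment services. A deliberate deviation:
those services compute $z$ from rank deviations against background
permutations that cannot be reproduced offline; the hypergeometric
standardisation used here is exactly reproducible and agrees in sign and
ordering for the over-representation case, but published combined-score
magnitudes from such services are not comparable to ours and are not
treated as reference values. The logarithm base (10) is configurable.

The default universe is the *detected proteome* — every protein
quantified in any IP arm — intersected with the collection's members.
Testing against all annotated genes would inflate enrichment for anything
abundant enough to detect by MS; the detected-proteome background is the
standard guard against that abundance bias. Sets are restricted to the
universe before size filtering (`min_set = 3`, `max_set = 2000`; smaller
sets cannot reach meaningful significance, larger ones are
uninformative), matching is case-insensitive on gene symbols (protein
identifiers, by contrast, are never case-folded — accessions are
case-significant), and BH adjustment spans all tested sets of a
collection.

## The synthetic benchmark

Because raw MS data are neither needed nor desk-scale, the package ships
a generator that emulates the statistical structure the curation assumes.
`sim_config()` defines five arms — wild-type BCS and CU, each with and
without competing peptide, plus a single bait-null isolation — and draws
PSM counts from a negative binomial parameterised by mean and size
(`dispersion`); overdispersion is the norm for spectral counts, and the
Poisson limit is recovered as the size grows.

Default settings: 150 true preys at mean 25 PSMs, 800 background proteins
at mean 8 PSMs, dispersion 5, competitive suppression 0.1, half the preys
shared between conditions (the private rest split evenly, odd remainder
to BCS), and a fixed bait count of 100 so bait detection is
deterministic. 40% of background proteins are placed on the simulated
contaminant list — bead-proteome repositories catalogue a large share of
recurrent background, and the exact fraction only scales the overlap
audit, not the curation. One top-level seed drives per-arm substreams
(`seed + ` a fixed offset per arm), so adding arms or replicates never
reshuffles existing draws, and generation is byte-reproducible.

Two structural choices deserve their rationale:

* **Leak into the null arm.** True preys draw counts in the bait-null arm
  (and in the arms of conditions they do not belong to) with a small mean,
  `null_leak` × `mu_background`, default 0.025 (mean 0.2 PSMs). A genetic
  null contains essentially no bait-dependent signal, so the leak is kept
  small — at dispersion 5 it removes about 2% of true preys through null
  subtraction, enough to exercise the subtraction nontrivially without
  turning the null control itself into a major source of false negatives.
  Setting it as high as 0.1 of `mu_background` makes null subtraction
  strip roughly a fifth of genuine preys; `null_leak = 0` gives a
  structurally clean null. The parameter is bounded at 0.1.
* **The no-effect control needs matched means.** With `suppression = 1`
  the competing peptide does nothing and true preys should be
  statistically indistinguishable from background. That holds only when
  the class means match: the pass probability of a count-ratio filter
  depends on the mean even without enrichment (about 0.165 at mean 25
  versus 0.195 at mean 8, dispersion 5), because larger counts
  concentrate the ratio near 1. The shipped control therefore sets
  `mu_true = mu_background`, making the two classes exchangeable by
  construction; the test asserts equal pass rates within Monte-Carlo
  error.

What the simulator does *not* emulate: peptide-level evidence and protein
inference, retention times or intensities, correlated background across
arms (batch structure), compositional competition for MS sampling depth,
or a rescue arm. Passing benchmarks therefore demonstrates that the
curation logic recovers truth under the count model it assumes — not that
the thresholds are optimal for any particular instrument or search
pipeline.

At the default settings the expected behaviour, calibrated by simulation
before the tests were frozen, is per-condition ratio-filter sensitivity
around 0.97, overall recall around 0.96 after null subtraction, and
precision around 0.95; the acceptance checks hold recall to at least 0.8
across replicate seeds.

## Numerical and interface choices

* Exact hypergeometric tails (`stats::phyper`), never a normal
  approximation; the z-score is a descriptive standardisation, not a
  test.
* The z-score is defined as 0 when the null variance is 0 (degenerate
  margins), which also forces the combined score to 0 there.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite checks it against a literal step-up double loop.
* Percentages are rounded half away from zero (half-up) to one decimal;
  base R's round-half-even would report 12.45% as 12.4%.
* Ties in enrichment ranking break by smaller $p$, then set name, so
  output order is total and reproducible.
* All tabular formats are strict TSV (tab-only, no quoting, LF, UTF-8),
  matching the GMT convention; duplicate (protein, sample) PSM rows are
  summed at read time; degenerate inputs (empty contaminant list,
  header-only PSM table) warn rather than fail, while a missing control
  arm or an out-of-domain parameter is a hard configuration error.
* Set operations return lexicographically sorted identifiers, so
  downstream files are byte-stable and reruns are idempotent.

Problem sizes in the shipped tests were chosen to keep the full suite
fast: oracle-equivalence sweeps use ≤ 50-protein simulations (where
exhaustive straight-line recomputation is trivial), invariance sweeps use
20–50 replicate seeds, and the benchmark runs use the default 951-protein
design.

## Known limitations

* The curation is a deterministic rule set, not a probabilistic
  interaction model; no posterior scores (SAINT/CompPASS-style) are
  produced.
* Identifier namespaces are the caller's responsibility: contaminant
  lists and PSM tables must share a namespace, and gene-set matching
  assumes symbols. A mapping table must be applied upstream when they
  differ.
* GO topology is ignored: redundant, nested terms are tested
  independently and no term-collapsing is attempted.
* Published combined scores from rank-based web services are not
  reproducible offline and are not comparison targets (see above).
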