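---
title: "Screening protein sequences for charge clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein sequences for charge clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chargescan)
```

## The detection model

A charge cluster is a run of residues of one charge sign — positive
(lysine, arginine) or negative (aspartate, glutamate) — dense enough that
it is unlikely to arise from the proteome's background composition.
Histidine, whose side chain is only partially protonated at physiological
pH, and the ambiguity letters B, Z, X, U, O and J are treated as neutral:
they can dilute a cluster but never seed one, the conservative choice for
a screen.

The null model is i.i.d. residues with class frequency $p_0$. For every
window of width $w$ (default 20) the count $k$ of class residues is
scored by the exact binomial upper tail
$P(X \ge k),\ X \sim \mathrm{Binomial}(w, p_0)$, and the window is
significant when that probability is at most $\alpha$ (default $10^{-5}$).
Because the tail is monotone in $k$, this is equivalent to a critical
count $k^\* = \min\{k : P(X \ge k) \le \alpha\}$, which is how
`scan_protein()` evaluates windows after computing rolling counts; the
per-window tail probabilities are recovered exactly for reporting.
Overlapping significant windows are merged by taking the union of the
residues they cover; each maximal covered region is trimmed inward to the
first and last residue of the class, so a reported cluster always begins
and ends on a charged residue and may be shorter than $w$. Proteins
shorter than $w$ are evaluated as a single window of their own width
rather than skipped — real proteomes contain proteins barely longer than
the window, and silently dropping them would bias the screen.

The two polarities are scanned independently and may overlap; *mixed* is
purely a protein-level label (at least one cluster of each sign). No
minimum cluster length is imposed beyond trimming, and no correction is
applied across windows: $\alpha$ is a per-window level, chosen stringent
enough ($10^{-5}$) that the expected number of false windows stays small
even over proteome-scale window counts.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `window_w` | 20 aa | width of the sliding window |
| `alpha` | 1e-5 | per-window binomial tail level |
| `background_mode` | `proteome` | pooled class frequency over all input residues |
| `positive_alphabet` | K, R | positive class |
| `negative_alphabet` | D, E | negative class |

The pooled (`proteome`) background is the stable default: per-protein
frequencies are noisy for short proteins and would let a uniformly charged
protein mask its own clusters. `per_protein` and `fixed` are provided for
sensitivity analysis and controlled experiments.

## Domain-relative mapping

Domain annotations (a simplified Pfam-style hit table) are merged per
protein — overlapping or abutting intervals become one — and each cluster
is assigned exactly one category: `n_terminal` (wholly before the first
domain), `c_terminal` (wholly after the last), `interdomain` (wholly
inside a gap), `domain`, or `unannotated` when the protein has no
annotation. A cluster straddling a domain boundary is assigned by majority
overlap between its in-domain residues and each flanking region it
touches, with ties going to `domain`; the majority rule is the natural
single-category assignment when the source of truth does not state one.
Unannotated clusters are excluded from contingency tables and reported as
a separate count, since located totals can legitimately fall short of
detected totals.

## Conservation grouping

Two clusters of the same polarity from different proteins are *conserved*
copies when their alignment identity reaches a threshold (default 1,
i.e. exact sequence identity — repeats across strain variants of the same
protein are the archetypal case). Identity is computed from a global
alignment with match +1, mismatch 0 and cost-free gaps, whose optimal
score is the longest common subsequence; the identity denominator is the
longer sequence length, so a short perfect substring cannot claim full
identity against a longer cluster. Groups are connected components of the
similarity graph restricted to cross-protein edges, reported only when
they span at least two distinct proteins, and ordered deterministically by
polarity, smallest member protein id and start.

## Comparative statistics

Location-by-polarity tables are tested with the Pearson chi-square test of
independence, with an optional fixed-margin Monte Carlo p-value for
small-count tables; a linear-by-linear trend statistic is deliberately not
offered because the four location categories have no natural ordering.
The Monte Carlo p agrees with the analytic tail only in the asymptotic
regime — the fixed-margin null is discrete, and for 2×2 tables the
discrepancy exceeds Monte Carlo error even at counts of a few hundred —
so the cross-check between the two methods is performed on large
multi-category tables. Protein-length comparisons use the Welch *t*-test
with a Mann–Whitney companion (length distributions are heavy-tailed);
multi-group length comparisons use fixed-effects one-way ANOVA.

## The synthetic proteome generator

`generate_proteome()` builds proteomes in which every pipeline claim can
be tested against known truth:

* **Lengths** are log-normal with `meanlog = 5.717`, `sdlog = 0.9458` —
  moment-matched to a mean of 475 aa and standard deviation of 572 aa —
  and clipped to [25, 18212] aa, the span observed in complete viral
  proteomes.
* **Background** residues are i.i.d. from a 20-letter table with
  K + R = 0.10 and D + E = 0.12 by default, typical charged-class
  frequencies; both are configurable per experiment.
* **Plants** are segments of stated length and charge density placed at
  uniformly chosen admissible positions; same-polarity plants within one
  protein keep at least `min_separation` (default 20) background residues
  between them. A plant with `copies = c` writes the identical segment
  into `c` distinct proteins.
* **Truth re-anchoring and guard zones.** The recorded truth interval is
  trimmed to the plant's first and last charged residue, and background
  residues of the plant's own class within `min_separation` of either end
  are resampled to neutral letters. Both serve the same purpose: the
  detector trims merged windows to charged boundaries, so without the
  guard zone a detection would extend to whatever charged background
  residue happens to sit within window reach, making truth coordinates
  and cross-copy sequence identity stochastic rather than exact.
* **Domains** per protein are Poisson (mean 1.5) with lengths uniform on
  30–200 aa and uniform placement; **metadata** assigns synthetic family
  and genome-group labels round-robin.

Recovery is scored by greedy one-to-one matching of truths and detections
at interval Jaccard ≥ 0.5, giving precision and recall.

What the generator does *not* emulate: real domain-composition coupling,
family-specific amino-acid usage, phylogenetic correlation between
proteins, and disorder. Passing recovery tests therefore demonstrates the
detector's statistical behaviour under its own null and plant model, not
performance on any particular real proteome.

### Problem sizes

The test suite and the acceptance script run the recovery benchmark at
100 proteins × 20 simulated proteomes (400 planted clusters of lengths
12–30 aa at density 1, positive-class background 0.05, fixed
$p_0 = 0.05$), the oracle-equivalence check on 500 random sequences of
10–200 aa, and the end-to-end screen at 200 proteins — sizes at which
every property is measured with comfortable margins while the whole suite
runs in well under a minute.

## Numerical choices and degenerate inputs

* Binomial tails come from `pbinom(k - 1, n, p0, lower.tail = FALSE)`,
  exact to well beyond 10 significant digits for window widths in use;
  the test suite cross-checks them against direct probability-mass
  summation.
* `critical_count()` returns `NA` when even a fully charged window is not
  significant; the scanner then reports no clusters rather than erring.
* A candidate region with no class residue after trimming is impossible
  once a window has triggered, but is guarded: dropped with a warning.
* Cluster tables serialise `min_window_p` with 17 significant digits so
  the write–read round trip is bit-exact.
* All coordinates are 1-based inclusive everywhere — in memory, on disk
  and in reports.

## Known limitations

The per-window level $\alpha$ is not corrected for the number of windows,
so the false-cluster rate scales with proteome size (kept negligible at
the default $\alpha$). The i.i.d. background ignores local composition
autocorrelation, which makes the null slightly conservative inside
low-complexity regions. Conservation at exact identity misses conserved
clusters that differ by a single substitution — the identity threshold is
exposed for exactly that reason. Structure-based charge analysis,
disorder prediction and pH-dependent protonation are out of scope.
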