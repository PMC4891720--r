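---
title: "Homo-repeat statistics under an i.i.d. null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homo-repeat statistics under an i.i.d. null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrun)
```

## The question

Proteomes contain striking runs of single amino acids — poly-Q tracts of
twenty residues, poly-A stretches in transcription factors. Are such runs
remarkable, or simply what a random sequence of the same composition would
produce? `polyrun` answers this by comparing observed repeat counts against
an exact null model, and then asks two follow-up questions: are
repeat-bearing proteins over-represented among disease-annotated proteins,
and are repeats enriched in externally defined protein sets?

## The exact longest-run law

The null model treats a protein as a chain of length $L$ whose residues are
drawn independently; the focal amino acid appears at each position with
probability $p$. The quantity of interest is $M$, the length of the longest
run of the focal amino acid (0 if it is absent).

The law of $M$ is computed by dynamic programming over the joint state
$(M, K)$, where $K$ is the length of the run touching the C-terminal end
($K = 0$ if the chain ends in another residue). Extending the chain by one
residue either:

* appends the focal residue: $(M, K) \to (M, K+1)$ with weight $p$, with the
  promotion $(M, M) \to (M+1, M+1)$ when the terminal run already equals the
  record; or
* appends any other residue: $(M, K) \to (M, 0)$ with weight $1 - p$.

A one-residue chain starts at $P(M{=}0, K{=}0) = 1-p$ and
$P(M{=}1, K{=}1) = p$; marginalizing over $K$ at any length gives
$P(M \mid p, L)$. Because the recursion runs over chain length, a single
sweep to the largest length in a proteome serves every length in its
distribution. The implementation is validated against full enumeration of
all $2^L$ strings for $L \le 14$ at probabilities from 0.01 to 0.5
(agreement to $10^{-12}$), and the test suite keeps that comparison alive.

Expected protein counts follow by weighting with the length distribution
$n_L$:

$$\langle N(M) \rangle = \sum_L n_L \, P(M \mid p_a, L),$$

with $p_a$ the background frequency of amino acid $a$. Note that $P$ here is
an *exactly-M* probability; cumulative ("at least $M$") figures are tail
sums, available via the `at_least` counting mode.

```{r}
profile <- as_proteome_profile(tibble::tibble(length = 395, count = 59053))
ec <- expected_counts(profile, "Q", p = 0.05, m_max = 12)
ec[ec$M %in% 4:7, ]
```

At human-proteome scale (59,053 chains, mean length 395, uniform residue
probability 1/20) only ~6.5 proteins are expected to have a longest run of
exactly 5, and ~0.3 a run of 6 — the baseline against which real repeat
counts are judged. The single fixed length stands in for the full length
distribution here because only the mean is published for that proteome; the
machinery accepts any `length`/`count` table.

## The closed-form approximation and its domain

When a run of length $M$ is rare, placement counting gives

$$P \approx 2\,p^M(1-p) + (L-M-1)\,p^M(1-p)^2,$$

two terminal placements flanked by one different residue and $L-M-1$
interior placements flanked by two. The approximation is reliable for
$p \le 0.05$, $M \ge 4$ and $Lp^M < 0.01$ (for residues with $p \approx
0.1$, such as leucine, from $M \ge 5$); `approx_repeat_probability()` warns
whenever $Lp^M \ge 0.01$. The tests verify agreement with the recursion to
within 5% across that domain.

## Numerical choices

* The $(M, K)$ table is iterated in linear probability space; the smallest
  quantities involved ($\sim p^M$) are far above double-precision underflow
  for every practically relevant $M$, so no log-space transform is needed.
* `m_max` truncates the table as an optimization: states with $M \ge
  m_{\max}$ are lumped into an absorbing tail bin, which is exact for the
  retained entries and conserves total mass to $10^{-12}$ (tested). The
  default (40) comfortably exceeds any repeat length with non-negligible
  null probability.
* Expected-count sweeps are shared between amino acids with identical
  background frequency, so uniform-composition analyses cost one sweep for
  all twenty.
* Coordinates in all run tables are 1-based with closed start/end, the
  convention of the R sequence-analysis stack (IRanges/Biostrings); the
  `length` column makes the intervals unambiguous.
* A printed inconsistency in the source recursion's base case (the roles of
  $p$ and $1-p$ swapped relative to the definition of $p$) is resolved in
  favour of the definition; the brute-force enumeration oracle pins the
  choice down.

## The 10-fold rule

`fold_comparison()` aligns observed and expected counts per repeat length
(ratio conventions: $0/0 = 0$; positive observed over zero expected is
flagged infinite, and TSV output carries the flag rather than a numeric
sentinel). `minimal_significant_length()` then reports the smallest $M$
with at least `min_observed` proteins observed and a fold ratio of at least
`fold_threshold` (default 10).

A known limitation, kept deliberately: with `min_observed = 1`, any single
protein whose longest run lands where the expectation is below 0.1 triggers
the rule. Under a pure null these events have probability roughly equal to
the summed sub-0.1 expectations — a few percent per amino acid near the
detection boundary, so across 20 amino acids a null proteome of tens of
thousands of proteins shows at least one spurious flag in a nontrivial
fraction of realizations (about one in five in our simulations). Raising
`min_observed` to 2–3 suppresses this at a small cost in sensitivity; the
default stays at 1 to count every protein, as repeat surveys conventionally
do, and users screening many proteomes should treat boundary-expectation
flags with caution.

## Disease association

With $N$ proteins, $N_a$ disease-annotated, $N_b$ carrying a homo-repeat of
length $\ge 5$ (configurable) and $N_{ab}$ both, independence predicts
$\mu = N_a N_b / N$ with rms deviation
$\sigma = \sqrt{\mu (1 - N_a/N)(1 - N_b/N)}$, and $Z = (N_{ab} - \mu)/\sigma$.
The shrinkage factors $(1 - N_a/N)(1 - N_b/N)$ are the finite-margin
correction of the binomial/hypergeometric family; a plain Poisson
$\sigma = \sqrt{\mu}$ is available behind `sd_method = "poisson"` and is
always more conservative. Bands follow the conventional colour coding:
strong for $Z > 5$, moderate for $3 < Z \le 5$.

```{r}
az <- association_z(human_disease_counts())
az[az$band != "none", c("amino_acid", "N_b", "N_ab", "z", "band")]
```

With the packaged human counts this yields the strong set
{L, A, G, S, P} and places E, Q, D, H (and, marginally, V) in the moderate
band.

## Resampling enrichment of target sets

For an externally defined protein set (e.g. proteins harbouring neuronal
micro-exons), `resample_enrichment()` counts target proteins whose longest
run of each amino acid reaches each motif length (4–9 by default,
cumulative counting — per-protein counts are then non-increasing in motif
length; an exact-length mode exists). It draws `n_samples = 20` same-size
sets uniformly without replacement from the whole universe (targets not
excluded), and standardizes the target count against the resample mean and
standard deviation. Cells with zero resample spread get $z = 0$ when the
target count matches, and an infinite, flagged $z$ otherwise — flagged, not
crashed, since with 20 draws a rare repeat can legitimately never be
sampled. Everything is deterministic given `seed`.

## What the synthetic generator emulates — and what it does not

`sample_null_proteome()` draws i.i.d. residues with lognormal chain lengths
(mean 395, sd 530, clamped to [30, 10000]) matching the human proteome's
published moments; the lognormal is chosen for its heavy right tail, the
shape real proteome length distributions have. `spike_repeats()` inserts
(never overwrites) runs at uniform positions so background composition is
preserved, and records ground truth. `simulate_disease_labels()` applies a
relative risk to a target set; `simulate_interaction_edges()` draws
per-protein target degrees from Poisson means and pairs degree stubs
uniformly (configuration-model style), which recovers group mean degrees —
an independent-partner-choice scheme would inflate every degree by the
population mean and was rejected for that reason.

Real proteomes violate the i.i.d. assumption in known ways the generator
does not emulate: compositional autocorrelation along sequences,
low-complexity regions beyond single-residue runs, and family-level
redundancy between entries. Passing the null-recovery and spike-in tests
therefore shows the *pipeline* is correct and calibrated under its stated
null — it does not show that real proteomes obey that null (they do not;
that departure is precisely what the method measures).

## Problem sizes used by the test suite

The end-to-end checks run at sizes chosen to exercise proteome-scale code
paths while staying desk-friendly: one 50,000-protein null proteome for the
observed-vs-expected comparison (all bins with expectation $\ge 5$ within
$3\sqrt{\text{expected}}$); ten 20,000-protein null proteomes for the
10-fold-rule false-flag rate; twenty seeds of a 10,000-protein universe
with 100 spiked targets for resampling power; and fifty seeded null target
draws against a 5,000-protein universe for calibration (fewer than 1% of
cells beyond $|z| = 5$).

## Known limitations

* The null is i.i.d. within and across proteins; no correction for
  compositional correlation or homologous redundancy.
* Only single-residue runs are modelled — no $k$-mer tandem repeats or
  SEG-style heterogeneous low-complexity regions.
* The 10-fold rule's boundary behaviour at sub-0.1 expectations (above).
  The resampling test shares a milder version of this multiplicity effect:
  with 120 cells per run and only 20 resamples per cell, screening many
  target sets will occasionally produce a near-threshold or degenerate-
  infinite cell outside the truly enriched amino acid.
* The disease Z-score is a marginal test per amino acid with fixed bands;
  no multiplicity correction across amino acids is applied.
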