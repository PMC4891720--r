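# polyrun

Homo-repeat detection and null-model statistics for proteomes.

Homo-repeats — uninterrupted runs of a single amino acid such as poly-Q or
poly-A — are common in eukaryotic proteins and linked to more than twenty
hereditary diseases, yet in any given proteome it is not obvious which repeat
lengths are remarkable and which are just what random composition produces.
`polyrun` is for sequence analysts who want to answer that question
quantitatively: it scans protein FASTA files for maximal single-residue runs,
computes the *exact* null distribution of the longest run under independent
residue sampling, and flags the repeat lengths whose observed protein counts
exceed the null expectation by a chosen factor. It also quantifies whether
repeat-bearing proteins are over-represented among disease-annotated proteins
(contingency Z-score), whether a protein target set is enriched for repeats
(seeded resampling), and how interaction degree varies across repeat classes.
A synthetic proteome generator with recorded ground truth makes the whole
pipeline testable end to end without downloading anything.

## The model

For a chain of length *L* in which the focal amino acid occurs independently
with probability *p*, track the pair (*M*, *K*): the longest run seen so far
and the length of the run touching the C-terminal end. Appending the focal
residue maps (*M*, *K*) → (*M*, *K* + 1), or (*M*, *M*) → (*M* + 1, *M* + 1);
appending any other residue resets *K* to 0. Starting from
P(*M* = 0, *K* = 0 | *L* = 1) = 1 − *p* and P(*M* = 1, *K* = 1 | *L* = 1) = *p*
and marginalizing over *K* gives the exact law P(*M* | *p*, *L*) of the
longest run. Summing over a proteome's length distribution *n<sub>L</sub>*
yields the expected number of proteins whose longest run equals *M*:

    N(M) = sum_L  n_L · P(M | p, L)

For rare repeats (*L·p^M* < 0.01, *p* ≤ 0.05, *M* ≥ 4) the closed-form
placement approximation

    P(M | p, L) ≈ 2 p^M (1 − p) + (L − M − 1) p^M (1 − p)^2

agrees with the recursion to within a few percent. Observed counts come from
the scanner; the *10-fold rule* reports, per amino acid, the smallest repeat
length at which the observed count is at least ten times the expectation.
Disease association uses mean = N<sub>a</sub>N<sub>b</sub>/N,
sd = sqrt(mean (1 − N<sub>a</sub>/N)(1 − N<sub>b</sub>/N)) and
z = (N<sub>ab</sub> − mean)/sd, banding z > 5 as strong and 3 < z ≤ 5 as
moderate.

## A worked example

The human proteome has 59,053 entries with mean chain length 395. At a
uniform residue probability of 1/20, how many proteins are *expected* to
carry a longest run of exactly 5, or 6, of some particular amino acid?

```r
library(polyrun)
profile <- as_proteome_profile(tibble::tibble(length = 395, count = 59053))
ec <- expected_counts(profile, "Q", p = 0.05, m_max = 12)
ec$expected[ec$M %in% 5:6]
#> [1] 6.5133907 0.3248551
```

About 6.5 proteins are expected at run length 5 and 0.3 at length 6 — so the
hundreds of poly-Q, poly-E or poly-A proteins seen in real proteomes are far
beyond compositional chance. The disease side, from the packaged human
OMIM/repeat contingency counts:

```r
az <- association_z(human_disease_counts())
dplyr::filter(az, band != "none")[, c("amino_acid", "N_b", "N_ab", "z", "band")]
#>    amino_acid   N_b  N_ab    z     band
#>  1 L           1503   125 7.96   strong
#>  2 V             49     7 3.49 moderate
#>  3 A           1300   105 6.95   strong
#>  4 G            836    67 5.46   strong
#>  5 S           1175    86 5.30   strong
#>  6 Q            529    41 4.03 moderate
#>  7 E           1625   108 4.89 moderate
#>  8 D            262    23 3.66 moderate
#>  9 H            148    16 3.98 moderate
#> 10 P           1363   114 7.66   strong
```

Poly-L, -A, -G, -S and -P proteins are strongly over-represented among
disease-annotated proteins (z > 5); poly-E, -Q, -D, -H (and -V) moderately so.
The full pipeline over a FASTA file, including these stages plus resampling
enrichment and interaction summaries, is one call:

```r
run_analysis("proteome.fasta", out_dir = "results", seed = 1)
```

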