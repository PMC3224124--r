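---
title: "Curating and mining clone-named EST libraries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and mining clone-named EST libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estcurate)
```

## The problem

Digital expression profiling from expressed sequence tags treats each cDNA
clone as one random draw from a tissue's transcript pool: the expression of
gene $x_i$ is estimated by its tag frequency $x_i / \sum x$, conventionally
reported per 10,000 clones. Two classes of bookkeeping error corrupt this
estimate in historical plated libraries:

1. **Re-sequencing redundancy.** A clone read from both its 5' and 3' ends
   (or re-sequenced in the same direction) contributes two or three reads
   but only one transcript observation. It must be counted exactly once.
2. **Plate-level naming errors.** Clone names encode the physical workflow
   — library stem, batch, plate (I–IV), 96-well coordinate, direction, as
   in `CA48LN09IF-A9, 5'end` — and that workflow goes wrong in stereotyped
   ways: well labels slip by a variable offset between a plate's 5' and 3'
   passes, whole plates are sequenced twice or three times under different
   names, the 3' plates of a batch are swapped, part of a plate is
   re-picked from another plate, and occasionally a plate is filed under
   the wrong library altogether.

`estcurate` implements both repairs and the downstream statistics: tag
frequency profiles, a multigroup chi-squared test and the exact
Audic–Claverie test for differential expression, average-linkage
clustering of significant-gene profiles, and cross-platform concordance
summaries.

## The dot-plot plate scan

For every (batch, plate, direction) of a library we materialize a
**plate sheet**: the 96 gene identifiers in well order A1, A2, …, H12
(`build_plate_sheets()`). Two sheets are compared exactly as a dot plot
compares two nucleotide sequences: `match_matrix()` marks every cell where
the gene ids agree (empty wells never match), and `detect_diagonals()`
extracts maximal diagonal runs. A correctly paired plate is a main
diagonal; a well slip is an off-diagonal or a piecewise chain of diagonals
whose offset changes mid-plate; a duplicated, swapped, or misfiled plate is
a strong diagonal where none should be.

Thresholds (`qc_thresholds()`): runs need `min_run = 4` matched wells and
tolerate `max_gap = 2` consecutive mismatches; pairs matching at
`t_full = 0.8` of their jointly non-empty wells are full relations
(correct pair / slip / duplicate / swap candidate), `t_partial = 0.3` to
`0.8` is a partial duplication, and fewer than `min_comparable = 10`
jointly non-empty wells is "no evidence". Genes occupying more than 10% of
a sheet's wells may extend but not seed a run, because a highly abundant
transcript paints spurious dots everywhere. None of these numbers is
prescribed by the underlying method; they are chosen so that a clean full
plate (with up to ~20% empty wells and the observed ~8% annotation
disagreement) is always classified, while two unrelated plates — whose
expected per-well collision probability is $\sum_g p_g^2 \ll 1/96$ for any
realistic transcriptome — essentially never produce a 4-run.

Pairwise classification cannot distinguish a plate-pair swap from a
quadruplicated plate set (in both, a 5' sheet matches another plate's 3'
sheet). The resolution happens in `build_correction_plan()` over connected
components of high-match relations: components carrying same-direction
duplicate evidence collapse to one retained physical plate; pure
complementary-direction components with a consistent perfect pairing
become pairing repairs; inconsistent components are excluded wholesale, as
a curator would. Cross-library duplicates exclude the copy that has no
correct in-library partner (ties: the lexicographically larger library
id). Applying a plan relabels or removes reads, never adds them.

## Redundancy collapse and frequencies

Clone identity is (library, stem, batch, plate, well) — direction is
deliberately excluded, so a 5'/3' pair is one clone (`group_clones()`).
Conflicting gene assignments within a clone keep the highest-confidence
id (ties: lexicographically smaller gene id, then read id). The collapse
obeys, and asserts, the conservation identity
$\text{unique} + \sum_k (k-1)\,n_k = \text{reads}$.

Library size is the **corrected unique-clone total**, and unannotated
clones stay in the denominator. Same-type libraries combine by the
size-weighted mean of their frequencies, which is algebraically the pooled
count frequency $10^4 \sum c_i / \sum n_i$ — the maximum-likelihood choice
under multinomial sampling, and the identity is tested to 1e-12.

## The two tests

**Chi-squared (g groups).** Goodness of fit of the observed counts to
expectations proportional to library sizes,
$\sum_j (c_j - e_j)^2 / e_j$, $e_j = (\sum c)\, N_j / \sum N$, with
$g - 1$ degrees of freedom, no continuity correction. Genes with fewer
than four tags in the whole dataset are excluded (reported, not tested).

**Audic–Claverie (pairs).** The exact conditional distribution of the
second count given the first,
$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$
summed into tails in log space; the smaller tail is always summed
directly, so p-values far below machine epsilon are still accurate to
~1e-13 relative. The two-sided significance is the doubled smaller tail,
capped at 1. Because the inclusive point mass makes the doubled-tail value
depend on which library is called "x" — while the choice is scientifically
arbitrary — the pair is first put in a canonical orientation
($N_1 \le N_2$, ties $x \le y$). This makes
`audic_claverie_p(x, y, N1, N2) == audic_claverie_p(y, x, N2, N1)` exact,
and it reproduces the conventional orientation for a small root library
against a large pooled background. Singletons (no side with at least two
tags) are removed before testing; Bonferroni control at $\alpha = 0.01$
over $m$ tests gives the conventional cutoff ($m = 3333$ yields
$3.0 \times 10^{-6}$). `m` defaults to the number of genes actually
tested and is exposed as a parameter because the historical tools did not
print theirs.

The AC implementation is verified against a frozen oracle computed once
with exact rational arithmetic (tails of $p(k\mid x)$ are finite exact
sums because the distribution sums to one): a 10×10 grid of $x, y$
spanning $[0, 50]$ for all nine size pairs from
$\{10^3, 10^4, 10^5\}^2$, stored as plain text under `tests/testthat/`.
No arbitrary-precision library is available to the offline test
environment, which is why the oracle is frozen rather than recomputed; an
independent double-precision direct-summation oracle (product-form terms,
no logarithms) runs at test time on random cases.

## Downstream statistics

Significant-gene profiles (per-10k frequencies, no further row scaling)
are clustered with distance $1 - r$ (Pearson) and average linkage (UPGMA,
delegated to `stats::hclust` behind `cluster_average()`, with a
deterministic subtree orientation so output is byte-stable; tests compare
it against a from-scratch brute-force agglomeration). Zero-variance rows
get distance 1 to everything and are flagged. Trees are cut at a fixed
$k$ (`cut_dendrogram()`); a height cut is the obvious alternative where a
fixed cluster count is not wanted.

Cross-platform agreement uses per-gene $\log_2$ ratios (pseudo-count 0.5
per-10k for zero frequencies — the choice is not prescribed anywhere, 0.5
tags being half the smallest observable count), Spearman/Pearson
correlations, and **directional concordance**: the fraction of genes whose
up/down direction agrees, $(n_{++} + n_{--})/n$, with exact-zero ratios
excluded from quadrant counts and reported separately.

## The synthetic world

`simulate_transcriptome()` draws gene abundances from a log-normal
(default 5,000 genes, sdlog 1.5); `simulate_library()` picks clones into
96-well plates (four plates per batch by default), sequences 80% of
plates bidirectionally (a per-plate Bernoulli draw — the rate real
plated libraries report), and misannotates each read with probability
0.04. The per-read rate is calibrated so that two reads of one clone
disagree about 8% of the time ($2q(1-q) + q^2 \approx 0.078$), the
within-clone disagreement real bidirectional libraries show; wrongly
annotated reads draw lower confidence scores so arbitration has signal.
Normalized libraries flatten sampling probabilities to $p^\gamma$
(renormalized), $\gamma = 1$ meaning unnormalized; at $\gamma \approx
0.5$ the singleton fraction approaches the ~54% seen in a real normalized
root library. `inject_errors()` applies the error taxonomy literally and
records an exact truth ledger.

Named scenarios (`end_to_end_fixture()`): `clean`, `table2_mixed` (one of
every error class across a leaf and a berry library), `root_vs_nonroot`
(18,109 root vs 291,233 non-root clones, 50 genes enriched 8-fold), and
`four_group_de` (four tissue/stress groups for clustering recovery). For
the two count-scale scenarios the catalogs carry no plate metadata —
the statistics need only counts, and this keeps the full pipeline well
inside a minute.

Decisions that the stated world did not pin down, made once:

* **Enriched genes' baseline abundance** (`root_vs_nonroot`): spread so
  expected root counts span ~10–60, the count range real root-enriched
  tag tables print. With the 8-fold effect fixed, the weakest of these
  genes sit near the Bonferroni boundary, so recovery is expected around
  90–95%, not 100% — the acceptance bound (≥ 90%) reflects that.
* **Type-I simulation**: 2,000 equiprobable genes, $10^6$ tags per
  library (expected 500 per gene). Exact tests on coarse count lattices
  are conservative by construction; demanding the uncorrected positive
  rate land inside the 99% binomial CI of $\alpha$ is only meaningful
  where the count support is effectively continuous, which these sizes
  provide.

What a green synthetic test does **not** establish: real dbEST catalogs
have ragged orientation metadata, non-uniform plate occupancy,
batch-correlated annotation errors, and normalization chemistry whose
bias is not a clean power law. The generator emulates structure, not
those pathologies; detector thresholds here are validated for recall and
precision on the stereotyped error classes only.

## Numerical and degenerate-input notes

* Clone-name stems must end in a letter; batch numbers are 1–2 digits,
  plates Roman I–IV or Arabic 1–4, direction suffixes `5'end`/`3'end`
  or absent (absent participates in counting, never in pairing).
* Well-slot collisions resolve by confidence, then read id, always with a
  warning; serialized output always uses well labels, never indices.
* `library_size <= 0`, empty groups, `k > n` cuts, fewer than 3
  concordance pairs, and non-integer AC counts are hard errors.
* Library metadata is TSV (the environment provides no YAML parser for
  offline R).

## Limitations

* The curation judges identity purely on assigned gene ids, as the
  method demands; sequence-level confirmation is out of scope.
* Frequencies from normalized libraries are biased (abundant transcripts
  under-counted); the package flags such groups but deliberately applies
  no correction — enrichment calls *toward* the normalized library are
  conservative, calls away from it are not trustworthy and are left to
  the caller to discard.
* The chi-squared construction is the g-cell goodness-of-fit form, not a
  2×g contingency table; the difference vanishes when tag fractions are
  small (tested), but the two are not identical.
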