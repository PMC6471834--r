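---
title: "Detecting parallel and convergent amino-acid replacements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel and convergent amino-acid replacements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcon)
```

## The question

Repeated evolution of the same amino acid at the same protein site in
independent lineages — parallelism (same ancestral residue, same derived
residue) and convergence (different ancestral residues, same derived
residue) — is often read as a signature of adaptation. But identical
replacements also arise by chance, at a rate set by the substitution
process, the branch lengths, and the residue composition of the protein.
`parcon` identifies such events in reconstructed ancestral sequences,
computes how many would be expected under a neutral substitution model,
and asks whether the observed counts are surprising.

## The data unit: an ancestral record

All analyses consume an *ancestral-sequence record*: a rooted guide tree in
Newick with branch lengths (in expected replacements per site) and labeled
internal nodes, one relative replacement rate $r_i$ per alignment column,
and one sequence per tree node — the observed tips plus the reconstructed
ancestors. Ancestral reconstruction itself is out of scope: any ML
reconstruction program can produce the states, and a small adapter that
writes the tab-delimited record layout (tree line, blank, rate line, blank,
`name<TAB>sequence` rows) connects it to this package. Records are read
with `read_ancestral_record()` and validated on read: the sequence names
must match the tree's node names exactly, all sequences must share one
length, and all rates must be positive. Alignments are expected to be
trimmed beforehand (`trim_alignment()` keeps only columns made entirely of
the 20 canonical uppercase residues), so every record position is an
unambiguous site; positions in all outputs refer to the trimmed
coordinates, and the `kept` map returned by `trim_alignment()` translates
back to the original columns.

## Which branch pairs are comparable

An event needs two *independent* lineages. `comparable_pairs()` excludes
(i) sibling branches — they share their ancestral node, so a shared
replacement cannot be attributed to two independent origins — and (ii) any
pair in which one branch lies on the root-to-tip path of the other, which
violates the independence requirement outright. Multifurcations are
allowed (the sibling rule generalizes to "same parent"), the root may have
two or more children, and every edge below the root is an ordinary branch.
For a strictly bifurcating tree with $L$ leaves and $K$ cherries, the
number of comparable *terminal* pairs is $\binom{L}{2} - K$; the test
suite checks this identity and full agreement with a brute-force predicate
scan on hundreds of random trees.

## Identification

For a comparable pair with ancestral states $a_1, a_2$ and descendant
states $d_1, d_2$ at a site, an event is recorded iff $a_1 \ne d_1$,
$a_2 \ne d_2$ and $d_1 = d_2$: parallel when $a_1 = a_2$, convergent
otherwise. A site therefore yields at most one event per pair, and
$d_1 = a_2$ does not block an event — only the three literal conditions
apply. Counts are reported for *every* comparable pair, zeros included, so
the observed, expected and test tables always join on identical pair keys.

## The null model and expected counts

The null is an empirical reversible amino-acid substitution model:
exchangeabilities $S$ and frequencies $\pi$ read from a PAML-format
`.dat` file (JTT is bundled; any matrix in that format works, including
"selection-free" matrices built from pseudogene mutation patterns). The
generator is $Q_{ij} = S_{ij}\pi_j$, normalized so $-\sum_i \pi_i Q_{ii}
= 1$ — one expected replacement per site per unit branch length, matching
how ML programs scale guide trees. Transition probabilities
$P(d) = e^{Qd}$ are computed by symmetric eigendecomposition of
$\Pi^{1/2} Q \Pi^{-1/2}$, which is exact for reversible generators and
numerically stable; $P(0)$ is returned as the exact identity, entries are
clipped to $[0,1]$ after a $-10^{-12}$ negativity check, and the
factorization is cached per distance so repeated site-rate lookups are
cheap. The evolutionary distance for column $i$ on a branch of length $t$
is $d = r_i\,t$.

Two estimators of the expected event counts are provided:

* **Simulation** (`expected_counts_simulation()`): replicate sequence sets
  are evolved along the record's tree — root drawn i.i.d. from residue
  frequencies estimated from the record's trimmed tip alignment (floored
  at $10^{-6}$ so no state is absorbing), children sampled from
  $P(r_i t)$ — and events are identified on each replicate's *true*
  ancestors, which a simulator knows exactly; no re-reconstruction step is
  interposed. The expectation is the per-pair mean over replicates
  (default 100; a seed is mandatory). Using true ancestors is a deliberate
  choice: it measures the chance rate of parallel/convergent events under
  the null process itself, not the compound of process plus
  reconstruction error.

* **Analytic** (`expected_counts_analytic()`): conditions on the record's
  (point-estimate) ancestral states. For a pair with branch lengths
  $t_1, t_2$,
  $$\lambda_P = \sum_{i:\,a_1=a_2}\ \sum_{c \ne a_1}
      P_{a_1 c}(r_i t_1)\, P_{a_2 c}(r_i t_2), \qquad
    \lambda_C = \sum_{i:\,a_1\ne a_2}\ \sum_{c \notin \{a_1,a_2\}}
      P_{a_1 c}(r_i t_1)\, P_{a_2 c}(r_i t_2),$$
  assuming the two branches evolve independently given their ancestors.
  This is the only calculation computable from exactly the quantities a
  record holds (matrix, rates, lengths, ancestral states); integrating
  over ancestral-state uncertainty would need per-node posteriors that the
  record format does not carry, and is a known limitation.

By default the analytic path uses the model file's equilibrium
frequencies inside $Q$ (`pi_override` swaps in alignment-estimated ones),
while simulation draws its root states from the tip alignment's observed
frequencies — the composition the real protein actually has.

## The test

Under the null, the event count $k$ of a pair and category is treated as
Poisson with mean $\lambda$, the expected count. `poisson_tail_p()`
returns the lower tail $P(X \le k)$ when $k < \lambda$ and otherwise the
strict upper tail $P(X \ge k + 1)$ (the convention verified against the
published lysozyme c table: $k=1,\lambda=0.35$ gives $1 - e^{-0.35}(1.35)
= 0.0487$, which requires the strict form; equality $k = \lambda$ falls to
the upper tail). When $k = 0$ and $\lambda = 0$ no test is possible and
`NA` ("N/A" in files) is reported; $\lambda = 0$ with $k > 0$ returns 0,
as the event is impossible under the null. `detect()` emits one parallel
and one convergent test per pair and, by default, applies no
multiple-comparison correction — mirroring common practice of reporting
raw tail probabilities and leaving correction to the user's design —
with Bonferroni and Benjamini–Hochberg available as opt-in, applied
jointly across all non-NA p-values.

## The synthetic fixture generator

`make_fixture()` makes the whole pipeline testable offline: a Yule
(pure-birth) topology, i.i.d. exponential branch lengths with mean 0.1
replacements per site (typical of the moderately diverged protein trees
this analysis targets), Gamma(shape 2, rate 2) site rates — mean 1 with a
realistic spread of slow and fast columns — and sequences simulated under
the bundled JTT model with true ancestors retained. What it emulates is
the *null* data-generating process; what it does not emulate is
reconstruction error, alignment error, selection, indels, or among-branch
compositional drift. Passing tests on fixtures therefore demonstrates that
the machinery is correct under its own assumptions, not that those
assumptions hold for any particular real dataset.

## Numerical and design choices

* Internal nodes are auto-named `N1, N2, ...` in preorder with collision
  skipping, so trees and records stay mutually consistent.
* Missing branch lengths are tolerated (as `NA`) for identification,
  which never uses them, and are a hard error for either expectation.
* Poisson tails come from `ppois`, which computes via the regularized
  incomplete gamma function; the suite cross-checks a log-space series
  summation to $10^{-10}$ over $k \le 50$, $\lambda \le 20$.
* The record writer emits rates with 17 significant digits and branch
  lengths with 9, so write/read round trips are lossless at working
  precision.
* Problem sizes in the test suite (trees of 3–20 leaves, records of
  20–200 sites, 100 fixture records, $2\times10^5$ conditional
  Monte-Carlo draws, $2\times10^4$ simulation replicates on a two-state
  toy) were chosen so that every stochastic comparison has a 3-standard-
  error resolution well below the effect sizes being verified.

## Limitations

Reconstructed ancestors are treated as known; uncertainty in ancestral
states, in the tree, and in the alignment propagates into both observed
and expected counts without being quantified here. The Poisson assumption
ignores the (slight) negative correlation between events at a site across
overlapping pair sets. And an excess of parallel replacements over a
neutral expectation is evidence of non-neutrality at most — conservative
exchanges between biochemically similar residues inflate parallel counts
under any realistic replacement matrix, which is exactly why the choice
of null matrix is exposed as a parameter.
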