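# parcon

Identification and testing of **par**allel and **con**vergent amino-acid
replacements in protein phylogenies.

## The problem

When two independent lineages replace the same ancestral residue with the
same derived residue at the same alignment site (a *parallel* replacement),
or arrive at the same derived residue from different ancestral ones
(a *convergent* replacement), the repetition is often taken as evidence of
adaptation. Whether it actually is depends on how many such events pure
chance would produce: a neutral substitution process on a tree with long
branches and a skewed residue composition generates plenty of repeated
replacements on its own. `parcon` is for molecular evolutionists who have
reconstructed ancestral sequences for a protein family and want the
observed event counts, the chance expectations, and a test — without
stitching the steps together by hand.

Given an *ancestral record* (guide tree + per-site rates + sequences at
every node, the standard output of ML ancestral reconstruction), the
package:

1. enumerates every **comparable branch pair** — pairs that are neither
   siblings nor on one root-to-tip path, the only pairs that can evidence
   independent evolution;
2. **identifies events** per pair and site: with ancestral/descendant
   states `a1 -> d1` and `a2 -> d2`, an event requires `a1 != d1`,
   `a2 != d2`, `d1 == d2`; parallel iff `a1 == a2`, convergent otherwise;
3. computes **expected counts** under an empirical substitution model
   (JTT bundled, any PAML `.dat` accepted) with generator
   `Q_ij = S_ij * pi_j` normalized to mean rate 1 — either by simulating
   replicate datasets along the tree, or analytically, conditioning on the
   ancestral states:
   `lambda_P = sum_i [a1==a2] sum_{c != a1} P_{a1,c}(r_i t1) P_{a2,c}(r_i t2)`
   (and the analogous sum over `c` outside `{a1, a2}` for `lambda_C`);
4. **tests** each pair and category with a Poisson tail rule: lower tail
   `P(X <= k)` when the observed count `k` is below its expectation
   `lambda`, otherwise the strict upper tail `P(X >= k+1)`; `N/A` when
   both are zero.

## Worked example

The bundled generator builds a complete synthetic dataset (Yule tree, JTT
sequences, true ancestors), which the one-call analysis then processes:

```r
library(parcon)
fx  <- make_fixture(seed = 42, n_leaves = 8, length = 200, outdir = "demo")
fit <- parcon(fx$record, method = "analytic")
summary(fit)
```

```
Parallel/convergent replacement analysis
  model: jtt | expectation: analytic
  tree: 8 tips, 200 sites, 58 comparable branch pairs
  events: 35 parallel, 0 convergent
  significant at p <= 0.05: 12 parallel, 0 convergent tests

Smallest p-values:
  pair category observed expected      p sig
 t2-t4        P        2   0.1426 0.0004  **
 N7-t2        P        1   0.0579 0.0016  **
 N4-t8        P        2   0.2663 0.0026  **
 ...
```

Each row is one branch pair and category: `observed` is the identified
event count, `expected` the chance expectation under JTT given the tree
and ancestral states, and `p` the Poisson tail probability (uncorrected —
this data was generated under the null, so at `p <= 0.05` a batch of
2 × 58 tests is expected to flag a handful of pairs by chance, as it
does). `run_pipeline()` performs the same analysis from files to files
(counts, details, expectation and tests TSVs plus a JSON manifest), and
`inst/cli/parcon.R` exposes `identify`, `expect`, `detect`, `pipeline`
and `fixture` subcommands for shell use:

```sh
Rscript inst/cli/parcon.R pipeline -a record.tsv -m jtt.dat --method analytic -o out/
```

Lower-level pieces are exported individually: `parse_newick()` /
`comparable_pairs()`, `read_ancestral_record()`, `read_paml_dat()` /
`build_rate_matrix()` / `transition_matrix()`, `identify_events()`,
`expected_counts_simulation()` / `expected_counts_analytic()`,
`poisson_tail_p()` / `detect()`.

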