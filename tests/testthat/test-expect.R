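test_that("simulate_record copies the root over zero-length branches and is seed-reproducible", {
  q <- build_rate_matrix(read_paml_dat(jtt_model_path()))
  tr <- label_unnamed_internals(parse_newick("((A:0,B:0):0,C:0);"))
  rec <- simulate_record(tr, q, 1, length = 30, seed = 1)
  root <- rec$sequences[[node_names(tr)[5]]]
  expect_true(all(rec$sequences == rec$sequences[[1]]))
  expect_equal(nchar(root), 30L)

  tr2 <- rand_tree(5)
  r1 <- simulate_record(tr2, q, rep(1, 20), 20, seed = 7)
  r2 <- simulate_record(tr2, q, rep(1, 20), 20, seed = 7)
  r3 <- simulate_record(tr2, q, rep(1, 20), 20, seed = 8)
  expect_identical(r1$sequences, r2$sequences)
  expect_false(identical(r1$sequences, r3$sequences))

  trNA <- parse_newick("((A:1,B)X:1,C:1)R;")
  expect_error(simulate_record(trNA, q, 1, 5, seed = 1), "length")
  expect_error(simulate_record(tr2, q, rep(1, 3), 20, seed = 1), "site rates")
})

test_that("a long branch equilibrates to the stationary frequencies", {
  q <- build_rate_matrix(read_paml_dat(jtt_model_path()))
  tr <- parse_newick("(A:50,B:0)R;")
  L <- 20000L
  rec <- simulate_record(tr, q, 1, L, root_freqs = q$pi, seed = 99)
  obs <- table(factor(strsplit(rec$sequences[["A"]], "")[[1]],
                      levels = PAML_RESIDUES))
  for (a in PAML_RESIDUES) {
    se <- sqrt(q$pi[[a]] * (1 - q$pi[[a]]) / L)
    expect_lt(abs(obs[[a]] / L - q$pi[[a]]), 3 * se + 1e-9)
  }
})

test_that("analytic expectation matches the 2-letter closed form", {
  q <- build_rate_matrix(toy2_model())
  tr <- label_unnamed_internals(parse_newick("((A:0.5,B:0.5):0.5,C:0.5);"))
  nm <- node_names(tr)
  seqs <- setNames(rep("A", 5), nm)
  rec <- ancestral_record(tr, 1, seqs)
  e <- expected_counts_analytic(rec, q)
  # pairs {A,C} and {B,C}: a1 == a2 == "A", t1 = t2 = 0.5, r = 1
  lamP <- ((1 - exp(-1)) / 2)^2
  expect_equal(e$e_parallel, rep(lamP, 2), tolerance = 1e-9)
  expect_equal(e$e_convergent, c(0, 0))   # no third state exists

  # zero branch lengths give zero expectations
  tr0 <- label_unnamed_internals(parse_newick("((A:0,B:0):0,C:0);"))
  rec0 <- ancestral_record(tr0, 1, setNames(rep("A", 5), node_names(tr0)))
  e0 <- expected_counts_analytic(rec0, q)
  expect_true(all(e0$e_parallel == 0) && all(e0$e_convergent == 0))
})

test_that("analytic expectations are monotone in branch length (2-letter toy)", {
  q <- build_rate_matrix(toy2_model())
  grid <- seq(0, 1, by = 0.1)
  prevP <- -1
  for (t1 in grid) {
    tr <- label_unnamed_internals(
      parse_newick(sprintf("((A:%g,B:0.2):0.2,C:0.4);", t1)))
    rec <- ancestral_record(tr, 1, setNames(rep("A", 5), node_names(tr)))
    e <- expected_counts_analytic(rec, q)
    lam <- e$e_parallel[e$first == "A" & e$second == "C"]
    expect_gte(lam, prevP)
    prevP <- lam
  }
})

test_that("analytic expectation agrees with the conditional Monte-Carlo oracle", {
  q <- build_rate_matrix(read_paml_dat(jtt_model_path()))
  rec <- rand_record(seed = 77, n_leaves = 4, L = 6, mean_len = 0.6)
  e <- expected_counts_analytic(rec, q)
  set.seed(78)
  mc <- oracle_conditional_mc(rec, q, nrep = 2e5)
  for (k in seq_len(nrow(e))) {
    expect_lt(abs(e$e_parallel[k] - mc$mc_p[k]),
              3 * mc$se_p[k] + 1e-9)
    expect_lt(abs(e$e_convergent[k] - mc$mc_c[k]),
              3 * mc$se_c[k] + 1e-9)
  }
})

test_that("simulation expectation converges to exact enumeration on a tiny toy", {
  q <- build_rate_matrix(toy2_model())
  tr <- label_unnamed_internals(parse_newick("((A:0.4,B:0.3):0.2,C:0.5);"))
  nm <- node_names(tr)
  rec <- ancestral_record(tr, 1, setNames(rep("A", 5), nm))
  # root draw in the simulation uses tip-estimated frequencies (all "A",
  # floored); the enumeration oracle must condition on the same draw
  tips <- rec$sequences[tr$tip.label]
  root_freqs <- estimate_frequencies(tips, q$alphabet)
  exact <- oracle_enumerate(tr, q, root_freqs)
  nrep <- 20000L
  sim <- expected_counts_simulation(rec, q, n_replicates = nrep, seed = 123)
  expect_identical(paste(sim$first, sim$second),
                   paste(exact$first, exact$second))
  for (k in seq_len(nrow(sim))) {
    # Poisson-like count per replicate; bound the SE by sqrt(mean/n) + slack
    se_p <- sqrt(max(exact$e_parallel[k], 1e-6) / nrep)
    se_c <- sqrt(max(exact$e_convergent[k], 1e-6) / nrep)
    expect_lt(abs(sim$e_parallel[k] - exact$e_parallel[k]), 3 * se_p)
    expect_lt(abs(sim$e_convergent[k] - exact$e_convergent[k]), 3 * se_c)
  }
})

test_that("simulation expectation is deterministic per seed and keyed like the counts", {
  q <- build_rate_matrix(read_paml_dat(jtt_model_path()))
  rec <- rand_record(seed = 55, n_leaves = 5, L = 15)
  e1 <- expected_counts_simulation(rec, q, n_replicates = 10, seed = 42)
  e2 <- expected_counts_simulation(rec, q, n_replicates = 10, seed = 42)
  expect_equal(e1, e2)
  obs <- identify_events(rec)$counts
  expect_identical(paste(e1$first, e1$second), paste(obs$first, obs$second))
  expect_true(all(e1$e_parallel >= 0) && all(e1$e_convergent >= 0))
  ea <- expected_counts_analytic(rec, q)
  expect_identical(paste(ea$first, ea$second), paste(obs$first, obs$second))
})
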