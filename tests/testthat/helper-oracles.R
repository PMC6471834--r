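# Independent oracles and random generators used across the suite.
# These deliberately re-derive results from first principles (brute force,
# literal definitions, exact enumeration) rather than calling the code paths
# they check.

# local copy so the helpers do not rely on unexported package internals
node_names <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl[is.na(nl)] <- ""
  c(tree$tip.label, nl)
}

# random labeled bifurcating tree with exponential branch lengths
rand_tree <- function(n_leaves, mean_len = 0.1) {
  tr <- ape::rtree(n_leaves, br = function(n) rexp(n, rate = 1 / mean_len))
  tr$node.label <- NULL
  label_unnamed_internals(tr)
}

# names of the nodes on the path root -> v (inclusive), by climbing
root_path <- function(tree, v) {
  nm <- node_names(tree)
  pm <- rep(NA_integer_, length(nm))
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  vn <- match(v, nm)
  path <- vn
  while (!is.na(pm[path[1]])) path <- c(pm[path[1]], path)
  nm[path]
}

# brute-force comparable pairs: double loop over all branch pairs applying
# the literal exclusion predicates via root paths
oracle_pairs <- function(tree) {
  nm <- node_names(tree)
  pm <- rep(NA_integer_, length(nm))
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  nonroot <- nm[tree$edge[, 2]]
  paths <- lapply(nonroot, function(v) root_path(tree, v))
  names(paths) <- nonroot
  res <- character(0)
  for (u in nonroot) for (v in nonroot) {
    if (u >= v) next
    sib <- identical(nm[pm[match(u, nm)]], nm[pm[match(v, nm)]])
    shared <- (u %in% paths[[v]]) || (v %in% paths[[u]])
    if (!sib && !shared) res <- c(res, paste(u, v, sep = "\r"))
  }
  sort(res)
}

pairs_as_keys <- function(pairs) sort(paste(pairs$first, pairs$second,
                                            sep = "\r"))

n_cherries <- function(tree) {
  ntip <- length(tree$tip.label)
  tip_parents <- tree$edge[tree$edge[, 2] <= ntip, 1]
  sum(table(tip_parents) == 2L)
}

# literal per-pair-per-site rescan of the identification definition
oracle_identify <- function(record) {
  tree <- record$tree
  nm <- node_names(tree)
  pm <- rep(NA_integer_, length(nm))
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  pairs <- comparable_pairs(tree)
  seqs <- lapply(record$sequences, function(s) strsplit(s, "")[[1]])
  L <- length(record$site_rates)
  out <- data.frame(first = pairs$first, second = pairs$second,
                    parallel = 0L, convergent = 0L)
  for (k in seq_len(nrow(pairs))) {
    b1 <- pairs$first[k]; b2 <- pairs$second[k]
    p1 <- nm[pm[match(b1, nm)]]; p2 <- nm[pm[match(b2, nm)]]
    for (i in seq_len(L)) {
      a1 <- seqs[[p1]][i]; d1 <- seqs[[b1]][i]
      a2 <- seqs[[p2]][i]; d2 <- seqs[[b2]][i]
      if (a1 != d1 && a2 != d2 && d1 == d2) {
        if (a1 == a2) out$parallel[k] <- out$parallel[k] + 1L
        else out$convergent[k] <- out$convergent[k] + 1L
      }
    }
  }
  out
}

# exact per-site expectation by enumerating every joint state assignment of
# all tree nodes (tractable for tiny alphabets/trees); one shared site rate
oracle_enumerate <- function(tree, q, root_freqs, rate = 1) {
  nm <- node_names(tree)
  n <- length(q$alphabet)
  pm <- rep(NA_integer_, length(nm))
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, length(nm))
  elen[tree$edge[, 2]] <- tree$edge.length
  P <- lapply(seq_along(nm), function(v)
    if (is.na(pm[v])) NULL else transition_matrix(q, rate * elen[v]))
  pairs <- comparable_pairs(tree)
  nn <- length(nm)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), nn)))
  rt <- which(is.na(pm))
  e_p <- numeric(nrow(pairs)); e_c <- numeric(nrow(pairs))
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- root_freqs[st[rt]]
    for (v in seq_len(nn)) if (!is.na(pm[v]))
      pr <- pr * P[[v]][st[pm[v]], st[v]]
    if (pr == 0) next
    for (k in seq_len(nrow(pairs))) {
      b1 <- match(pairs$first[k], nm); b2 <- match(pairs$second[k], nm)
      a1 <- st[pm[b1]]; d1 <- st[b1]; a2 <- st[pm[b2]]; d2 <- st[b2]
      if (a1 != d1 && a2 != d2 && d1 == d2) {
        if (a1 == a2) e_p[k] <- e_p[k] + pr else e_c[k] <- e_c[k] + pr
      }
    }
  }
  data.frame(first = pairs$first, second = pairs$second,
             e_parallel = e_p, e_convergent = e_c)
}

# conditional Monte-Carlo oracle for the analytic expectation: holds the
# record's ancestral states fixed and resamples only the two descendant
# states; returns estimate and standard error per pair/category
oracle_conditional_mc <- function(record, q, nrep = 2e5) {
  tree <- record$tree
  nm <- node_names(tree)
  pm <- rep(NA_integer_, length(nm))
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, length(nm))
  elen[tree$edge[, 2]] <- tree$edge.length
  seqs <- lapply(record$sequences, function(s)
    match(strsplit(s, "")[[1]], q$alphabet))
  L <- length(record$site_rates)
  pairs <- comparable_pairs(tree)
  n <- length(q$alphabet)
  res <- data.frame(first = pairs$first, second = pairs$second,
                    mc_p = NA_real_, se_p = NA_real_,
                    mc_c = NA_real_, se_c = NA_real_)
  for (k in seq_len(nrow(pairs))) {
    b1 <- match(pairs$first[k], nm); b2 <- match(pairs$second[k], nm)
    tot_p <- numeric(nrep); tot_c <- numeric(nrep)
    for (i in seq_len(L)) {
      a1 <- seqs[[nm[pm[b1]]]][i]; a2 <- seqs[[nm[pm[b2]]]][i]
      P1 <- transition_matrix(q, record$site_rates[i] * elen[b1])
      P2 <- transition_matrix(q, record$site_rates[i] * elen[b2])
      d1 <- sample.int(n, nrep, replace = TRUE, prob = P1[a1, ])
      d2 <- sample.int(n, nrep, replace = TRUE, prob = P2[a2, ])
      hit <- d1 != a1 & d2 != a2 & d1 == d2
      if (a1 == a2) tot_p <- tot_p + hit else tot_c <- tot_c + hit
    }
    # SE floored at 1/nrep: with zero hits the empirical sd is 0, but the
    # rule of three still only bounds the true rate by ~3/nrep
    res$mc_p[k] <- mean(tot_p)
    res$se_p[k] <- max(sd(tot_p) / sqrt(nrep), 1 / nrep)
    res$mc_c[k] <- mean(tot_c)
    res$se_c[k] <- max(sd(tot_c) / sqrt(nrep), 1 / nrep)
  }
  res
}

# two-state symmetric toy model on alphabet {A, R}
toy2_model <- function(pi = c(0.5, 0.5)) {
  empirical_model(matrix(c(0, 1, 1, 0), 2), pi, alphabet = c("A", "R"),
                  name = "toy2")
}

# random protein alignment as a named character vector
rand_alignment <- function(n_seq, L, alphabet = PAML_RESIDUES) {
  setNames(replicate(n_seq, paste(sample(alphabet, L, replace = TRUE),
                                  collapse = "")),
           paste0("s", seq_len(n_seq)))
}

# small random ancestral record over the full 20-letter alphabet
rand_record <- function(seed, n_leaves = 4, L = 5, mean_len = 0.1) {
  q <- build_rate_matrix(read_paml_dat(jtt_model_path()))
  set.seed(seed)
  tr <- rand_tree(n_leaves, mean_len = mean_len)
  simulate_record(tr, q, rep(1, L), L, seed = seed + 1000L)
}
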