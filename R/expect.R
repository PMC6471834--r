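# transition-matrix cache keyed by exact distance, shared across calls
tm_cache <- function(q) {
  env <- new.env(parent = emptyenv())
  function(d) {
    key <- sprintf("%.17g", d)
    P <- env[[key]]
    if (is.null(P)) {
      P <- transition_matrix(q, d)
      env[[key]] <- P
    }
    P
  }
}

# core simulator: integer state matrix (nodes x sites) without seeding
simulate_states <- function(tree, q, rates, L, root_freqs, getP) {
  n <- length(q$alphabet)
  nm <- node_names(tree)
  br_len <- rep(NA_real_, length(nm))
  if (!is.null(tree$edge.length)) br_len[tree$edge[, 2]] <- tree$edge.length
  if (anyNA(br_len[tree$edge[, 2]]))
    stop("simulation requires a length on every branch")
  states <- matrix(NA_integer_, nrow = length(nm), ncol = L)
  rt <- root_node(tree)
  states[rt, ] <- sample.int(n, L, replace = TRUE, prob = root_freqs)
  cl <- ape::reorder.phylo(tree, "cladewise")
  # map reordered edges back to node numbers (reorder keeps numbering)
  for (e in seq_len(nrow(cl$edge))) {
    par <- cl$edge[e, 1]; chd <- cl$edge[e, 2]
    t_ <- br_len[chd]
    if (t_ == 0) {
      states[chd, ] <- states[par, ]
      next
    }
    ps <- states[par, ]
    cs <- integer(L)
    for (i in seq_len(L)) {
      P <- getP(rates[i] * t_)
      cs[i] <- sample.int(n, 1L, prob = P[ps[i], ])
    }
    states[chd, ] <- cs
  }
  rownames(states) <- nm
  states
}

states_to_seqs <- function(states, alphabet) {
  apply(states, 1L, function(s) paste(alphabet[s], collapse = ""))
}

#' Simulate an ancestral record along a tree
#'
#' Evolves sequences under a continuous-time Markov substitution model: the
#' root sequence is drawn i.i.d. from \code{root_freqs}; each child state is
#' then sampled from the parent's row of \code{P(r_i * t)} where \code{r_i}
#' is the site rate and \code{t} the branch length. All internal (true
#' ancestral) sequences are retained. Bit-reproducible for a fixed seed.
#'
#' @param tree a \code{phylo} with named nodes and branch lengths.
#' @param q a \code{rate_matrix}.
#' @param site_rates positive rates, one per site (or a single shared value).
#' @param length number of sites.
#' @param root_freqs frequency vector for the root draw (default the
#'   model's equilibrium frequencies).
#' @param seed integer seed.
#' @return an \code{ancestral_record}.
#' @export
simulate_record <- function(tree, q, site_rates, length,
                            root_freqs = q$pi, seed) {
  L <- length
  if (base::length(site_rates) == 1L) site_rates <- rep(site_rates, L)
  if (base::length(site_rates) != L)
    stop("got ", base::length(site_rates), " site rates for ", L, " sites")
  if (any(site_rates <= 0)) stop("site rates must be positive")
  set.seed(seed)
  getP <- tm_cache(q)
  states <- simulate_states(tree, q, site_rates, L, root_freqs, getP)
  ancestral_record(tree, site_rates, states_to_seqs(states, q$alphabet))
}

new_expectation <- function(pairs, e_p, e_c, method, n_replicates = NA_integer_,
                            seed = NA_integer_) {
  structure(data.frame(first = pairs$first, second = pairs$second,
                       e_parallel = e_p, e_convergent = e_c,
                       stringsAsFactors = FALSE),
            method = method, n_replicates = n_replicates, seed = seed,
            class = c("pc_expectation", "data.frame"))
}

#' Expected replacement counts by simulation
#'
#' Simulates replicate records with the observed record's tree, branch
#' lengths and site rates, a sequence length equal to the record's, and
#' root frequencies estimated from the record's trimmed tip alignment;
#' identifies parallel/convergent events on each replicate's true
#' ancestors; returns per-pair mean counts.
#'
#' @param record an \code{ancestral_record}.
#' @param q a \code{rate_matrix}.
#' @param n_replicates number of replicates (>= 1).
#' @param seed integer seed.
#' @return a \code{pc_expectation} data frame (columns \code{first},
#'   \code{second}, \code{e_parallel}, \code{e_convergent}) with
#'   attributes \code{method}, \code{n_replicates}, \code{seed}.
#' @export
expected_counts_simulation <- function(record, q, n_replicates = 100L,
                                       seed) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  tree <- record$tree
  L <- length(record$site_rates)
  tips <- record$sequences[tree$tip.label]
  trimmed <- trim_alignment(tips, q$alphabet)$alignment
  root_freqs <- if (nchar(trimmed[[1]]) > 0L)
    estimate_frequencies(trimmed, q$alphabet) else q$pi
  set.seed(seed)
  getP <- tm_cache(q)
  pairs <- comparable_pairs(tree)
  acc_p <- numeric(nrow(pairs))
  acc_c <- numeric(nrow(pairs))
  for (r in seq_len(n_replicates)) {
    states <- simulate_states(tree, q, record$site_rates, L, root_freqs,
                              getP)
    rec <- ancestral_record(tree, record$site_rates,
                            states_to_seqs(states, q$alphabet))
    cnt <- identify_events(rec)$counts
    acc_p <- acc_p + cnt$parallel
    acc_c <- acc_c + cnt$convergent
  }
  new_expectation(pairs, acc_p / n_replicates, acc_c / n_replicates,
                  "simulation", as.integer(n_replicates), as.integer(seed))
}

#' Expected replacement counts by analytic calculation
#'
#' Conditions on the record's (point-estimate) ancestral states: for each
#' comparable pair and site, with ancestral residues a1, a2 above the two
#' branches and distances d = r_i * t,
#' \deqn{\lambda_P = \sum_i [a1 = a2] \sum_{c \ne a1} P_{a1,c}(r_i t_1)
#'   P_{a2,c}(r_i t_2)}
#' \deqn{\lambda_C = \sum_i [a1 \ne a2] \sum_{c \notin \{a1,a2\}}
#'   P_{a1,c}(r_i t_1) P_{a2,c}(r_i t_2)}
#' assuming the two branches evolve independently given their ancestors.
#'
#' @param record an \code{ancestral_record} with branch lengths.
#' @param q a \code{rate_matrix}.
#' @return a \code{pc_expectation} data frame.
#' @export
expected_counts_analytic <- function(record, q) {
  tree <- record$tree
  br <- branches(tree)
  if (anyNA(br$length))
    stop("analytic expectation requires a length on every branch")
  rates <- record$site_rates
  L <- length(rates)
  m <- aln_matrix(record$sequences)
  state_idx <- matrix(match(m, q$alphabet), nrow = nrow(m),
                      dimnames = dimnames(m))
  if (anyNA(state_idx))
    stop("record contains residues outside the model alphabet")
  getP <- tm_cache(q)
  t_of <- setNames(br$length, br$child)
  anc_of <- setNames(br$parent, br$child)
  pairs <- comparable_pairs(tree)
  e_p <- numeric(nrow(pairs))
  e_c <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    b1 <- pairs$first[k]; b2 <- pairs$second[k]
    t1 <- t_of[[b1]]; t2 <- t_of[[b2]]
    a1 <- state_idx[anc_of[[b1]], ]
    a2 <- state_idx[anc_of[[b2]], ]
    lp <- 0; lc <- 0
    for (i in seq_len(L)) {
      P1 <- getP(rates[i] * t1)
      P2 <- getP(rates[i] * t2)
      r1 <- P1[a1[i], ]; r2 <- P2[a2[i], ]
      dot <- sum(r1 * r2)
      if (a1[i] == a2[i]) {
        lp <- lp + dot - r1[a1[i]] * r2[a1[i]]
      } else {
        lc <- lc + dot - r1[a1[i]] * r2[a1[i]] - r1[a2[i]] * r2[a2[i]]
      }
    }
    e_p[k] <- lp
    e_c[k] <- lc
  }
  new_expectation(pairs, e_p, e_c, "analytic")
}

#' Write an expectation table to TSV
#'
#' Columns: \code{pair}, \code{e_parallel}, \code{e_convergent},
#' \code{method}, \code{n_replicates}, \code{seed}.
#'
#' @param expectation a \code{pc_expectation}.
#' @param path output path.
#' @export
write_expectation_tsv <- function(expectation, path) {
  out <- data.frame(pair = pair_key(expectation$first, expectation$second),
                    e_parallel = sprintf("%.6f", expectation$e_parallel),
                    e_convergent = sprintf("%.6f", expectation$e_convergent),
                    method = attr(expectation, "method"),
                    n_replicates = attr(expectation, "n_replicates"),
                    seed = attr(expectation, "seed"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
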