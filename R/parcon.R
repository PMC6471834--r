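#' Parallel/convergent replacement analysis of an ancestral record
#'
#' The end-to-end analysis: identifies observed parallel and convergent
#' amino-acid replacements for every comparable branch pair of the record's
#' guide tree, computes the expected counts under the given substitution
#' model (by simulation along the tree or by the analytic calculation
#' conditioning on the record's ancestral states), and tests observed
#' against expected counts with the Poisson tail rule.
#'
#' @param record an \code{ancestral_record}, or a path to a record file.
#' @param model an \code{empirical_model}, or a path to a PAML '.dat' file
#'   (default the bundled JTT model).
#' @param method \code{"analytic"} or \code{"simulation"}.
#' @param n_replicates simulation replicates (simulation method only).
#' @param seed integer seed (required for the simulation method).
#' @param correction multiple-comparison correction passed to
#'   \code{\link{detect}}.
#' @param pi_override optional frequencies replacing the model's
#'   equilibrium frequencies in the rate matrix.
#' @return an object of class \code{parcon}: a list with elements
#'   \code{counts}, \code{events}, \code{expectation}, \code{tests},
#'   \code{record}, \code{model_name}, \code{method}.
#' @examples
#' fx <- make_fixture(seed = 1, n_leaves = 6, length = 60,
#'                    outdir = tempdir())
#' fit <- parcon(fx$record, method = "analytic")
#' summary(fit)
#' @export
parcon <- function(record, model = jtt_model_path(),
                   method = c("analytic", "simulation"),
                   n_replicates = 100L, seed = NULL,
                   correction = "none", pi_override = NULL) {
  method <- match.arg(method)
  cl <- match.call()
  if (is.character(record)) record <- read_ancestral_record(record)
  if (!inherits(record, "ancestral_record"))
    stop("record must be an ancestral_record or a file path")
  if (is.character(model)) model <- read_paml_dat(model)
  if (!inherits(model, "empirical_model"))
    stop("model must be an empirical_model or a '.dat' file path")
  q <- build_rate_matrix(model, pi_override = pi_override)
  obs <- identify_events(record)
  expectation <- switch(method,
    analytic = expected_counts_analytic(record, q),
    simulation = {
      if (is.null(seed))
        stop("the simulation method requires a seed for reproducibility")
      expected_counts_simulation(record, q, n_replicates = n_replicates,
                                 seed = seed)
    })
  tests <- detect(obs$counts, expectation, correction = correction)
  structure(list(counts = obs$counts, events = obs$events,
                 expectation = expectation, tests = tests,
                 record = record, model_name = model$name,
                 method = method, call = cl),
            class = "parcon")
}

#' @export
print.parcon <- function(x, ...) {
  cat("Parallel/convergent replacement analysis\n")
  cat("  model:", x$model_name, "| expectation:", x$method, "\n")
  cat("  tree:", length(x$record$tree$tip.label), "tips,",
      length(x$record$site_rates), "sites,",
      nrow(x$counts), "comparable branch pairs\n")
  cat("  events:", sum(x$counts$parallel), "parallel,",
      sum(x$counts$convergent), "convergent\n")
  invisible(x)
}

#' @export
summary.parcon <- function(object, ...) {
  t <- object$tests
  sig <- !is.na(t$p) & t$p <= 0.05
  print(object)
  cat("  significant at p <= 0.05:",
      sum(sig & t$category == "P"), "parallel,",
      sum(sig & t$category == "C"), "convergent tests\n")
  show <- t[order(ifelse(is.na(t$p), Inf, t$p)), ]
  show <- utils::head(show, 10L)
  cat("\nSmallest p-values:\n")
  print(data.frame(pair = pair_key(show$first, show$second),
                   category = show$category, observed = show$observed,
                   expected = round(show$expected, 4),
                   p = ifelse(is.na(show$p), NA, round(show$p, 4)),
                   sig = show$significance), row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.parcon <- function(x, ...) as.data.frame(x$tests)

#' Run the full pipeline on files and write all outputs
#'
#' Chains identification, expectation and testing on an ancestral-record
#' file, writing the counts, details, expectation and tests TSVs plus a
#' machine-readable manifest to \code{outdir}. Re-running with an identical
#' configuration reproduces byte-identical files.
#'
#' @param ancestors path to an ancestral-record file.
#' @param model path to a PAML '.dat' model file (default bundled JTT).
#' @param method \code{"analytic"} or \code{"simulation"}.
#' @param n_replicates simulation replicates.
#' @param seed integer seed (simulation method).
#' @param outdir output directory (created if needed).
#' @param correction multiple-comparison correction.
#' @return invisibly, a named list of output paths (the manifest).
#' @export
run_pipeline <- function(ancestors, model = jtt_model_path(),
                         method = c("analytic", "simulation"),
                         n_replicates = 100L, seed = NULL,
                         outdir = ".", correction = "none") {
  method <- match.arg(method)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[parcon] %s done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  fit <- stage("identify+expect+test",
               parcon(ancestors, model = model, method = method,
                      n_replicates = n_replicates, seed = seed,
                      correction = correction))
  paths <- list(counts = file.path(outdir, "counts.tsv"),
                details = file.path(outdir, "details.tsv"),
                expectation = file.path(outdir, "expectation.tsv"),
                tests = file.path(outdir, "tests.tsv"),
                manifest = file.path(outdir, "manifest.json"))
  write_counts_tsv(fit$counts, paths$counts)
  write_details_tsv(fit$events, paths$details)
  write_expectation_tsv(fit$expectation, paths$expectation)
  write_tests_tsv(fit$tests, paths$tests)
  hashes <- as.list(tools::md5sum(unlist(paths[1:4])))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    package = "parcon",
    version = as.character(utils::packageVersion("parcon")),
    inputs = list(ancestors = ancestors,
                  model = if (is.character(model)) model else "in-memory"),
    method = method,
    n_replicates = if (method == "simulation") n_replicates else NULL,
    seed = seed, correction = correction,
    outputs = lapply(paths[1:4], normalizePath),
    md5 = hashes)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             paths$manifest)
  invisible(paths)
}

#' Generate a synthetic test fixture
#'
#' Draws a random rooted bifurcating tree (Yule process) with independent
#' exponential branch lengths (mean 0.1 replacements per site) and
#' Gamma-distributed site rates (shape 2, rate 2, mean 1), simulates an
#' ancestral record under the model with true ancestors retained, and
#' writes the record, the tip FASTA and the Newick tree. Deterministic per
#' seed.
#'
#' @param seed integer seed.
#' @param n_leaves number of tips (>= 3).
#' @param length number of sites (>= 1).
#' @param model path to a PAML '.dat' model file (default bundled JTT).
#' @param birth Yule birth rate.
#' @param outdir output directory.
#' @return a named list of paths: \code{record}, \code{fasta}, \code{tree}.
#' @export
make_fixture <- function(seed, n_leaves = 8L, length = 200L,
                         model = jtt_model_path(), birth = 1,
                         outdir = tempfile("fixture")) {
  if (n_leaves < 3L) stop("n_leaves must be >= 3")
  if (length < 1L) stop("length must be >= 1")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mod <- if (is.character(model)) read_paml_dat(model) else model
  q <- build_rate_matrix(mod)
  set.seed(seed)
  tree <- ape::rphylo(n_leaves, birth = birth, death = 0)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
  tree$node.label <- NULL
  tree <- label_unnamed_internals(tree)
  rates <- stats::rgamma(length, shape = 2, rate = 2)
  rec_seed <- sample.int(.Machine$integer.max, 1L)
  rec <- simulate_record(tree, q, rates, length, root_freqs = q$pi,
                         seed = rec_seed)
  paths <- list(record = file.path(outdir, "record.tsv"),
                fasta = file.path(outdir, "tips.fasta"),
                tree = file.path(outdir, "tree.nwk"))
  write_ancestral_record(rec, paths$record)
  write_fasta(rec$sequences[tree$tip.label], paths$fasta)
  writeLines(write_newick(tree), paths$tree)
  paths
}
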