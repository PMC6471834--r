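#' Construct an empirical substitution model
#'
#' An empirical reversible amino-acid model is parameterised by a symmetric
#' exchangeability matrix S (zero diagonal) and equilibrium frequencies pi.
#'
#' @param S symmetric non-negative matrix with zero diagonal.
#' @param pi positive frequency vector summing to 1 (within 1e-4; it is
#'   renormalized exactly).
#' @param alphabet residue labels, one per state (default PAML order).
#' @param name model name.
#' @return an object of class \code{empirical_model}.
#' @export
empirical_model <- function(S, pi, alphabet = PAML_RESIDUES,
                            name = "custom") {
  S <- as.matrix(S)
  n <- nrow(S)
  if (ncol(S) != n || n < 2L) stop("S must be square, n >= 2")
  if (length(pi) != n) stop("pi must have one entry per state")
  if (length(alphabet) != n) stop("alphabet must have one label per state")
  if (any(S < 0)) stop("negative exchangeability")
  if (max(abs(S - t(S))) > 1e-9) stop("S is not symmetric")
  if (any(diag(S) != 0)) stop("S must have a zero diagonal")
  if (any(pi <= 0)) stop("frequencies must be positive")
  if (abs(sum(pi) - 1) > 1e-4)
    stop("frequencies sum to ", format(sum(pi)), ", not 1")
  pi <- pi / sum(pi)
  dimnames(S) <- list(alphabet, alphabet)
  structure(list(name = name, S = S, pi = setNames(pi, alphabet),
                 alphabet = alphabet),
            class = "empirical_model")
}

#' Read a PAML-format substitution model file
#'
#' The '.dat' dialect: the strict lower triangle of the exchangeability
#' matrix (row-wise, whitespace separated), then the equilibrium
#' frequencies; any trailing commentary is ignored. State count n is
#' inferred from the leading numeric token count (n(n+1)/2); files with a
#' 20-state prefix followed by further numbers are read as n = 20.
#'
#' @param path path to a .dat file.
#' @param name model name (default the file name without extension).
#' @return an \code{empirical_model}.
#' @export
read_paml_dat <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tokens <- scan(path, what = "", quiet = TRUE)
  vals <- suppressWarnings(as.numeric(tokens))
  stop_at <- which(is.na(vals))
  nv <- if (length(stop_at)) stop_at[1] - 1L else length(vals)
  if (nv < 3L) stop("too few numeric entries in ", path)
  vals <- vals[seq_len(nv)]
  # n(n-1)/2 triangle entries + n frequencies = n(n+1)/2 tokens
  n <- (sqrt(8 * nv + 1) - 1) / 2
  if (abs(n - round(n)) > 1e-9) {
    if (nv >= 210L) {
      n <- 20L
      vals <- vals[1:210]
    } else {
      stop("cannot infer state count from ", nv, " numeric entries in ", path)
    }
  }
  n <- as.integer(round(n))
  if (any(vals < 0)) stop("negative value in ", path)
  tri <- vals[seq_len(n * (n - 1L) / 2L)]
  freq <- vals[n * (n - 1L) / 2L + seq_len(n)]
  S <- matrix(0, n, n)
  k <- 1L
  for (i in 2:n) for (j in 1:(i - 1L)) {
    S[i, j] <- tri[k]
    S[j, i] <- tri[k]
    k <- k + 1L
  }
  if (abs(sum(freq) - 1) > 1e-4)
    stop("frequencies in ", path, " sum to ", format(sum(freq)), ", not 1")
  alphabet <- if (n == 20L) PAML_RESIDUES else
    c(PAML_RESIDUES, LETTERS)[seq_len(n)]
  empirical_model(S, freq, alphabet = alphabet, name = name)
}

#' Path to the bundled JTT model file
#'
#' The Jones-Taylor-Thornton (1992) empirical amino-acid model in PAML
#' '.dat' format, bundled as the default model.
#'
#' @return a file path.
#' @export
jtt_model_path <- function() {
  system.file("extdata", "jtt.dat", package = "parcon", mustWork = TRUE)
}

#' Build a normalized rate matrix from an empirical model
#'
#' Q_ij = S_ij * pi_j for i != j, diagonal set so rows sum to zero, then
#' the whole generator divided by mu = -sum_i pi_i Q_ii so the mean rate is
#' one and branch lengths read as expected replacements per site. A
#' reversible symmetric eigendecomposition is precomputed for fast
#' transition probabilities.
#'
#' @param model an \code{empirical_model}.
#' @param pi_override optional frequency vector replacing the model's
#'   equilibrium frequencies (positive, sums to 1).
#' @return an object of class \code{rate_matrix} with elements \code{Q},
#'   \code{pi}, \code{alphabet}.
#' @export
build_rate_matrix <- function(model, pi_override = NULL) {
  pi <- if (is.null(pi_override)) model$pi else {
    if (length(pi_override) != length(model$pi))
      stop("pi_override has wrong length")
    if (any(pi_override <= 0)) stop("pi_override must be positive")
    if (abs(sum(pi_override) - 1) > 1e-4) stop("pi_override must sum to 1")
    setNames(pi_override / sum(pi_override), model$alphabet)
  }
  n <- length(pi)
  Q <- model$S * rep(pi, each = n)   # Q_ij = S_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate model: zero mean rate")
  Q <- Q / mu
  # Pi^{1/2} Q Pi^{-1/2} is symmetric for a reversible Q
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(Q = Q, pi = pi, alphabet = model$alphabet,
                 values = eig$values,
                 left = eig$vectors / sp,        # Pi^{-1/2} V
                 right = t(eig$vectors * sp)),   # V' Pi^{1/2}
            class = "rate_matrix")
}

#' Transition probability matrix P(d) = exp(Q d)
#'
#' Computed from the precomputed reversible eigendecomposition; rows sum to
#' one and entries are clipped to [0, 1] after a -1e-12 negativity check.
#'
#' @param q a \code{rate_matrix}.
#' @param d non-negative evolutionary distance (replacements per site).
#' @return an n x n stochastic matrix.
#' @export
transition_matrix <- function(q, d) {
  if (!is.finite(d) || d < 0) stop("distance d must be >= 0")
  n <- length(q$alphabet)
  if (d == 0)
    return(matrix(diag(n), n, n, dimnames = list(q$alphabet, q$alphabet)))
  P <- q$left %*% (exp(q$values * d) * q$right)
  if (min(P) < -1e-12)
    stop("numerical failure: transition probability ", format(min(P)))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(q$alphabet, q$alphabet)
  P
}

#' Estimate residue frequencies from a trimmed alignment
#'
#' Observed residue proportions over the alphabet; zero entries are floored
#' at 1e-6 and the vector renormalized, so no state is absorbing when the
#' frequencies seed a simulation.
#'
#' @param aln named character vector of trimmed, equal-length sequences.
#' @param alphabet residue labels.
#' @return a named frequency vector summing to 1.
#' @export
estimate_frequencies <- function(aln, alphabet = PAML_RESIDUES) {
  if (!length(aln) || all(nchar(aln) == 0L)) stop("empty alignment")
  chars <- unlist(strsplit(aln, ""), use.names = FALSE)
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad))
    stop("residues outside alphabet (trim the alignment first): ",
         paste(bad, collapse = ", "))
  counts <- table(factor(chars, levels = alphabet))
  f <- as.numeric(counts) / length(chars)
  f[f == 0] <- 1e-6
  setNames(f / sum(f), alphabet)
}
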