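#' Poisson tail probability for an observed count
#'
#' The detection rule applied to each branch pair and category: with
#' observed count k and expected count lambda, the lower tail
#' P(X <= k) is returned when k < lambda, otherwise the (strict) upper
#' tail P(X >= k + 1). When both k and lambda are zero no test is
#' possible and NA is returned; lambda = 0 with k > 0 returns 0 (the
#' event is impossible under the null).
#'
#' @param observed non-negative integer count(s) k.
#' @param expected non-negative expected count(s) lambda.
#' @return p-value(s) in [0, 1], NA where observed and expected are both 0.
#' @examples
#' poisson_tail_p(0, 0.43)  # lower tail, exp(-0.43)
#' poisson_tail_p(1, 0.35)  # upper tail, 1 - exp(-0.35) * 1.35
#' @export
poisson_tail_p <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0))
    stop("observed and expected counts must be >= 0")
  n <- max(length(observed), length(expected))
  k <- rep_len(observed, n)
  lam <- rep_len(expected, n)
  p <- numeric(n)
  na <- lam == 0 & k == 0
  zero <- lam == 0 & k > 0
  lower <- !na & !zero & k < lam
  upper <- !na & !zero & !lower
  p[na] <- NA_real_
  p[zero] <- 0
  p[lower] <- stats::ppois(k[lower], lam[lower])
  p[upper] <- stats::ppois(k[upper], lam[upper], lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

significance_flag <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Test observed against expected replacement counts
#'
#' Emits two Poisson tail tests (parallel and convergent) per branch pair.
#' Multiple-comparison correction, if requested, is applied jointly across
#' all non-NA p-values of both categories; significance flags are derived
#' from the (possibly corrected) p-values.
#'
#' @param observed counts data frame from \code{identify_events}.
#' @param expected a \code{pc_expectation} with the same pairs.
#' @param correction one of \code{"none"}, \code{"bonferroni"}, \code{"bh"}.
#' @return a data frame of class \code{pc_tests} with columns \code{first},
#'   \code{second}, \code{category}, \code{observed}, \code{expected},
#'   \code{p}, \code{significance}.
#' @export
detect <- function(observed, expected, correction = c("none", "bonferroni",
                                                      "bh")) {
  correction <- match.arg(correction)
  if (nrow(observed) != nrow(expected))
    stop("observed and expected cover different numbers of pairs")
  ko <- order(observed$first, observed$second)
  ke <- order(expected$first, expected$second)
  observed <- observed[ko, , drop = FALSE]
  exp_s <- expected[ke, , drop = FALSE]
  if (!identical(paste(observed$first, observed$second),
                 paste(exp_s$first, exp_s$second)))
    stop("observed and expected branch pairs do not match")
  n <- nrow(observed)
  out <- data.frame(
    first = rep(observed$first, each = 2L),
    second = rep(observed$second, each = 2L),
    category = rep(c("P", "C"), n),
    observed = as.vector(rbind(observed$parallel, observed$convergent)),
    expected = as.vector(rbind(exp_s$e_parallel, exp_s$e_convergent)),
    stringsAsFactors = FALSE)
  out$p <- poisson_tail_p(out$observed, out$expected)
  if (correction != "none" && any(!is.na(out$p))) {
    method <- c(bonferroni = "bonferroni", bh = "BH")[[correction]]
    out$p[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], method)
  }
  out$significance <- significance_flag(out$p)
  class(out) <- c("pc_tests", "data.frame")
  out
}

#' Write test results to TSV
#'
#' Columns: \code{pair}, \code{category}, \code{observed}, \code{expected},
#' \code{p} (4 decimals, literal \code{"N/A"} when undefined),
#' \code{significance}.
#'
#' @param tests a \code{pc_tests} data frame.
#' @param path output path.
#' @export
write_tests_tsv <- function(tests, path) {
  out <- data.frame(pair = pair_key(tests$first, tests$second),
                    category = tests$category,
                    observed = tests$observed,
                    expected = sprintf("%.6f", tests$expected),
                    p = ifelse(is.na(tests$p), "N/A",
                               sprintf("%.4f", tests$p)),
                    significance = tests$significance)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
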