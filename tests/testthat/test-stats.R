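# independent high-precision reference: direct log-space term summation
ref_tail <- function(k, lam) {
  if (lam == 0) return(if (k == 0) NA_real_ else 0)
  terms <- exp(-lam + (0:k) * log(lam) - lgamma((0:k) + 1))
  if (k < lam) sum(terms) else 1 - sum(terms)
}

test_that("poisson_tail_p applies the tail-selection and N/A rules", {
  expect_equal(poisson_tail_p(0, 0.43), exp(-0.43), tolerance = 1e-12)
  expect_equal(round(poisson_tail_p(1, 0.35), 4), 0.0487)
  expect_equal(round(poisson_tail_p(1, 1.6), 4), 0.5249)   # lower, 1 < 1.6
  expect_true(is.na(poisson_tail_p(0, 0)))
  expect_equal(poisson_tail_p(3, 0), 0)                    # impossible null
  # upper tail is strict: P(X >= k+1); at k == lambda the upper tail applies
  expect_equal(poisson_tail_p(2, 2), 1 - ppois(2, 2), tolerance = 1e-12)
  expect_error(poisson_tail_p(-1, 1), ">= 0")
  expect_error(poisson_tail_p(1, -1), ">= 0")
})

test_that("tails are complementary and monotone in lambda", {
  for (k in c(0L, 1L, 5L, 20L)) for (lam in c(0.1, 1, 7.5)) {
    lower <- ppois(k, lam)
    upper <- ppois(k, lam, lower.tail = FALSE)
    expect_equal(lower + upper, 1, tolerance = 1e-12)
  }
  lams <- seq(0.05, 20, by = 0.05)
  for (k in c(0L, 2L, 8L)) {
    up <- vapply(lams[lams <= k], function(l) poisson_tail_p(k, l), 0)
    lo <- vapply(lams[lams > k], function(l) poisson_tail_p(k, l), 0)
    if (length(up) > 1) expect_true(all(diff(up) > 0))  # upper increasing
    if (length(lo) > 1) expect_true(all(diff(lo) < 0))  # lower decreasing
  }
})

test_that("poisson_tail_p agrees with the log-space series reference", {
  for (k in 0:50) for (lam in c(0.01, 0.43, 1.6, 5, 12.3, 20)) {
    expect_lt(abs(poisson_tail_p(k, lam) - ref_tail(k, lam)), 1e-10)
  }
})

make_counts <- function(df) {
  data.frame(first = df$first, second = df$second,
             parallel = df$op, convergent = df$oc)
}
make_exp <- function(df) {
  structure(data.frame(first = df$first, second = df$second,
                       e_parallel = df$ep, e_convergent = df$ec),
            method = "analytic", class = c("pc_expectation", "data.frame"))
}

test_that("detect emits two tests per pair with flags from the tail rule", {
  df <- data.frame(first = c("Cow", "Cat"), second = c("Langur", "Pig"),
                   op = c(0L, 5L), oc = c(1L, 0L),
                   ep = c(0.43, 2.87), ec = c(0.35, 0))
  res <- detect(make_counts(df), make_exp(df))
  expect_equal(nrow(res), 4L)
  cl_p <- res[res$first == "Cow" & res$category == "P", ]
  expect_equal(round(cl_p$p, 4), 0.6505)
  expect_identical(cl_p$significance, "")
  cl_c <- res[res$first == "Cow" & res$category == "C", ]
  expect_equal(round(cl_c$p, 4), 0.0487)
  expect_identical(cl_c$significance, "*")
  na_row <- res[res$first == "Cat" & res$category == "C", ]
  expect_true(is.na(na_row$p))
  expect_identical(na_row$significance, "")
})

test_that("corrections act jointly on non-NA p-values only", {
  df <- data.frame(first = c("a", "b"), second = c("x", "y"),
                   op = c(1L, 0L), oc = c(2L, 0L),
                   ep = c(0.35, 0.5), ec = c(0.48, 0))
  raw <- detect(make_counts(df), make_exp(df))
  bon <- detect(make_counts(df), make_exp(df), correction = "bonferroni")
  m <- sum(!is.na(raw$p))
  expect_equal(m, 3L)
  expect_equal(bon$p[!is.na(bon$p)],
               pmin(1, m * raw$p[!is.na(raw$p)]), tolerance = 1e-12)
  expect_true(is.na(bon$p[is.na(raw$p)]))
  bh <- detect(make_counts(df), make_exp(df), correction = "bh")
  expect_true(all(bh$p[!is.na(bh$p)] >= raw$p[!is.na(raw$p)] - 1e-12))
})

test_that("detect validates keys and handles empty input", {
  empty <- data.frame(first = character(0), second = character(0),
                      parallel = integer(0), convergent = integer(0))
  eexp <- structure(data.frame(first = character(0), second = character(0),
                               e_parallel = numeric(0),
                               e_convergent = numeric(0)),
                    method = "analytic",
                    class = c("pc_expectation", "data.frame"))
  expect_equal(nrow(detect(empty, eexp)), 0L)

  df <- data.frame(first = "a", second = "x", op = 1L, oc = 0L,
                   ep = 0.3, ec = 0.3)
  bad <- make_exp(data.frame(first = "a", second = "z", op = 1, oc = 0,
                             ep = 0.3, ec = 0.3))
  expect_error(detect(make_counts(df), bad), "do not match")
})

test_that("tests TSV prints 4-decimal p-values and the N/A literal", {
  df <- data.frame(first = c("Cow", "Cat"), second = c("Langur", "Pig"),
                   op = c(0L, 0L), oc = c(1L, 0L),
                   ep = c(0.43, 0), ec = c(0.35, 0))
  res <- detect(make_counts(df), make_exp(df))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tests_tsv(res, f)
  lines <- readLines(f)
  expect_identical(lines[1],
                   "pair\tcategory\tobserved\texpected\tp\tsignificance")
  expect_true(any(grepl("^Cow-Langur\tP\t0\t0.430000\t0.6505\t$", lines)))
  expect_true(any(grepl("\tN/A\t", lines)))
})
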