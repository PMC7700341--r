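test_that("Kruskal-Wallis matches the hand-computed example and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(kw$H, 27 / 7)
  expect_equal(kw$H, 3.857, tolerance = 0.001 / 3.857)
  expect_equal(kw$p, pchisq(27 / 7, df = 1, lower.tail = FALSE))
  expect_equal(kw$df, 1)

  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2))), list(H = 0, df = 1, p = 1))
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "non-empty")
  expect_error(kruskal_wallis(list(1, 2)), "at least 5")
})

test_that("Kruskal-Wallis equals the no-ties closed form and is invariant", {
  closed_form <- function(groups) {
    r <- rank(unlist(groups))
    N <- length(r)
    sizes <- vapply(groups, length, integer(1))
    Rj <- split(r, rep(seq_along(groups), sizes))
    12 / (N * (N + 1)) * sum(vapply(Rj, sum, numeric(1))^2 / sizes) - 3 * (N + 1)
  }
  set.seed(91)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j) runif(sample(3:12, 1)))  # no ties
    kw <- kruskal_wallis(groups)
    expect_equal(kw$H, closed_form(groups), tolerance = 1e-12)
    # invariance to increasing transforms of the pooled values
    expect_equal(kruskal_wallis(lapply(groups, function(g) exp(3 * g)))$H, kw$H)
    # invariance to group order
    expect_equal(kruskal_wallis(rev(groups))$H, kw$H)
  }
})

test_that("with two groups KW reproduces the Wilcoxon normal approximation", {
  wilcoxon_p <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x); N <- length(r)
    W <- sum(r[seq_len(n1)])
    t <- table(c(x, y))
    v <- n1 * (N - n1) / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    2 * pnorm(-abs((W - n1 * (N + 1) / 2) / sqrt(v)))
  }
  set.seed(97)
  for (i in 1:100) {
    x <- sample(1:9, sample(4:15, 1), replace = TRUE)  # ties on purpose
    y <- sample(1:9, sample(4:15, 1), replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(kruskal_wallis(list(x, y))$p, wilcoxon_p(x, y),
                 tolerance = 1e-9)
  }
})

test_that("quartile descriptives follow the linear-interpolation convention", {
  expect_equal(describe_quartiles(1:4)$median, 2.5)
  d <- describe_quartiles(1:5)
  expect_equal(d$median, 3)
  expect_equal(d$q1, oracle_quantile(1:5, 0.25))
  expect_equal(d$q3, oracle_quantile(1:5, 0.75))
  expect_equal(d$iqr, d$q3 - d$q1)

  set.seed(101)
  x <- rnorm(37)
  expect_equal(describe_quartiles(rev(x)), describe_quartiles(x))
  expect_equal(describe_quartiles(rep(2, 6))$iqr, 0)
  expect_error(describe_quartiles(numeric(0)), "no values")
})

test_that("attrition tests type correctly, flag real shifts, skip degenerates", {
  set.seed(103)
  n_r <- 200; n_d <- 60
  retained <- data.frame(age = rnorm(n_r, 34, 6),
                         employed = sample(c("yes", "no"), n_r, TRUE),
                         site = "A")
  dropped <- data.frame(age = rnorm(n_d, 34 - 12, 6),  # -2 SD shift
                        employed = sample(c("yes", "no"), n_d, TRUE),
                        site = "A")
  rep_types <- c(age = "continuous", employed = "categorical",
                 site = "categorical")
  out <- attrition_tests(retained, dropped, rep_types)
  expect_equal(out$type, unname(rep_types))
  expect_true(out$flagged[out$variable == "age"])
  expect_equal(out$note[out$variable == "site"], "single observed level")
  expect_true(is.na(out$p[out$variable == "site"]))

  # identically distributed groups: null flag rate stays near alpha
  flags <- vapply(1:200, function(i) {
    r <- data.frame(x = rnorm(100)); d <- data.frame(x = rnorm(40))
    attrition_tests(r, d, c(x = "continuous"))$flagged
  }, logical(1))
  expect_lt(mean(flags), 0.10)
  expect_gt(mean(flags), 0.01)
})

test_that("validation reports summarize both groups and handle degenerate ones", {
  set.seed(107)
  n <- 60
  groups <- data.frame(dyad_id = sprintf("d%02d", 1:n),
                       group = factor(rep(c("low", "high"), c(45, 15)),
                                      levels = c("low", "high")))
  outcomes <- data.frame(dyad_id = groups$dyad_id,
                         good = c(rnorm(45, 0), rnorm(15, -1.5)),
                         flat = rnorm(n))
  rep1 <- validation_report(groups, outcomes, anova_check = TRUE)
  expect_s3_class(rep1, "validation_report")
  expect_equal(rep1$n_low, c(45, 45))
  expect_true(all(rep1$tested))
  expect_lt(rep1$p[rep1$outcome == "good"], 0.05)
  expect_gt(rep1$median_low[1], rep1$median_high[1])
  # parametric cross-check agrees on the clear effect
  expect_lt(rep1$anova_p[rep1$outcome == "good"], 0.05)

  # empty high group: outcomes reported untested, report still emitted
  g2 <- groups; g2$group[] <- "low"
  rep2 <- validation_report(g2, outcomes)
  expect_false(any(rep2$tested))
  expect_true(all(is.na(rep2$p)))
  expect_equal(rep2$n_high, c(0, 0))
  expect_equal(rep2$median_low[1],
               describe_quartiles(outcomes$good)$median)
})
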