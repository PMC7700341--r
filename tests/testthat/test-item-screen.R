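test_that("discretization keeps observed levels and merges thin ones", {
  expect_equal(nlevels(discretize_item(c(3, 3, 4, 4, 5), min_count = 1)), 3)

  scores <- c(rep(3, 50), rep(4, 50), rep(5, 2))
  d <- discretize_item(scores, min_count = 5)
  expect_equal(levels(d), c("3", "4"))
  expect_equal(as.character(d[scores == 5]), c("4", "4"))  # merged upward-nearest

  expect_equal(nlevels(discretize_item(rep(4, 30))), 1)
  expect_error(discretize_item(c(0.5, 3)), "\\[1, 5\\]")
})

test_that("screen keeps inverse trends and rejects flat or reversed ones", {
  set.seed(71)
  n <- 200
  item <- sample(3:5, n, replace = TRUE)
  markers_down <- data.frame(bmi_z = 2 - 0.8 * item + rnorm(n, 0, 0.5))
  expect_true(screen_item(item, markers_down)$kept)

  markers_up <- data.frame(bmi_z = 0.8 * item + rnorm(n, 0, 0.5))
  res_up <- screen_item(item, markers_up)
  expect_false(res_up$kept)

  # a constant item cannot be screened
  expect_false(screen_item(rep(4, n), markers_down)$kept)
  expect_match(screen_item(rep(4, n), markers_down)$reason, "single category")

  # too few paired observations drops the item with a reason
  few <- screen_item(item[1:10], markers_down[1:10, , drop = FALSE],
                     min_pairs = 20, min_count = 1)
  expect_false(few$kept)
})

test_that("null items survive the screen at roughly the nominal rate", {
  set.seed(73)
  n <- 200
  marker <- data.frame(bmi_z = rnorm(n))
  kept <- vapply(1:200, function(i) {
    screen_item(sample(seq(2, 5, 0.5), n, replace = TRUE), marker)$kept
  }, logical(1))
  # one-sided alpha = 0.05 gate: admission near 5%, nowhere near the ~24%
  # a raw rho threshold of 0.05 would allow at this sample size
  expect_lt(mean(kept), 0.10)
  expect_gt(mean(kept), 0.005)
})

test_that("screen decisions are rank-based: monotone marker transforms and
           dyad duplication change nothing", {
  set.seed(79)
  n <- 150
  item <- sample(seq(2, 5, 0.5), n, replace = TRUE)
  y <- 1 - 0.4 * item + rnorm(n)
  m1 <- data.frame(marker = y)
  m2 <- data.frame(marker = exp(y))           # strictly increasing transform
  r1 <- screen_item(item, m1)
  r2 <- screen_item(item, m2)
  expect_equal(r1$stats$rho, r2$stats$rho)
  expect_equal(r1$kept, r2$kept)

  dup <- screen_item(rep(item, 2), data.frame(marker = rep(y, 2)))
  expect_equal(dup$stats$rho, r1$stats$rho)
  expect_equal(dup$kept, r1$kept)
})

test_that("pool reduction prunes deterministically to the size range", {
  mk <- function(item, construct, rho, kept = TRUE)
    data.frame(item = item, construct = construct, kept = kept,
               reason = "", best_rho = rho)
  # 20 passing within range: untouched
  res <- do.call(rbind, lapply(1:20, function(i)
    mk(sprintf("i%02d", i), "C", -0.2)))
  red <- reduce_pool(res, size_range = c(16, 20))
  expect_length(red$items, 20)
  expect_false(red$under_minimum)

  # 25 passing: exactly 20 kept, the strongest (most negative) correlations
  rhos <- seq(-0.30, -0.06, length.out = 25)
  res <- do.call(rbind, lapply(1:25, function(i)
    mk(sprintf("i%02d", i), c("A", "B")[1 + i %% 2], rhos[i])))
  red <- reduce_pool(res, size_range = c(16, 20))
  expect_length(red$items, 20)
  expect_setequal(red$items, sprintf("i%02d", 1:20))  # the 20 strongest

  # deterministic lexicographic tie-break at equal strength
  res <- do.call(rbind, lapply(1:21, function(i)
    mk(sprintf("i%02d", i), "C", -0.1)))
  red <- reduce_pool(res, size_range = c(16, 20))
  expect_equal(red$items, sprintf("i%02d", 1:20))

  # under-minimum pool is returned whole with the warning flag
  res <- do.call(rbind, lapply(1:10, function(i)
    mk(sprintf("i%02d", i), "C", -0.2)))
  red <- reduce_pool(res, size_range = c(16, 20))
  expect_length(red$items, 10)
  expect_true(red$under_minimum)

  # per-construct caps bind before the global prune
  res <- rbind(do.call(rbind, lapply(1:9, function(i)
    mk(sprintf("fv%02d", i), "FV", -0.3 + 0.01 * i))),
    do.call(rbind, lapply(1:12, function(i)
      mk(sprintf("ot%02d", i), "Other", -0.2))))
  red <- reduce_pool(res, size_range = c(16, 20), construct_caps = c(FV = 4))
  expect_equal(sum(grepl("^fv", red$items)), 4)
  expect_setequal(red$items[grepl("^fv", red$items)], sprintf("fv%02d", 1:4))
})

test_that("screen_items + reduce_pool runs end-to-end on a cohort", {
  ch <- simulate_cohort(sim_config(), seed = 83)
  an <- derive_anthro(ch$anthro)
  scr <- screen_items(ch$responses, ch$codebook,
                      an[, c("dyad_id", "bmi_percentile", "bmi_z", "whtr")])
  expect_equal(nrow(scr), 45)
  expect_true(all(c("kept", "best_rho", "rho_bmi_z") %in% names(scr)))
  # BMI percentile and BMI z are rank-equivalent markers
  expect_equal(scr$rho_bmi_percentile, scr$rho_bmi_z)
  red <- reduce_pool(scr)
  expect_true(all(red$items %in% scr$item[scr$kept]))
})
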