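test_that("replicate selection follows the best-2-of-3 CV rule", {
  r <- select_replicates(c(10, 10, 20))
  expect_equal(r$value, 10)
  expect_equal(r$flag, "best_pair")

  r <- select_replicates(c(10.0, 10.1, 10.2))
  expect_equal(r$value, 10.1)
  expect_equal(r$flag, "ok")
  expect_lt(r$cv, 0.05)

  # duplicates: CV on the pair, pass/fail per threshold
  expect_equal(select_replicates(c(5, 10))$flag, "fail")
  expect_equal(select_replicates(c(10, 10.05))$flag, "ok")
  expect_equal(select_replicates(c(5, 10))$value, 7.5)

  # all replicates equal: value is that constant, flag ok
  expect_equal(select_replicates(c(7, 7, 7)), list(value = 7, cv = 0, flag = "ok"))

  # no pair passes: best pair retained but flagged
  r <- select_replicates(c(1, 10, 100))
  expect_equal(r$flag, "fail")

  expect_error(select_replicates(7), "at least 2")
})

test_that("replicate selection is invariant to replicate order", {
  set.seed(31)
  for (i in 1:50) {
    v <- round(rlnorm(3, log(10), 0.3), 3)
    base <- select_replicates(v)
    perms <- list(v[c(2, 1, 3)], v[c(3, 2, 1)], v[c(2, 3, 1)])
    for (p in perms) expect_equal(select_replicates(p), base)
  }
})

test_that("plate normalization applies the geometric-mean ratio rule", {
  vals <- c(a = 10, b = 20, c = 30)
  plates <- c("P1", "P1", "P2")

  expect_equal(plate_normalize(vals, plates, c(P1 = 5, P2 = 5)), vals)

  # control at twice the geometric mean halves that plate's values
  ctrl <- c(P1 = 1, P2 = 4)  # geometric mean 2, so P2 factor = 1/2
  adj <- plate_normalize(vals, plates, ctrl)
  expect_equal(unname(adj), c(20, 40, 15))

  # correction factors multiply to 1 across plates
  ctrl <- c(P1 = 2.3, P2 = 7.7, P3 = 0.9)
  gm <- exp(mean(log(ctrl)))
  expect_equal(prod(gm / ctrl), 1)

  expect_error(plate_normalize(vals, plates, c(P1 = 5)), "no control")
  expect_error(plate_normalize(vals, plates, c(P1 = 5, P2 = -1)), "positive")
})

test_that("Tukey fences agree with an exhaustive brute-force oracle", {
  expect_equal(flag_outliers(1:9), rep(FALSE, 9))
  expect_equal(flag_outliers(c(1, 2, 3, 4, 100)), c(rep(FALSE, 4), TRUE))
  expect_equal(flag_outliers(rep(3, 6)), rep(FALSE, 6))
  expect_error(flag_outliers(1:3), "at least 4")

  # all multisets of sizes 4-8 drawn from a small grid
  grid <- c(0, 1, 2, 3, 50)
  set.seed(41)
  for (n in 4:8) {
    sets <- unique(t(replicate(60, sort(sample(grid, n, replace = TRUE)))))
    for (i in seq_len(nrow(sets))) {
      x <- sets[i, ]
      expect_equal(flag_outliers(x), oracle_tukey_flags(x))
    }
  }
})

test_that("derived biomarkers follow Friedewald, HOMA-IR and the ratio rules", {
  p <- data.frame(dyad_id = "a", total_cholesterol = 170, hdl_c = 50,
                  triglycerides = 100, glucose = 90, insulin = 10,
                  leptin = 4, adiponectin = 8)
  d <- derive_panel(p)
  expect_equal(d$ldl_c, 100)
  expect_equal(d$non_hdl_c, 120)
  expect_equal(d$homa_ir, 10 * (90 * 0.0555) / 22.5)  # 2.22
  expect_equal(d$chol_hdl_ratio, 3.4)
  expect_equal(d$tg_hdl_ratio, 2)
  expect_equal(d$leptin_adiponectin_ratio, 4 / 8000)

  # Friedewald withheld at TG >= 400, with the validity flag
  p$triglycerides <- 400
  d <- derive_panel(p)
  expect_true(is.na(d$ldl_c))
  expect_false(d$friedewald_valid)
  expect_equal(d$non_hdl_c, 120)  # unaffected

  # missing inputs leave derived values missing, not errors
  p2 <- data.frame(dyad_id = "b", glucose = 90)
  expect_true(is.na(derive_panel(p2)$homa_ir))
})

test_that("non-HDL dominates LDL and HOMA-IR is linear in insulin", {
  set.seed(51)
  p <- data.frame(dyad_id = sprintf("d%d", 1:30),
                  total_cholesterol = runif(30, 120, 220),
                  hdl_c = runif(30, 30, 70),
                  triglycerides = runif(30, 30, 350),
                  glucose = runif(30, 70, 110), insulin = runif(30, 2, 25))
  d <- derive_panel(p)
  expect_true(all(d$non_hdl_c >= d$ldl_c))
  p2 <- p; p2$insulin <- 2 * p$insulin
  expect_equal(derive_panel(p2)$homa_ir, 2 * d$homa_ir)
})

test_that("the lab pipeline recovers true values through plates and replicates", {
  set.seed(61)
  n <- 24
  truth <- rlnorm(n, log(8), 0.4)
  plates <- rep(c("P1", "P2", "P3"), length.out = n)
  pf <- c(P1 = 1.15, P2 = 0.9, P3 = 1.0)
  m <- truth * pf[plates]
  reps <- data.frame(dyad_id = sprintf("d%02d", 1:n), analyte = "insulin",
                     plate_id = plates,
                     rep1 = m * exp(rnorm(n, 0, 0.02)),
                     rep2 = m * exp(rnorm(n, 0, 0.02)),
                     rep3 = m * exp(rnorm(n, 0, 0.02)))
  ctrl <- data.frame(analyte = "insulin", plate_id = names(pf),
                     value = 100 * unname(pf))
  out <- process_lab(reps, ctrl)
  rel_err <- abs(out$panel$insulin / (truth * exp(mean(log(pf)))) - 1)
  expect_lt(max(rel_err), 0.05)
  expect_true(all(out$qc$flag %in% c("ok", "best_pair")))
})
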