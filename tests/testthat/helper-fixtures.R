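# small in-code fixtures shared across tests

# k-item codebook, integer option scores 1..5
tiny_codebook <- function(k = 18, construct = "Test") {
  items <- lapply(seq_len(k), function(i) {
    item_def(sprintf("q%02d", i), construct, paste("prompt", i),
             c(never = 1, rarely = 2, sometimes = 3, often = 4, always = 5))
  })
  codebook(items, version_tag = "tiny")
}

# response table where every item of `cb` gets the same score
uniform_responses <- function(cb, score, n = 1) {
  out <- data.frame(dyad_id = sprintf("d%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (id in item_ids(cb)) out[[id]] <- rep(score, n)
  out
}

# wide biomarker panel with all index components, built from a latent driver
# so that component correlations are realistic; no missing values
complete_panel <- function(n = 60, seed = 42, driver_sd = 1) {
  set.seed(seed)
  z <- rnorm(n, 0, driver_sd)
  noise <- function(s) rnorm(n, 0, s)
  panel <- data.frame(
    dyad_id = sprintf("d%03d", seq_len(n)),
    glucose = 85 * exp(0.07 * (0.5 * z + noise(0.8))),
    insulin = 5 * exp(0.5 * (0.5 * z + noise(0.8))),
    leptin = 3 * exp(0.7 * (0.5 * z + noise(0.8))),
    adiponectin = 10 * exp(0.35 * (-0.5 * z + noise(0.8))),
    triglycerides = 60 * exp(0.35 * (0.5 * z + noise(0.8))),
    total_cholesterol = 160 * exp(0.12 * (0.3 * z + noise(0.9))),
    hdl_c = 50 * exp(0.18 * (-0.5 * z + noise(0.8))),
    igfbp1 = 30 * exp(0.6 * (-0.5 * z + noise(0.8))),
    il10 = 0.5 * exp(0.5 * (-0.5 * z + noise(0.8))),
    crp = 0.5 * exp(0.9 * (0.5 * z + noise(0.8))),
    resistin = 10 * exp(0.4 * (0.5 * z + noise(0.8))),
    stringsAsFactors = FALSE)
  derive_panel(panel)
}

# independent quartile oracle: explicit linear interpolation between order
# statistics, written from the definition (h = (n-1)p + 1)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_tukey_flags <- function(x) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}
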