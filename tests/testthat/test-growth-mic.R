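# Maximum growth rate ---------------------------------------------------------

test_that("the mean-curve maximum-slope interval drives per-replicate rates", {
  g <- data.frame(replicate_id = rep(c("a", "b"), each = 3), strain = "TRP",
                  time_h = rep(c(0, 3, 6), 2),
                  cfu_per_ml = c(100, 200, 800, 100, 200, 800))
  r <- max_growth_rate(g)
  expect_equal(unname(r$interval), c(3, 6))
  expect_equal(r$rates$rate_log, rep(log(4) / 3, 2))
  expect_equal(r$rates$rate_raw, rep(200, 2))
  expect_equal(r$rates$yield72, c(800, 800))
})

test_that("flat curves give zero rate over the first interval", {
  g <- data.frame(replicate_id = rep(c("a", "b"), each = 3), strain = "TRP",
                  time_h = rep(c(0, 3, 6), 2), cfu_per_ml = rep(500, 6))
  r <- max_growth_rate(g)
  expect_equal(unname(r$interval), c(0, 3))
  expect_equal(r$rates$rate_log, c(0, 0))
})

test_that("a single replicate reduces to its own maximum slope", {
  g <- data.frame(replicate_id = "only", strain = "TYR",
                  time_h = c(0, 3, 6, 9), cfu_per_ml = c(10, 40, 400, 500))
  r <- max_growth_rate(g)
  expect_equal(unname(r$interval), c(3, 6))
  expect_equal(r$rates$rate_log, log(10) / 3)
})

test_that("zero CFU inside the chosen interval is flagged, not an error", {
  g <- data.frame(replicate_id = rep(c("a", "b"), each = 3), strain = "TRP",
                  time_h = rep(c(0, 3, 6), 2),
                  cfu_per_ml = c(100, 200, 800, 0, 0, 900))
  r <- max_growth_rate(g)
  expect_true(r$rates$flagged[r$rates$replicate_id == "b"])
  expect_true(is.na(r$rates$rate_log[r$rates$replicate_id == "b"]))
  expect_false(r$rates$flagged[r$rates$replicate_id == "a"])
})

# MIC calling ------------------------------------------------------------------

test_that("MIC is the first concentration without threshold growth", {
  r <- call_mic(data.frame(concentration = c(1, 2, 4, 8),
                           od600 = c(0.5, 0.3, 0.005, 0.002)))
  expect_equal(r$mic, 4)
  expect_false(r$censored)

  r2 <- call_mic(data.frame(concentration = c(1, 2, 4, 8),
                            od600 = c(0.5, 0.3, 0.02, 0.011)))
  expect_true(r2$censored)
  expect_equal(r2$label, "> 8")
  expect_true(is.na(r2$mic))

  # literal first-crossing rule on a non-monotone curve
  r3 <- call_mic(data.frame(concentration = c(1, 2, 4, 8),
                            od600 = c(0.005, 0.5, 0.005, 0.002)))
  expect_equal(r3$mic, 1)
  expect_true(r3$non_monotone)
})

test_that("MIC is invariant under appending higher concentrations", {
  base <- call_mic(data.frame(concentration = c(1, 2, 4),
                              od600 = c(0.5, 0.005, 0.002)))
  ext <- call_mic(data.frame(concentration = c(1, 2, 4, 8, 16),
                             od600 = c(0.5, 0.005, 0.002, 0.001, 0.001)))
  expect_equal(ext$mic, base$mic)
})

test_that("delta MIC subtracts the ancestral median and excludes censored", {
  der <- data.frame(replicate_id = paste0("d", 1:3), mic = c(8, 8, 8),
                    censored = FALSE)
  anc <- data.frame(replicate_id = paste0("a", 1:3), mic = c(2, 2, 2),
                    censored = FALSE)
  dm <- delta_mic(der, anc)
  expect_equal(dm$delta$delta, c(6, 6, 6))

  same <- delta_mic(der, der)
  expect_equal(same$delta$delta, c(0, 0, 0))

  anc$censored[2] <- TRUE
  expect_warning(dm2 <- delta_mic(der, anc), "censored")
  expect_equal(dm2$n_ancestral, 2)
  expect_equal(dm2$n_excluded, 1)
})

# Pairwise Mann-Whitney / BH / letters -----------------------------------------

test_that("exact MWU p-values match an exhaustive enumeration oracle", {
  r <- pairwise_compare(list(a = c(1, 2, 3), b = c(10, 11, 12)))
  expect_equal(r$pairs$p_raw, 0.1)
  expect_equal(r$pairs$U, 0)

  set.seed(5)
  for (k in 1:8) {
    x <- round(rnorm(sample(3:6, 1), 0, 10), 3)
    y <- round(rnorm(sample(3:6, 1), 1, 10), 3)
    got <- pairwise_compare(list(x = x, y = y))$pairs$p_raw
    expect_equal(got, mwu_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to exact enumeration at n = 8", {
  set.seed(9)
  for (k in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- mwu_enum_oracle(x, y)
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("identical samples give the null-mean U, p = 1 and a shared letter", {
  s <- c(3, 1, 4, 1, 5)
  r <- pairwise_compare(list(g1 = s, g2 = s))
  expect_equal(r$pairs$U, length(s)^2 / 2)
  expect_equal(r$pairs$p_bh, 1)
  expect_equal(unname(r$letters["g1"]), unname(r$letters["g2"]))
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("BH is monotone, bounded and the identity for a single test", {
  set.seed(2)
  for (k in 1:10) {
    p <- runif(7)
    adj <- p.adjust(p, "BH")
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
  expect_equal(p.adjust(0.37, "BH"), 0.37)
})

test_that("letters separate clearly different groups and join similar ones", {
  set.seed(4)
  lo1 <- rnorm(10, 0, 0.5); lo2 <- rnorm(10, 0.2, 0.5)
  hi <- rnorm(10, 50, 0.5)
  r <- pairwise_compare(list(lo1 = lo1, lo2 = lo2, hi = hi))
  expect_true(grepl(substr(r$letters["lo1"], 1, 1), r$letters["lo2"]))
  expect_false(r$letters["hi"] == r$letters["lo1"])
  shared <- intersect(strsplit(r$letters[["hi"]], "")[[1]],
                      strsplit(r$letters[["lo1"]], "")[[1]])
  expect_length(shared, 0)
})
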