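test_that("binning uses half-open bins and preserves counts", {
  tr <- make_trains(list(e = c(1, 4, 9) / 1000, f = numeric(0),
                         g = c(5, 9.999) / 1000), duration_s = 0.01)
  b <- bin_trains(tr, bin_ms = 5)
  expect_equal(unname(b$counts[, "e"]), c(2L, 1L))
  expect_equal(unname(b$counts[, "f"]), c(0L, 0L))
  # a spike exactly at 5 ms falls in the second bin
  expect_equal(unname(b$counts[, "g"]), c(0L, 2L))
  expect_equal(colSums(b$counts), vapply(tr$trains, length, 0L),
               ignore_attr = TRUE)
})

test_that("cross_correlate recovers identity and shifts", {
  set.seed(21)
  x <- rpois(400, 2)
  r <- cross_correlate(x, x, 5)
  expect_equal(unname(r["0"]), 1)
  y <- c(rep(0, 2), x[1:398])  # y = x delayed by 2 bins (x leads)
  r2 <- cross_correlate(x, y, 5)
  expect_equal(attr(r2, "lags")[which.max(r2)], 2L)
  expect_error(cross_correlate(x, y[-1], 5), "length mismatch")
})

test_that("degenerate variance yields zero coefficients with a flag", {
  x <- rpois(100, 2)
  z <- rep(0, 100)
  r <- cross_correlate(x, z, 3)
  expect_true(all(r == 0))
  expect_true(all(attr(r, "degenerate")))
})

test_that("cross_correlate equals the brute-force reference", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    x <- rpois(n, runif(1, 0.5, 3))
    y <- rpois(n, runif(1, 0.5, 3))
    L <- sample(1:6, 1)
    expect_equal(as.vector(cross_correlate(x, y, L)), ref_cc(x, y, L),
                 tolerance = 1e-12)
  }
})

test_that("maximum-bin ties break toward the smallest, then positive, lag", {
  r <- structure(c(.1, .5, .2, .2, .2, .5, .1),
                 names = -3:3, lags = -3:3)
  ex <- mfnet:::cc_extract(r)
  expect_equal(ex$lag, 2L)  # tie at -2/+2: positive lag preferred
  r2 <- structure(c(.1, .5, .2, .6, .5, .3, .1), names = -3:3, lags = -3:3)
  expect_equal(mfnet:::cc_extract(r2)$lag, 0L)
  expect_equal(mfnet:::cc_extract(r2)$c0, .6)
})

test_that("the correlation matrix is symmetric with compartment ordering", {
  lay <- build_layout(config_2x2())
  set.seed(23)
  base <- sort(runif(80, 0, 10))
  tr <- make_trains(list("11" = base, "21" = base,  # identical trains
                         "12" = sort(runif(60, 0, 10)),
                         "22" = numeric(0)), duration_s = 10)
  m <- correlation_matrix(bin_trains(tr), layout = lay)
  expect_equal(m, t(m))
  expect_equal(m["11", "21"], 1)
  # silent electrode: zero row/column, flagged
  expect_true(all(m["22", ] == 0))
  expect_true(attr(m, "silent")["22"])
  expect_equal(diag(m), c("11" = 1, "12" = 1, "21" = 1, "22" = 0))
  # compartment ordering: somatic column first
  expect_equal(colnames(m), c("11", "12", "21", "22"))
})

test_that("an exact shifted copy is maximally significant", {
  set.seed(24)
  x <- sort(runif(150, 0, 10))
  y <- x + 0.010  # +2 bins at 5 ms
  s <- significance_by_surrogates(x, y, 10, n_surrogates = 199, seed = 1)
  expect_equal(s$p_cmax, 1 / 200)
  expect_equal(s$observed$lag, 2L)
  expect_false(s$undefined)
})

test_that("pairs with fewer than two spikes are flagged undefined", {
  s <- significance_by_surrogates(numeric(0), sort(runif(20, 0, 5)), 5,
                                  n_surrogates = 100)
  expect_true(s$undefined)
  expect_true(is.na(s$p_cmax))
  tr <- make_trains(list(a = 1, b = sort(runif(30, 0, 10))), 10)
  cc <- correlate_pairs(tr, n_surrogates = 100, seed = 2)
  expect_true(cc$undefined)
  expect_false(cc$significant)
})

test_that("pair-level invariants hold and swapped pairs negate the delay", {
  set.seed(25)
  base <- sort(runif(120, 0.2, 9.8))
  tr <- make_trains(list(a = base, b = sort(base + 0.01),
                         c = sort(runif(100, 0, 10))), duration_s = 10)
  cc <- correlate_pairs(tr, n_surrogates = 199, seed = 3)
  ok <- !cc$undefined
  expect_true(all(cc$cmax[ok] >= cc$c0[ok] - 1e-12))
  expect_true(all(abs(cc$cmax[ok]) <= 1))
  expect_true(all(cc$delay_ms[ok] %% attr(cc, "bin_ms") == 0))
  # delay antisymmetry under argument swap of the underlying statistic
  b <- bin_trains(tr)
  rab <- mfnet:::cc_extract(cross_correlate(b$counts[, "a"], b$counts[, "b"], 5))
  rba <- mfnet:::cc_extract(cross_correlate(b$counts[, "b"], b$counts[, "a"], 5))
  expect_equal(rab$lag, -rba$lag)
  expect_equal(rab$cmax, rba$cmax, tolerance = 1e-12)
  # a-leads-b pair carries a positive delay
  expect_equal(cc$delay_ms[cc$a == "a" & cc$b == "b"], 10)
})

test_that("independent trains are rarely significant", {
  set.seed(26)
  hits <- 0
  for (i in 1:40) {
    x <- sort(runif(40, 0, 10)); y <- sort(runif(40, 0, 10))
    s <- significance_by_surrogates(x, y, 10, n_surrogates = 199)
    if (!is.na(s$p_cmax) && s$p_cmax <= 0.01) hits <- hits + 1
  }
  expect_lte(hits, 3)
})
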