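# Table-2/3-scale inputs used throughout: sire variances and genetic
# correlations of the three teat traits with MY and SCS
G_ts <- function(r_ms = 0.1)
  assemble_G(0.438, 0.958, 0.148, 0.86, 0.44, r_ms, check_pd = FALSE)
G_tsa <- function(r_ms = 0.1)
  assemble_G(0.128, 0.958, 0.148, 0.89, 0.36, r_ms, check_pd = FALSE)
G_tsb <- function(r_ms = 0.1)
  assemble_G(0.036, 0.958, 0.148, 0.54, 0.38, r_ms, check_pd = FALSE)

test_that("G is assembled from variances and correlations exactly", {
  G <- G_ts()
  expect_equal(G["teat", "MY"], 0.86 * sqrt(0.438 * 0.958), tolerance = 1e-12)
  expect_equal(G["teat", "MY"], 0.557, tolerance = 1e-3)
  expect_equal(diag(assemble_G(1, 2, 3, 0, 0, 0)), c(teat = 1, MY = 2, SCS = 3))
  expect_true(all(assemble_G(1, 2, 3, 0, 0, 0)[upper.tri(G)] == 0))
  expect_error(assemble_G(1, 1, 1, 1.01, 0, 0), "correlations")
  expect_error(assemble_G(-1, 1, 1, 0, 0, 0), "> 0")
  expect_error(assemble_G(1, 1, 1, 0.9, 0.9, -0.9), "minor")
})

test_that("single-trait index weights recover genetic correlations", {
  G <- G_ts()
  expect_equal(index_response(c(0, 1, 0), G), 0.86, tolerance = 1e-12)
  expect_equal(index_response(c(0, 0, -1), G), -0.44, tolerance = 1e-12)
  expect_error(index_response(c(0, 0, 0), G), "zero variance")
})

test_that("response sign equals the sign of the weighted covariances", {
  set.seed(41)
  for (k in 1:40) {
    r <- runif(3, -0.6, 0.6)
    G <- try(assemble_G(runif(1, .1, 2), runif(1, .1, 2), runif(1, .1, 2),
                        r[1], r[2], r[3]), silent = TRUE)
    if (inherits(G, "try-error")) next
    e <- sample(0:100, 1)
    w <- c(0, e / 100, -(1 - e / 100))
    num <- w[2] * G[2, 1] + w[3] * G[3, 1]
    for (nrm in c("sd_units", "gv")) {
      if (abs(num) < 1e-12) next
      expect_equal(sign(index_response(w, G, normalization = nrm)), sign(num))
    }
  }
})

test_that("emphasis sweep reproduces the study break-even points", {
  expect_equal(attr(emphasis_sweep(G_ts()), "breakeven"), 17)
  expect_equal(attr(emphasis_sweep(G_tsa()), "breakeven"), 14)
  expect_equal(attr(emphasis_sweep(G_tsb()), "breakeven"), 22)
  sw <- emphasis_sweep(G_ts())
  expect_equal(nrow(sw), 101)
  expect_equal(sw$emphasis, 0:100)
  # null covariances with the teat trait give a flat zero response
  G0 <- assemble_G(0.438, 0.958, 0.148, 0, 0, 0.1)
  expect_true(all(abs(emphasis_sweep(G0)$response) < 1e-12))
})

test_that("closed-form break-even equals the sweep on random PD matrices", {
  expect_equal(breakeven_emphasis(G_ts())$breakeven_exact, 16.74,
               tolerance = 0.01)
  # rho = 1 gives 50; zero teat-SCS covariance gives 0
  Gsym <- assemble_G(1, 1, 1, 0.5, 0.5, 0.1)
  expect_equal(breakeven_emphasis(Gsym)$breakeven_exact, 50)
  G0 <- assemble_G(1, 1, 1, 0.5, 0, 0.1)
  expect_equal(breakeven_emphasis(G0)$breakeven_exact, 0)
  set.seed(42)
  for (k in 1:50) {
    G <- try(assemble_G(runif(1, .1, 2), runif(1, .1, 2), runif(1, .1, 2),
                        runif(1, 0.05, 0.9), runif(1, -0.9, 0.9),
                        runif(1, -0.5, 0.5)), silent = TRUE)
    if (inherits(G, "try-error")) next
    expect_equal(breakeven_emphasis(G)$breakeven_grid,
                 attr(emphasis_sweep(G), "breakeven"))
  }
})

test_that("break-even is invariant to the MY-SCS genetic correlation", {
  for (r_ms in seq(-0.5, 0.5, by = 0.1)) {
    expect_equal(attr(emphasis_sweep(G_ts(r_ms)), "breakeven"), 17)
    expect_equal(attr(emphasis_sweep(G_tsa(r_ms)), "breakeven"), 14)
    expect_equal(attr(emphasis_sweep(G_tsb(r_ms)), "breakeven"), 22)
  }
})

test_that("response curve is continuous and crosses zero once when both
           covariances with the teat trait are positive", {
  for (Gf in list(G_ts, G_tsa, G_tsb)) {
    sw <- emphasis_sweep(Gf())
    expect_true(all(abs(diff(sw$response)) < 0.15)) # no jumps on 1% grid
    signs <- sign(sw$response[sw$response != 0])
    expect_equal(sum(diff(signs) != 0), 1)
  }
})

test_that("plateau responses are reported but depend on normalization", {
  # the curve levels off at high MY emphasis; both normalizations and both
  # genetic-SD conventions are computable
  sw <- emphasis_sweep(G_ts())
  plateau <- sw$response[sw$emphasis == 100]
  expect_true(is.finite(plateau))
  expect_equal(plateau, 0.86) # identity at full MY emphasis
  expect_equal(index_response(c(0, 1, 0), G_ts(), genetic_sd = "additive"),
               0.43, tolerance = 1e-12)
  gv <- index_response(c(0, 1, 0), G_ts(), normalization = "gv")
  expect_true(is.finite(gv) && gv > 0)
})
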