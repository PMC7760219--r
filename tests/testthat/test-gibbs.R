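# rtnorm() is the package's truncated-normal draw used for liability
# augmentation; closed forms for the standard normal tail moments give
# independent expected values.

test_that("truncated-normal draws match closed-form moments", {
  set.seed(51)
  n <- 1e5
  x <- rtnorm(n, mean = 0, sd = 1, lower = -Inf, upper = 0)
  # E[Z | Z < 0] = -sqrt(2/pi); var = 1 - 2/pi
  se <- sqrt((1 - 2 / pi) / n)
  expect_lt(abs(mean(x) - (-sqrt(2 / pi))), 3 * se)
  expect_true(all(x < 0))
  y <- rtnorm(n, mean = 0, sd = 1, lower = 0, upper = Inf)
  expect_true(all(y > 0))
  expect_lt(abs(mean(y) - sqrt(2 / pi)), 3 * se)
  # two-sided: interval (0, 1)
  z <- rtnorm(n, 0, 1, 0, 1)
  expect_true(all(z > 0 & z < 1))
  m01 <- (dnorm(0) - dnorm(1)) / (pnorm(1) - pnorm(0))
  expect_lt(abs(mean(z) - m01), 0.005)
})

test_that("truncated-normal sampling is seed-reproducible and tail-safe", {
  set.seed(7); a <- rtnorm(1000, 0, 1, -Inf, 0)
  set.seed(7); b <- rtnorm(1000, 0, 1, -Inf, 0)
  expect_identical(a, b)
  # deep tail: interval (8, Inf) under a standard normal
  set.seed(8)
  t8 <- rtnorm(2000, 0, 1, 8, Inf)
  expect_true(all(is.finite(t8)) && all(t8 >= 8))
  expect_lt(mean(t8), 8.3) # exponential tail: mean approx 8 + 1/8
})

test_that("chain bookkeeping gives the documented number of stored samples", {
  expect_equal(chain_plan(thl_control())$n_stored, 5000)
  expect_equal(chain_plan(1000, burn_in = 100, thin = 10)$n_stored, 90)
  expect_equal(chain_plan(thl_control(n_iter = 20000, burn_in = 8000,
                                      thin = 10))$n_stored, 1200)
})

test_that("chains are reproducible from the seed and invariant to row order", {
  sim <- small_sim()
  ctl <- thl_control(n_iter = 600, burn_in = 100, thin = 5, seed = 99)
  f1 <- fit_thl(sim$stacked, sim$pedigree, trait = "TS", control = ctl)
  f2 <- fit_thl(sim$stacked, sim$pedigree, trait = "TS", control = ctl)
  expect_identical(f1$draws, f2$draws)
  set.seed(1)
  shuffled <- sim$stacked[sample(nrow(sim$stacked)), ]
  f3 <- fit_thl(shuffled, sim$pedigree, trait = "TS", control = ctl)
  expect_identical(f1$draws, f3$draws)
  f4 <- fit_thl(sim$stacked, sim$pedigree, trait = "TS",
                control = thl_control(n_iter = 600, burn_in = 100, thin = 5,
                                      seed = 100))
  expect_false(identical(f1$draws, f4$draws))
})

test_that("residual constraints and threshold order hold at every draw", {
  sim <- small_sim()
  ctl <- thl_control(n_iter = 800, burn_in = 200, thin = 2, seed = 11)
  fit <- fit_thl(sim$stacked, sim$pedigree, trait = "TS", control = ctl)
  # teat-production residual covariance is structurally absent
  expect_false(any(grepl("R\\[MY,TS\\]|R\\[TS,MY\\]|R\\[SCS,TS\\]",
                         names(fit$draws))))
  # pinned thresholds and strictly increasing free threshold
  expect_true(all(fit$draws$t3 > 1))
  expect_equal(fit$pinned_thresholds, c(t1 = 0, t2 = 1))
  expect_true(all(fit$draws$`R[TS,TS]` > 0))
  # binary scheme: liability residual fixed at one
  fitb <- fit_thl(sim$stacked, sim$pedigree, trait = "TSa", control = ctl)
  expect_true(all(fitb$draws$`R[TSa,TSa]` == 1))
  expect_false("t3" %in% names(fitb$draws))
})

test_that("degenerate teat data are rejected with informative errors", {
  sim <- small_sim()
  st <- sim$stacked
  st$ts[st$block == "teat"] <- 1L
  expect_error(fit_thl(st, sim$pedigree, trait = "TS",
                       control = thl_control(200, 50, 1)),
               "no observations")
  # duplicate-coded fixed effects: hygiene aliased with quarter
  st2 <- sim$stacked
  teat_rows <- st2$block == "teat"
  st2$hygiene[teat_rows] <- match(st2$quarter[teat_rows], c("FL", "FR", "RL", "RR"))
  expect_error(fit_thl(st2, sim$pedigree, trait = "TS",
                       control = thl_control(200, 50, 1)),
               "rank deficient")
})

test_that("fixed-effect posterior means match the GLS oracle when
           covariances are fixed (Gaussian-only submodel)", {
  set.seed(61)
  n_cow <- 60; n_herd <- 6; n_sire <- 15; reps <- 4
  H <- diag(c(1, 4, 0.5)); P <- diag(c(1, 8, 1)); S <- diag(c(0.2, 0.6, 0.1))
  Rp <- matrix(c(6, -0.5, -0.5, 1.2), 2)
  herd_of <- rep_len(seq_len(n_herd), n_cow)
  sire_of <- rep_len(seq_len(n_sire), n_cow)
  ps_of <- rep_len(1:2, n_cow)
  uh <- cbind(rnorm(n_herd, 0, 2), rnorm(n_herd, 0, sqrt(0.5)))
  up <- cbind(rnorm(n_cow, 0, sqrt(8)), rnorm(n_cow, 0, 1))
  us <- cbind(rnorm(n_sire, 0, sqrt(0.6)), rnorm(n_sire, 0, sqrt(0.1)))
  b_true <- cbind(c(25, 30), c(3, 4.2))
  idx <- rep(seq_len(n_cow), each = reps)
  e <- matrix(rnorm(n_cow * reps * 2), ncol = 2) %*% chol(Rp)
  y <- b_true[ps_of[idx], ] + uh[herd_of[idx], ] + up[idx, ] +
    us[sire_of[idx], ] + e
  prod <- tibble::tibble(block = "prod", cow = paste0("c", idx),
                         herd = paste0("h", herd_of[idx]),
                         sire = paste0("s", sire_of[idx]),
                         parity = 1L, month = 1L,
                         ps_class = ps_of[idx], hygiene = NA_integer_,
                         quarter = NA_character_, ts = NA_integer_,
                         my = y[, 1], scs = y[, 2])
  ped <- tibble::tibble(id = c(paste0("s", 1:n_sire), paste0("c", 1:n_cow)),
                        sire = c(rep(NA, n_sire), paste0("s", sire_of)),
                        dam = NA)
  fit <- fit_thl(prod, ped, trait = "TS",
                 control = thl_control(n_iter = 6000, burn_in = 1000,
                                       thin = 2, seed = 31),
                 fix_covariances = list(H = H, P = P, S = S, Rprod = Rp,
                                        r11 = 1))
  # dense GLS oracle on the stacked 2-trait system
  A <- build_A(ped)[paste0("s", sire_of), paste0("s", sire_of)]
  n <- nrow(prod)
  kron_part <- function(K, member) {
    M <- outer(member, member, "==") * 1
    rbind(cbind(K[2, 2] * M, K[2, 3] * M), cbind(K[3, 2] * M, K[3, 3] * M))
  }
  V <- kron_part(H, herd_of[idx]) + kron_part(P, seq_len(n_cow)[idx]) +
    rbind(cbind(S[2, 2] * A[idx, idx], S[2, 3] * A[idx, idx]),
          cbind(S[3, 2] * A[idx, idx], S[3, 3] * A[idx, idx])) +
    kronecker(Rp, diag(n))
  X1 <- stats::model.matrix(~ 0 + factor(ps_of[idx]))
  X <- rbind(cbind(X1, 0 * X1), cbind(0 * X1, X1))
  yv <- c(y[, 1], y[, 2])
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
  post <- colMeans(fit$draws[, c("b[MY,ps1]", "b[MY,ps2]",
                                 "b[SCS,ps1]", "b[SCS,ps2]")])
  mcse <- apply(fit$draws[, c("b[MY,ps1]", "b[MY,ps2]",
                              "b[SCS,ps1]", "b[SCS,ps2]")], 2, function(v)
    sd(v) / sqrt(coda::effectiveSize(coda::mcmc(v))))
  expect_true(all(abs(post - drop(beta)) < 4 * mcse + 0.02))
})

test_that("stacked fits tolerate a missing production trait on some rows", {
  sim <- small_sim()
  st <- sim$stacked
  prod_rows <- which(st$block == "prod")
  st$scs[prod_rows[1:20]] <- NA
  fit <- fit_thl(st, sim$pedigree, trait = "TS",
                 control = thl_control(n_iter = 400, burn_in = 100, thin = 2,
                                       seed = 13))
  expect_true(all(is.finite(fit$draws$`R[SCS,SCS]`)))
})

test_that("least-squares means transform liability contrasts to
           probabilities", {
  sim <- small_sim(n_cows = 200, seed = 5)
  ctl <- thl_control(n_iter = 3000, burn_in = 1000, thin = 4, seed = 17)
  fit <- fit_thl(sim$stacked, sim$pedigree, trait = "TSa", control = ctl)
  lsm <- lsm_probability(fit, effect = "quarter")
  expect_setequal(lsm$level, c("FL", "FR", "RL", "RR"))
  expect_true(all(lsm$estimate > 0 & lsm$estimate < 1))
  expect_true(all(lsm$conf.low <= lsm$estimate &
                  lsm$estimate <= lsm$conf.high))
  # generator truth puts front quarters above rear ones on the liability
  # scale; the recovered front-vs-rear gap must be inside its own HPD
  front <- mean(lsm$estimate[lsm$level %in% c("FL", "FR")])
  rear <- mean(lsm$estimate[lsm$level %in% c("RL", "RR")])
  expect_gt(front, rear - 0.05)
  # eta at the threshold maps to probability one half
  expect_equal(1 - pnorm((0 - 0) / 1), 0.5)
})

test_that("tidy, glance and autoplot summarize a fit", {
  sim <- small_sim()
  fit <- fit_thl(sim$stacked, sim$pedigree, trait = "TS",
                 control = thl_control(n_iter = 400, burn_in = 100, thin = 2,
                                       seed = 3))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                  names(td)))
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_stored, chain_plan(thl_control(400, 100, 2))$n_stored)
  expect_s3_class(autoplot(fit), "ggplot")
  gp <- genetic_parameters(fit)
  expect_true(all(abs(gp$estimate[gp$parameter == "genetic_correlation"]) <= 1))
  expect_true(all(gp$estimate[gp$parameter == "heritability"] >= 0))
})
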