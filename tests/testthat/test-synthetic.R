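test_that("default configuration reproduces the study design sizes", {
  cfg <- sim_config()
  expect_equal(cfg$n_cows, 2649)
  expect_equal(cfg$n_sires, 869)
  expect_equal(cfg$n_dams, 2408)
  expect_equal(cfg$n_cow_dams, 275)
  expect_equal(cfg$n_herds, 48)
  set.seed(1)
  ped <- simulate_pedigree(cfg)
  cows <- grep("^C", ped$id, value = TRUE)
  expect_length(cows, 2649)
  sires_used <- unique(ped$sire[match(cows, ped$id)])
  expect_length(sires_used, 869)
  # cows reused as dams
  cow_dams <- intersect(ped$dam, cows)
  expect_length(cow_dams, cfg$n_cow_dams)
  # acyclic by construction: topological sort succeeds
  expect_silent(teatgen:::ped_index(ped))
})

test_that("scaled configurations shrink the pedigree proportionally", {
  cfg <- sim_config(n_cows = 500)
  expect_equal(cfg$n_sires, round(869 * 500 / 2649))
  expect_lt(cfg$n_cow_dams, cfg$n_dams)
  set.seed(2)
  ped <- simulate_pedigree(cfg)
  expect_length(grep("^C", ped$id), 500)
})

test_that("unrelated sires give an identity sire relationship block", {
  cfg <- sim_config(n_cows = 150, p_grandsire = 0)
  set.seed(3)
  ped <- simulate_pedigree(cfg)
  cows <- grep("^C", ped$id, value = TRUE)
  sires <- sort(unique(ped$sire[match(cows, ped$id)]))
  A <- teatgen:::sire_relationship(ped, sires)$A
  expect_equal(A, diag(length(sires)), ignore_attr = TRUE)
})

test_that("simulation is reproducible from the seed", {
  cfg <- sim_config(n_cows = 100, n_herds = 6)
  s1 <- simulate_study(cfg, seed = 42)
  s2 <- simulate_study(cfg, seed = 42)
  expect_identical(s1$teat, s2$teat)
  expect_identical(s1$production, s2$production)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- simulate_study(cfg, seed = 43)
  expect_false(identical(s1$teat, s3$teat))
})

test_that("generated records have the study's marginal structure", {
  sim <- simulate_study(sim_config(), seed = 7)
  # four quarter rows per cow, one scoring visit
  expect_equal(nrow(sim$teat), 4 * 2649)
  expect_true(all(table(sim$teat$cow) == 4))
  # calibrated intercept: class-1 share near the study's 65.7%
  expect_equal(mean(sim$teat$ts == 1), 0.657, tolerance = 0.05)
  # about ten monthly test-day records per cow
  expect_equal(median(table(sim$production$cow)), 10, tolerance = 0.1)
  expect_true(all(sim$production$scc > 0))
  expect_true(all(sim$production$my >= 0.1))
  # SCC was generated by inverting the score transform: exact round trip
  expect_equal(scc_from_scs(scs_from_scc(sim$production$scc)),
               sim$production$scc, tolerance = 1e-12)
  # herd sizes in a plausible range around the study mean of about 106
  hs <- table(sim$teat$herd) / 4
  expect_gt(mean(hs), 30)
  expect_lt(max(hs), 500)
  # realized sire-family means of herd- and stage-corrected milk yield
  # correlate with the true transmitting abilities at the default size
  dev <- sim$production$my -
    ave(sim$production$my, sim$production$herd) -
    ave(sim$production$my,
        paste(pmin(sim$production$parity, 3), sim$production$month)) +
    mean(sim$production$my)
  fam <- tapply(dev, sim$pedigree$sire[
    match(sim$production$cow, sim$pedigree$id)], mean)
  keep <- names(fam)[!is.na(fam)]
  expect_gt(cor(fam[keep], sim$truth$s[keep, 2]), 0.3)
})

test_that("truth object supports downstream recovery checks", {
  sim <- simulate_study(sim_config(n_cows = 400, n_herds = 20), seed = 9)
  tr <- sim$truth
  expect_true(all(eigen(tr$covariances$S)$values > 0))
  expect_equal(tr$thresholds[1:2], c(0, 1))
  expect_gt(tr$thresholds[3], 1)
  expect_equal(dim(tr$s), c(length(tr$sires), 3))
  expect_true(is.function(tr$profiles$mu_my))
})

test_that("near-null random effects leave only residual variation", {
  cfg <- sim_config(n_cows = 400, n_herds = 10)
  eps <- 1e-4
  cfg$covariances$S <- diag(3) * eps
  cfg$covariances$P <- diag(3) * eps
  cfg$covariances$H <- diag(3) * eps
  sim <- simulate_study(cfg, seed = 11)
  # de-trend by parity-month cell and compare to the residual truth
  res <- sim$production$my -
    ave(sim$production$my,
        paste(pmin(sim$production$parity, 3), sim$production$month))
  expect_equal(sd(res), sqrt(cfg$covariances$Rprod[1, 1]),
               tolerance = 0.05)
})
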