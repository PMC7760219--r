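#' Study-scale covariance truth for the generator
#'
#' Default (co)variance matrices for (teat liability, MY, SCS) at the
#' scale of the study design: sire, cow permanent-environment and herd
#' 3x3 matrices, the 2x2 production residual block and the teat
#' liability residual variance, assembled from variances and
#' correlations.  The MY-SCS correlations are free parameters of the
#' generator (mildly negative environmental, mildly positive genetic
#' defaults).
#'
#' @param trait `"TS"`, `"TSa"` or `"TSb"` — selects the teat-trait
#'   variance set.
#' @return List with `S`, `P`, `H` (3x3), `Rprod` (2x2), `r11`.
#' @export
default_covariances <- function(trait = c("TS", "TSa", "TSb")) {
  trait <- match.arg(trait)
  v <- switch(trait,
    TS  = list(s = 0.438, p = 3.998, h = 1.648, e = 1.281,
               r_sm = 0.86, r_ss = 0.44, r_pm = 0.01, r_ps = 0.14,
               r_hm = 0.30, r_hs = -0.25),
    TSa = list(s = 0.128, p = 1.449, h = 0.506, e = 1.073,
               r_sm = 0.89, r_ss = 0.36, r_pm = 0.02, r_ps = 0.12,
               r_hm = 0.30, r_hs = -0.25),
    TSb = list(s = 0.036, p = 0.430, h = 0.160, e = 1.085,
               r_sm = 0.54, r_ss = 0.38, r_pm = -0.003, r_ps = 0.15,
               r_hm = 0.46, r_hs = -0.47))
  mk3 <- function(v1, v2, v3, r12, r13, r23) {
    sd <- sqrt(c(v1, v2, v3))
    C <- diag(3)
    C[1, 2] <- C[2, 1] <- r12
    C[1, 3] <- C[3, 1] <- r13
    C[2, 3] <- C[3, 2] <- r23
    M <- C * tcrossprod(sd)
    if (any(eigen(M, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("non-positive-definite truth matrix")
    M
  }
  list(S = mk3(v$s, 0.958, 0.148, v$r_sm, v$r_ss, 0.10),
       P = mk3(v$p, 15.12, 1.488, v$r_pm, v$r_ps, -0.10),
       H = mk3(v$h, 15.04, 0.624, v$r_hm, v$r_hs, -0.20),
       Rprod = {
         sd <- sqrt(c(28.01, 1.788))
         M <- matrix(c(1, -0.10, -0.10, 1), 2) * tcrossprod(sd)
         M
       },
       r11 = v$e)
}

#' Generator configuration
#'
#' Describes the stacked study design the generator emulates: 48 herds,
#' 2,649 cows from 869 sires and 2,408 dams (275 cows reused as dams),
#' one scoring visit of four quarters per cow, about 10 monthly test-day
#' records per cow on the scoring lactation.  When `n_cows` is reduced,
#' sire/dam counts scale proportionally unless given explicitly.
#'
#' @param n_herds,n_cows,n_sires,n_dams,n_cow_dams,n_grandsires Design
#'   sizes; `NULL` entries scale with `n_cows`.
#' @param mean_testdays Poisson mean of test-day records per cow.
#' @param p_grandsire Probability a sire has a recorded (shared) sire.
#' @param covariances Truth (co)variances, see [default_covariances()].
#' @param class_freq Target marginal relative frequencies of the four
#'   teat scores, used to calibrate the liability intercept and the
#'   third threshold (the first two thresholds are pinned at 0 and 1,
#'   matching the model's identifiability scheme).
#' @param quarter_effects Liability shifts per quarter (front > rear).
#' @param hygiene_effects Liability shifts per hygiene class (null by
#'   default: hygiene carried but not causal).
#' @param herd_size_cv Log-scale SD of the herd-size weights.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_herds = 48, n_cows = 2649, n_sires = NULL,
                       n_dams = NULL, n_cow_dams = NULL,
                       n_grandsires = NULL, mean_testdays = 10,
                       p_grandsire = 0.6,
                       covariances = default_covariances("TS"),
                       class_freq = c(0.657, 0.249, 0.0778, 0.0161),
                       quarter_effects = c(FL = 0.12, FR = 0.12,
                                           RL = 0, RR = 0),
                       hygiene_effects = c(0, 0, 0, 0),
                       herd_size_cv = 0.4) {
  scale <- n_cows / 2649
  n_sires <- n_sires %||% max(5L, round(869 * scale))
  n_dams <- n_dams %||% max(5L, round(2408 * scale))
  n_cow_dams <- n_cow_dams %||% min(round(275 * scale), n_dams - 1L,
                                    floor(n_cows / 3))
  n_grandsires <- n_grandsires %||% max(2L, round(n_sires / 4))
  stopifnot(n_cow_dams < n_dams, n_cow_dams <= floor(n_cows / 2),
            abs(sum(class_freq) - 1) < 0.005) # printed frequencies round
  class_freq <- class_freq / sum(class_freq)
  structure(list(n_herds = n_herds, n_cows = n_cows, n_sires = n_sires,
                 n_dams = n_dams, n_cow_dams = n_cow_dams,
                 n_grandsires = n_grandsires,
                 mean_testdays = mean_testdays, p_grandsire = p_grandsire,
                 covariances = covariances, class_freq = class_freq,
                 quarter_effects = quarter_effects,
                 hygiene_effects = hygiene_effects,
                 herd_size_cv = herd_size_cv),
            class = "sim_config")
}

#' Simulate a study-shaped pedigree
#'
#' Grandsires are founders; sires descend from a shared grandsire with
#' probability `p_grandsire` (creating paternal half-sib relationships
#' among sires); dams are founders except for a fraction of cows that
#' reappear as dams of later cows.  The construction is generative, so
#' the pedigree is acyclic and parents precede offspring.
#'
#' @param cfg A [sim_config()].
#' @return Pedigree tibble (`id`, `sire`, `dam`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gs <- paste0("GS", seq_len(cfg$n_grandsires))
  sires <- paste0("S", seq_len(cfg$n_sires))
  n_founder_dams <- cfg$n_dams - cfg$n_cow_dams
  dams <- paste0("D", seq_len(n_founder_dams))
  cows <- paste0("C", seq_len(cfg$n_cows))

  sire_gs <- ifelse(runif(cfg$n_sires) < cfg$p_grandsire,
                    sample(gs, cfg$n_sires, replace = TRUE), NA_character_)

  # every sire gets at least one daughter; extras follow skewed usage
  sire_of_cow <- character(cfg$n_cows)
  sire_of_cow[seq_len(cfg$n_sires)] <- sample(sires)
  extra <- cfg$n_cows - cfg$n_sires
  if (extra > 0) {
    w <- stats::rlnorm(cfg$n_sires, 0, 1)
    sire_of_cow[cfg$n_sires + seq_len(extra)] <-
      sample(sires, extra, replace = TRUE, prob = w)
  }
  sire_of_cow <- sample(sire_of_cow) # decouple sire from cow index

  # dams: founder dams each used at least once; a fixed number of cows
  # from the first half reappear as dams of cows in the second half
  dam_of_cow <- character(cfg$n_cows)
  half <- floor(cfg$n_cows / 2)
  cow_dams <- sample(cows[seq_len(half)], cfg$n_cow_dams)
  daughters <- sample((half + 1):cfg$n_cows, cfg$n_cow_dams)
  dam_of_cow[daughters] <- cow_dams
  rest <- which(dam_of_cow == "")
  dam_of_cow[rest[seq_len(min(n_founder_dams, length(rest)))]] <-
    sample(dams)[seq_len(min(n_founder_dams, length(rest)))]
  rest <- which(dam_of_cow == "")
  if (length(rest))
    dam_of_cow[rest] <- sample(dams, length(rest), replace = TRUE)

  tibble::tibble(
    id = c(gs, sires, dams, cows),
    sire = c(rep(NA_character_, length(gs)), sire_gs,
             rep(NA_character_, length(dams)), sire_of_cow),
    dam = c(rep(NA_character_, length(gs) + length(sires) + length(dams)),
            dam_of_cow))
}

# smooth fixed-effect truth profiles; all centred so the liability
# intercept calibration below is exact in expectation
sim_profiles <- function(cfg) {
  pclass_prob <- c(0.35, 0.30, 0.35)
  month_prob <- rep(1 / 10, 10) # scoring month 1..10
  ts_parity <- c(0, 0.45, 0.55)
  ts_month <- function(m) 0.03 * (pmin(m, 12) - 1)
  mu_ts_raw <- function(p, m) ts_parity[pmin(p, 3)] + ts_month(m)
  e_ts <- sum(pclass_prob * ts_parity) +
    sum(month_prob * ts_month(1:10)) +
    mean(cfg$quarter_effects)
  sd_tot <- sqrt(cfg$covariances$S[1, 1] + cfg$covariances$P[1, 1] +
                 cfg$covariances$H[1, 1] + cfg$covariances$r11)
  mu0 <- -sd_tot * qnorm(cfg$class_freq[1])
  t3 <- mu0 + sd_tot * qnorm(1 - cfg$class_freq[4])
  list(
    pclass_prob = pclass_prob, month_prob = month_prob,
    mu_ts = function(p, m) mu0 + mu_ts_raw(p, m) - e_ts,
    thresholds = c(0, 1, t3),
    mu_my = function(p, m) c(27, 31, 32)[pmin(p, 3)] +
      2.5 * exp(-0.3 * (m - 1)) - 0.25 * (m - 1),
    mu_scs = function(p, m) c(3.4, 3.9, 4.2)[pmin(p, 3)] +
      0.05 * (pmin(m, 15) - 1))
}

#' Simulate teat-score and test-day records with known truth
#'
#' Draws sire effects from `N(0, A (x) S)` on the simulated pedigree,
#' herd and cow permanent-environment effects from their 3x3 truths,
#' then generates per-quarter liabilities (cut at the true thresholds
#' into 1-4 scores) and monthly test-day MY/SCS pairs per the model
#' equation.  SCC is back-transformed from a Gaussian SCS so the score
#' transform round-trips exactly.  Negative MY draws are truncated at
#' 0.1 kg (count reported in the truth object).
#'
#' @param cfg A [sim_config()].
#' @param ped Pedigree from [simulate_pedigree()].
#' @return List `teat`, `production` (tibbles in the raw-record formats
#'   [stack_records()] reads) and `truth` (true effects, covariances,
#'   thresholds, profiles and bookkeeping).
#' @export
simulate_records <- function(cfg, ped) {
  stopifnot(inherits(cfg, "sim_config"))
  cv <- cfg$covariances
  prof <- sim_profiles(cfg)
  cows <- paste0("C", seq_len(cfg$n_cows))
  pedn <- ped_normalize(ped)
  sire_of <- setNames(pedn$sire, pedn$id)[cows]
  sires <- sort(unique(unname(sire_of)))

  # correlated random effects
  rel <- sire_relationship(ped, sires, scheme = "full")
  LA <- t(chol(rel$A))
  s_mat <- LA %*% matrix(rnorm(length(sires) * 3), ncol = 3) %*%
    chol(cv$S)
  rownames(s_mat) <- sires
  h_mat <- matrix(rnorm(cfg$n_herds * 3), ncol = 3) %*% chol(cv$H)
  p_mat <- matrix(rnorm(cfg$n_cows * 3), ncol = 3) %*% chol(cv$P)

  herd_w <- stats::rlnorm(cfg$n_herds, 0, cfg$herd_size_cv)
  herd_of <- sample(seq_len(cfg$n_herds), cfg$n_cows, replace = TRUE,
                    prob = herd_w)
  pclass <- sample(1:3, cfg$n_cows, replace = TRUE, prob = prof$pclass_prob)
  parity <- ifelse(pclass < 3, pclass, sample(3:5, cfg$n_cows, TRUE))
  month0 <- sample(1:10, cfg$n_cows, replace = TRUE, prob = prof$month_prob)
  hygiene <- sample(1:4, cfg$n_cows, replace = TRUE,
                    prob = c(0.35, 0.35, 0.20, 0.10))

  qlev <- quarter_levels()
  sidx <- match(unname(sire_of), sires)
  eta_cow <- prof$mu_ts(parity, month0) + cfg$hygiene_effects[hygiene] +
    h_mat[herd_of, 1] + p_mat[, 1] + s_mat[sidx, 1]
  teat <- tidyr::expand_grid(i = seq_len(cfg$n_cows), quarter = qlev)
  lam <- eta_cow[teat$i] + cfg$quarter_effects[teat$quarter] +
    rnorm(nrow(teat), 0, sqrt(cv$r11))
  ts <- 1L + findInterval(lam, prof$thresholds)
  teat_tbl <- tibble::tibble(
    cow = cows[teat$i], herd = paste0("H", herd_of[teat$i]),
    parity = parity[teat$i], month = month0[teat$i],
    hygiene = hygiene[teat$i], quarter = teat$quarter, ts = ts)

  n_td <- pmax(3L, rpois(cfg$n_cows, cfg$mean_testdays))
  n_td <- pmin(n_td, 15L)
  prod <- tibble::tibble(i = rep(seq_len(cfg$n_cows), n_td),
                         month = unlist(lapply(n_td, seq_len)))
  e_prod <- matrix(rnorm(nrow(prod) * 2), ncol = 2) %*% chol(cv$Rprod)
  my <- prof$mu_my(parity[prod$i], prod$month) + h_mat[herd_of[prod$i], 2] +
    p_mat[prod$i, 2] + s_mat[sidx[prod$i], 2] + e_prod[, 1]
  scs <- prof$mu_scs(parity[prod$i], prod$month) +
    h_mat[herd_of[prod$i], 3] + p_mat[prod$i, 3] + s_mat[sidx[prod$i], 3] +
    e_prod[, 2]
  n_my_trunc <- sum(my < 0.1)
  my <- pmax(my, 0.1)
  prod_tbl <- tibble::tibble(
    cow = cows[prod$i], herd = paste0("H", herd_of[prod$i]),
    parity = parity[prod$i], month = prod$month,
    my = my, scc = scc_from_scs(scs))

  list(teat = teat_tbl, production = prod_tbl,
       truth = list(covariances = cv, thresholds = prof$thresholds,
                    s = s_mat, h = h_mat, p = p_mat,
                    sires = sires, herd_of = herd_of,
                    profiles = prof, n_my_truncated = n_my_trunc))
}

#' Simulate a complete study (pedigree + records) from one seed
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed governing the whole dataset.
#' @return List `pedigree`, `teat`, `production`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_records(cfg, ped)
  c(list(pedigree = ped), rec)
}
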