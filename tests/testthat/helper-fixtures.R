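# shared fixtures: random pedigrees, a kinship-recursion oracle for A,
# and small simulated study datasets

random_pedigree <- function(n, seed, p_parent = 0.7) {
  set.seed(seed)
  ids <- paste0("I", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 2) next
    if (runif(1) < p_parent) sire[i] <- ids[sample(i - 1L, 1)]
    if (runif(1) < p_parent) {
      d <- ids[sample(i - 1L, 1)]
      if (!identical(d, sire[i])) dam[i] <- d
    }
  }
  tibble::tibble(id = ids, sire = sire, dam = dam)
}

# independent oracle: additive relationship via the coefficient-of-kinship
# recursion (2 * phi), memoized; assumes rows are ordered parents-first
kinship_A_oracle <- function(ped) {
  ids <- ped$id
  si <- stats::setNames(ped$sire, ids)
  di <- stats::setNames(ped$dam, ids)
  pos <- stats::setNames(seq_along(ids), ids)
  memo <- new.env(hash = TRUE)
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      0.5 * (1 + phi(si[[a]], di[[a]]))
    } else {
      if (pos[[a]] < pos[[b]]) { tmp <- a; a <- b; b <- tmp }
      0.5 * (phi(si[[a]], b) + phi(di[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * phi(ids[i], ids[j])
  A
}

# small complete raw-record fixture for stacking tests
tiny_records <- function() {
  quarters <- c("FL", "FR", "RL", "RR")
  teat <- tibble::tibble(
    cow = rep(c("c1", "c2"), each = 4),
    herd = "h1", parity = rep(c(1L, 2L), each = 4), month = 3L,
    hygiene = rep(c(2L, 1L), each = 4), quarter = rep(quarters, 2),
    ts = c(1L, 2L, 1L, 1L, 3L, 4L, 2L, 2L))
  production <- tibble::tibble(
    cow = c("c1", "c1", "c2", "c2", "c2"),
    herd = "h1",
    parity = c(1L, 1L, 2L, 2L, 1L), # last row: other lactation
    month = c(2L, 4L, 1L, 5L, 3L),
    my = c(28, 30, 35, 33, 31),
    scc = c(1e5, 4e5, 5e4, 2e5, 1e5))
  pedigree <- tibble::tibble(id = c("s1", "s2", "d1", "d2", "c1", "c2"),
                             sire = c(NA, NA, NA, NA, "s1", "s2"),
                             dam = c(NA, NA, NA, NA, "d1", "d2"))
  list(teat = teat, production = production, pedigree = pedigree)
}

# small stacked simulated dataset + fit, cached per test run
small_sim <- function(n_cows = 120, seed = 3, n_herds = 8) {
  cfg <- sim_config(n_cows = n_cows, n_herds = n_herds)
  sim <- simulate_study(cfg, seed = seed)
  sim$stacked <- suppressWarnings(
    stack_records(sim$teat, sim$production, sim$pedigree))
  sim
}
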