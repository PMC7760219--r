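#' Chain-length and prior settings for the Gibbs sampler
#'
#' Defaults mirror the study protocol: 300,000 iterations, 50,000
#' burn-in, thinning every 50, giving 5,000 stored samples per parameter.
#' Priors are flat for fixed effects and weakly informative proper
#' inverse-Wisharts (identity scale, dimension + 1 degrees of freedom)
#' for the herd, permanent-environment and sire covariance matrices and
#' the production residual block; the liability residual (when
#' estimated) gets a scaled-inverse-chi-square with `nu_e = 1`,
#' `s2_e = 1`.
#'
#' @param n_iter,burn_in,thin Chain length, burn-in and thinning.
#' @param seed Master seed; every random draw in the run derives from it.
#' @param prior_df3,prior_scale3 Inverse-Wishart prior for the 3x3 herd,
#'   permanent-environment and sire covariance matrices.
#' @param prior_df2,prior_scale2 Inverse-Wishart prior for the 2x2
#'   production residual block.
#' @param nu_e,s2_e Scaled-inverse-chi-square prior for the liability
#'   residual variance (4-category scheme only).
#' @return A list of class `thl_control`.
#' @export
thl_control <- function(n_iter = 300000, burn_in = 50000, thin = 50,
                        seed = 1L,
                        prior_df3 = 4, prior_scale3 = diag(3),
                        prior_df2 = 3, prior_scale2 = diag(2),
                        nu_e = 1, s2_e = 1) {
  stopifnot(n_iter > burn_in, thin >= 1, burn_in >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df3 = prior_df3, prior_scale3 = prior_scale3,
                 prior_df2 = prior_df2, prior_scale2 = prior_scale2,
                 nu_e = nu_e, s2_e = s2_e),
            class = "thl_control")
}

#' Number of stored samples implied by chain settings
#'
#' @param control A [thl_control()] object (or `n_iter` given directly).
#' @param burn_in,thin Used when `control` is numeric.
#' @return Tibble with `n_iter`, `burn_in`, `thin`, `n_stored`.
#' @examples
#' chain_plan(thl_control()) # 5,000 stored samples
#' @export
chain_plan <- function(control, burn_in = NULL, thin = NULL) {
  if (is.numeric(control))
    control <- thl_control(n_iter = control, burn_in = burn_in, thin = thin)
  n_stored <- length(seq.int(control$burn_in + 1L, control$n_iter,
                             by = control$thin))
  tibble::tibble(n_iter = control$n_iter, burn_in = control$burn_in,
                 thin = control$thin, n_stored = n_stored)
}

trait_labels <- function(trait) c(trait, "MY", "SCS")

# draw column names, matching the C++ storage layout
draw_names <- function(trait, K, n_ps, store_effects) {
  tl <- trait_labels(trait)
  vech <- function(M) {
    idx <- rbind(c(1, 1), c(2, 1), c(3, 1), c(2, 2), c(3, 2), c(3, 3))
    paste0(M, "[", tl[idx[, 1]], ",", tl[idx[, 2]], "]")
  }
  nm <- c(vech("S"), vech("P"), vech("H"),
          "R[MY,MY]", "R[SCS,MY]", "R[SCS,SCS]",
          paste0("R[", trait, ",", trait, "]"))
  if (K == 4) nm <- c(nm, "t3")
  if (store_effects)
    nm <- c(nm,
            paste0("b[", trait, ",ps", seq_len(n_ps), "]"),
            paste0("b[", trait, ",hyg", 2:4, "]"),
            paste0("b[", trait, ",qtr", 2:4, "]"),
            paste0("b[MY,ps", seq_len(n_ps), "]"),
            paste0("b[SCS,ps", seq_len(n_ps), "]"))
  nm
}

# rank check on the teat fixed-effect design (detects confounded /
# duplicate-coded levels among parity-stage, hygiene and quarter)
check_teat_design <- function(df) {
  if (!nrow(df)) return(invisible(TRUE))
  combos <- dplyr::distinct(df, .data$ps_class, .data$hygiene, .data$quarter)
  fac <- lapply(combos, function(x) factor(x))
  keep <- vapply(fac, function(f) nlevels(f) > 1L, logical(1))
  if (!any(keep)) return(invisible(TRUE))
  X <- stats::model.matrix(~., data = as.data.frame(fac[keep]))
  r <- qr(X)$rank
  if (r < ncol(X))
    stop("teat fixed-effect design is rank deficient (confounded levels ",
         "among parity-stage, hygiene and quarter)")
  invisible(TRUE)
}

#' Fit the tri-variate threshold-linear sire model by Gibbs sampling
#'
#' Fits the joint model of one teat trait (on the liability scale), milk
#' yield and somatic cell score to a stacked dataset.  Fixed effects:
#' parity-by-stage class (all traits), hygiene and quarter (teat trait
#' only).  Random effects: herd, cow permanent environment and sire (with
#' numerator-relationship covariance `A (x) S`), each a full 3x3
#' covariance matrix.  The residual covariance between the teat and
#' production blocks is structurally zero; the production block is a free
#' 2x2 matrix.
#'
#' Identifiability on the liability scale: binary traits (`TSa`, `TSb`)
#' fix the threshold at 0 and the liability residual variance at 1; the
#' 4-category trait (`TS`) pins the first two thresholds at 0 and 1 and
#' estimates the liability residual variance (the third threshold is
#' sampled).  The scheme can be overridden via `liability_residual`.
#'
#' @param data Stacked dataset from [stack_records()] (or
#'   [simulate_study()] + [stack_records()]).
#' @param pedigree Pedigree data frame covering all sires in `data`.
#' @param trait `"TS"` (4-category), `"TSa"` or `"TSb"` (binary
#'   collapses of the stored 4-class score).
#' @param control Chain settings, see [thl_control()].
#' @param liability_residual `"estimate"` or `"fix"`; default follows
#'   the trait (`"estimate"` for TS, `"fix"` for binary traits).
#' @param sire_A `"full"` (A built on the full pedigree, sire block
#'   extracted) or `"sires_only"` (dam links discarded).
#' @param fix_covariances Optional list with elements `H`, `P`, `S`
#'   (3x3), `Rprod` (2x2) and `r11`; when supplied the covariance
#'   matrices are held fixed at these values and only location
#'   parameters and liabilities are sampled.
#' @param start_covariances Optional list like `fix_covariances` used
#'   only as starting values; covariances are still sampled.
#' @param store_effects Keep draws of the fixed-effect solutions
#'   (needed for least-squares means).
#' @param verbose Print progress every 10,000 iterations.
#' @return An object of class `thl_fit`: list with `draws` (tibble, one
#'   row per stored sample), `trait`, `K`, `control`, level dictionaries,
#'   design frequencies and run metadata.
#' @export
fit_thl <- function(data, pedigree, trait = c("TS", "TSa", "TSb"),
                    control = thl_control(),
                    liability_residual = NULL,
                    sire_A = c("full", "sires_only"),
                    fix_covariances = NULL, start_covariances = NULL,
                    store_effects = TRUE, verbose = FALSE) {
  trait <- match.arg(trait)
  sire_A <- match.arg(sire_A)
  stopifnot(inherits(control, "thl_control"))
  data <- tibble::as_tibble(data)
  need <- c("block", "cow", "herd", "sire", "ps_class", "hygiene",
            "quarter", "ts", "my", "scs")
  if (length(miss <- setdiff(need, names(data))))
    stop("stacked data lack columns: ", paste(miss, collapse = ", "))

  # canonical row order: results do not depend on the input ordering
  data <- dplyr::arrange(data, .data$block, .data$cow, .data$herd,
                         .data$ps_class, .data$quarter, .data$my, .data$scs)

  is_teat <- data$block == "teat"
  K <- if (trait == "TS") 4L else 2L
  cat <- rep(0L, nrow(data))
  if (any(is_teat)) {
    ts <- data$ts[is_teat]
    cat[is_teat] <- if (trait == "TS") as.integer(ts)
      else collapse_ts(ts, scheme = if (trait == "TSa") "a" else "b") + 1L
    present <- tabulate(cat[is_teat], nbins = K)
    if (any(present == 0L))
      stop("teat category ", which(present == 0L)[1], " of trait ", trait,
           " has no observations; consider collapsing classes")
    check_teat_design(data[is_teat, ])
  }

  if (is.null(liability_residual))
    liability_residual <- if (K == 4L) "estimate" else "fix"
  liability_residual <- match.arg(liability_residual, c("estimate", "fix"))

  pattern <- ifelse(is_teat, 0L,
                    ifelse(is.na(data$scs), 2L,
                           ifelse(is.na(data$my), 3L, 1L)))
  ymat <- cbind(0, ifelse(is.na(data$my), 0, data$my),
                ifelse(is.na(data$scs), 0, data$scs))

  herd_lev <- sort(unique(data$herd))
  cow_lev <- sort(unique(data$cow))
  sire_lev <- sort(unique(data$sire))
  n_ps <- 36L
  if (any(data$ps_class < 1 | data$ps_class > n_ps))
    stop("ps_class must lie in 1..36")

  rel <- sire_relationship(pedigree, sire_lev, scheme = sire_A)

  qtr_idx <- match(data$quarter, quarter_levels())
  start <- list(H = diag(3), P = diag(3), S = diag(3),
                Rprod = diag(2), r11 = 1)
  fix_cov <- !is.null(fix_covariances)
  if (fix_cov) {
    for (nm in c("H", "P", "S", "Rprod", "r11")) {
      if (is.null(fix_covariances[[nm]]))
        stop("fix_covariances needs element ", nm)
      start[[nm]] <- fix_covariances[[nm]]
    }
  } else if (!is.null(start_covariances)) {
    for (nm in intersect(names(start_covariances), names(start)))
      start[[nm]] <- start_covariances[[nm]]
  }
  thr <- if (K == 4L && !any(is_teat)) {
    c(-Inf, 0, 1, 2, Inf)
  } else if (K == 4L) {
    # start the free threshold at its empirical probit position, mapped
    # through the pinned (t1, t2) = (0, 1) scale
    cum <- cumsum(tabulate(cat[is_teat], nbins = 4L)) / sum(is_teat)
    z <- qnorm(pmin(pmax(cum[1:3], 1e-4), 1 - 1e-4))
    t3 <- if (z[2] > z[1]) (z[3] - z[1]) / (z[2] - z[1]) else 2
    c(-Inf, 0, 1, max(t3, 1.5), Inf)
  } else c(-Inf, 0, Inf)
  prior <- list(df3 = control$prior_df3, scale3 = control$prior_scale3,
                df2 = control$prior_df2, scale2 = control$prior_scale2,
                nu_e = control$nu_e, s2_e = control$s2_e)

  set.seed(control$seed)
  t0 <- Sys.time()
  res <- gibbs_thl_cpp(pattern, ymat, cat,
                       match(data$herd, herd_lev) - 1L,
                       match(data$cow, cow_lev) - 1L,
                       match(data$sire, sire_lev) - 1L,
                       as.integer(data$ps_class) - 1L,
                       ifelse(is.na(data$hygiene), -1L,
                              as.integer(data$hygiene) - 1L),
                       ifelse(is.na(qtr_idx), -1L, qtr_idx - 1L),
                       length(herd_lev), length(cow_lev), length(sire_lev),
                       n_ps, rel$Ainv, K, thr,
                       control$n_iter, control$burn_in, control$thin,
                       prior, start, fix_cov,
                       liability_residual == "estimate" && !fix_cov,
                       store_effects, verbose)
  draws <- tibble::as_tibble(as.data.frame(res$draws), .name_repair = "minimal")
  names(draws) <- draw_names(trait, K, n_ps, store_effects)
  draws <- dplyr::bind_cols(tibble::tibble(.iteration = seq_len(nrow(draws))),
                            draws)

  teat_df <- data[is_teat, ]
  design_freq <- if (nrow(teat_df)) list(
    ps = prop.table(table(factor(teat_df$ps_class, levels = 1:n_ps))),
    hygiene = prop.table(table(factor(teat_df$hygiene, levels = 1:4))),
    quarter = prop.table(table(factor(teat_df$quarter,
                                      levels = quarter_levels())))
  ) else NULL

  structure(list(
    draws = draws, trait = trait, K = K,
    liability_residual = if (fix_cov) "fixed_covariances" else liability_residual,
    control = control, sire_A = sire_A, fix_covariances = fix_cov,
    levels = list(herd = herd_lev, cow = cow_lev, sire = sire_lev),
    counts = c(n_rows = nrow(data), n_teat = res$n_teat,
               n_prod = res$n_prod, n_stored = res$n_stored),
    design_freq = design_freq,
    pinned_thresholds = if (K == 4L) c(t1 = 0, t2 = 1) else c(t1 = 0),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "thl_fit")
}

#' @export
print.thl_fit <- function(x, ...) {
  cat("Threshold-linear sire model fit (teat trait:", x$trait, ")\n")
  cat(sprintf("  records: %d (%d teat, %d production)\n",
              x$counts["n_rows"], x$counts["n_teat"], x$counts["n_prod"]))
  cat(sprintf("  levels: %d herds, %d cows, %d sires\n",
              length(x$levels$herd), length(x$levels$cow),
              length(x$levels$sire)))
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d -> %d stored\n",
              x$control$n_iter, x$control$burn_in, x$control$thin,
              x$counts["n_stored"]))
  cat("  liability scheme:", x$liability_residual, "\n")
  invisible(x)
}

#' Truncated-normal random draws
#'
#' Inverse-CDF sampling with an exponential-rejection fallback for deep
#' tails; the same routine the Gibbs sampler uses for liability
#' augmentation.  Draws use R's RNG, so `set.seed()` applies.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale (recycled).
#' @param lower,upper Truncation bounds (may be infinite; recycled).
#' @return Numeric vector of length `n`.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(all(sd > 0), all(lower < upper))
  rtnorm_cpp(as.integer(n), as.numeric(mean), as.numeric(sd),
             as.numeric(lower), as.numeric(upper))
}
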