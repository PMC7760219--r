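#' Genetic-parameter functionals of the sire model
#'
#' Sire-model definitions: heritability `4 * sigma_s^2 / (sigma_s^2 +
#' sigma_p^2 + sigma_h^2 + sigma_e^2)`; intra-herd heritability drops the
#' herd term from the denominator; cow repeatability `sigma_p^2 /
#' (sigma_s^2 + sigma_p^2 + sigma_h^2 + sigma_e^2)` (the genetic effect
#' is not counted as a source of cow repeatability); herd repeatability
#' `sigma_h^2 / (same denominator)`.  All are vectorized so they can be
#' applied per stored draw.
#'
#' @param sigma_s2,sigma_p2,sigma_h2,sigma_e2 Sire, cow
#'   permanent-environment, herd and residual variances (>= 0).
#' @return Numeric vector.
#' @examples
#' heritability(0.438, 3.998, 1.648, 1.281) # 0.238
#' @export
heritability <- function(sigma_s2, sigma_p2, sigma_h2, sigma_e2) {
  den <- sigma_s2 + sigma_p2 + sigma_h2 + sigma_e2
  check_varcomp(sigma_s2, sigma_p2, sigma_h2, sigma_e2, den = den)
  4 * sigma_s2 / den
}

#' @rdname heritability
#' @export
intra_herd_heritability <- function(sigma_s2, sigma_p2, sigma_e2) {
  den <- sigma_s2 + sigma_p2 + sigma_e2
  check_varcomp(sigma_s2, sigma_p2, sigma_e2, den = den)
  4 * sigma_s2 / den
}

#' @rdname heritability
#' @export
cow_repeatability <- function(sigma_p2, sigma_s2, sigma_h2, sigma_e2) {
  den <- sigma_s2 + sigma_p2 + sigma_h2 + sigma_e2
  check_varcomp(sigma_s2, sigma_p2, sigma_h2, sigma_e2, den = den)
  sigma_p2 / den
}

#' @rdname heritability
#' @export
herd_repeatability <- function(sigma_h2, sigma_s2, sigma_p2, sigma_e2) {
  den <- sigma_s2 + sigma_p2 + sigma_h2 + sigma_e2
  check_varcomp(sigma_s2, sigma_p2, sigma_h2, sigma_e2, den = den)
  sigma_h2 / den
}

check_varcomp <- function(..., den) {
  args <- list(...)
  if (any(unlist(args) < 0, na.rm = TRUE)) stop("variances must be >= 0")
  if (any(den <= 0, na.rm = TRUE)) stop("zero denominator")
  invisible(TRUE)
}

#' Correlation from a covariance and two variances
#'
#' @param cov Covariance.
#' @param var1,var2 Variances (> 0).
#' @return `cov / sqrt(var1 * var2)`.
#' @export
correlation <- function(cov, var1, var2) {
  if (any(var1 <= 0 | var2 <= 0, na.rm = TRUE))
    stop("variances must be > 0")
  cov / sqrt(var1 * var2)
}

#' Highest-posterior-density interval
#'
#' The shortest interval containing `ceiling(level * n)` of the sorted
#' samples.
#'
#' @param samples Numeric vector of posterior draws.
#' @param level Probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0) stop("no finite samples")
  m <- min(n, max(1L, ceiling(level * n)))
  if (m == n) return(c(lower = x[1], upper = x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first 10% of a chain with the mean
#' of the last 50%, with spectral-density variance estimates (delegated
#' to \pkg{coda}).  Returns `NA` with a warning for a constant chain.
#'
#' @param samples Numeric vector of draws in chain order.
#' @param frac1,frac2 Fractions of the chain compared.
#' @return Z-score (standard normal under convergence).
#' @export
geweke_z <- function(samples, frac1 = 0.1, frac2 = 0.5) {
  if (stats::sd(samples) < 1e-12) {
    warning("constant chain: Geweke diagnostic undefined")
    return(NA_real_)
  }
  z <- tryCatch(
    unname(coda::geweke.diag(coda::mcmc(samples),
                             frac1 = frac1, frac2 = frac2)$z),
    error = function(e) NA_real_)
  z
}

# pull a draw column by name, erroring helpfully
draw_col <- function(fit, nm) {
  if (!nm %in% names(fit$draws)) stop("no stored draws for ", nm)
  fit$draws[[nm]]
}

summarize_draws <- function(x, level = 0.95) {
  h <- hpd_interval(x, level)
  tibble::tibble(estimate = mean(x), conf.low = h[["lower"]],
                 conf.high = h[["upper"]],
                 geweke_z = suppressWarnings(geweke_z(x)))
}

#' Posterior genetic parameters of a fitted model
#'
#' Computes, at every stored draw, the variance components, heritability,
#' intra-herd heritability, cow and herd repeatability for each trait and
#' the genetic, permanent-environment and herd correlations between the
#' teat trait and the production traits, then summarizes each as
#' posterior mean, 95% HPD interval and Geweke z.  Because a ratio of
#' means differs from the mean of per-draw ratios, the functional of the
#' posterior-mean variance components is also reported
#' (`estimate_at_means`).
#'
#' @param fit A [fit_thl()] object.
#' @param level HPD probability mass.
#' @return A tibble: `parameter`, `trait`, `estimate` (posterior mean of
#'   the per-draw functional), `conf.low`, `conf.high`, `geweke_z`,
#'   `estimate_at_means`.
#' @export
genetic_parameters <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "thl_fit"))
  tl <- trait_labels(fit$trait)
  res_col <- c(paste0("R[", fit$trait, ",", fit$trait, "]"),
               "R[MY,MY]", "R[SCS,SCS]")
  per_trait <- function(t_idx) {
    t <- tl[t_idx]
    s2 <- draw_col(fit, paste0("S[", t, ",", t, "]"))
    p2 <- draw_col(fit, paste0("P[", t, ",", t, "]"))
    h2v <- draw_col(fit, paste0("H[", t, ",", t, "]"))
    e2 <- draw_col(fit, res_col[t_idx])
    funs <- list(
      sire_variance = s2, pe_variance = p2, herd_variance = h2v,
      residual_variance = e2,
      heritability = heritability(s2, p2, h2v, e2),
      intra_herd_heritability = intra_herd_heritability(s2, p2, e2),
      cow_repeatability = cow_repeatability(p2, s2, h2v, e2),
      herd_repeatability = herd_repeatability(h2v, s2, p2, e2))
    purrr::imap_dfr(funs, function(x, nm) {
      s <- summarize_draws(x, level)
      means <- switch(nm,
        heritability = heritability(mean(s2), mean(p2), mean(h2v), mean(e2)),
        intra_herd_heritability =
          intra_herd_heritability(mean(s2), mean(p2), mean(e2)),
        cow_repeatability = cow_repeatability(mean(p2), mean(s2),
                                              mean(h2v), mean(e2)),
        herd_repeatability = herd_repeatability(mean(h2v), mean(s2),
                                                mean(p2), mean(e2)),
        mean(x))
      dplyr::bind_cols(tibble::tibble(parameter = nm, trait = t), s,
                       tibble::tibble(estimate_at_means = means))
    })
  }
  pair_cor <- function(M, t1, t2, label) {
    # covariance column stores the lower-triangle element
    cv <- draw_col(fit, paste0(M, "[", t2, ",", t1, "]"))
    v1 <- draw_col(fit, paste0(M, "[", t1, ",", t1, "]"))
    v2 <- draw_col(fit, paste0(M, "[", t2, ",", t2, "]"))
    r <- correlation(cv, v1, v2)
    s <- summarize_draws(r, level)
    dplyr::bind_cols(
      tibble::tibble(parameter = label, trait = paste0(t1, ":", t2)), s,
      tibble::tibble(estimate_at_means =
                       correlation(mean(cv), mean(v1), mean(v2))))
  }
  cors <- purrr::map_dfr(list(c("S", "genetic_correlation"),
                              c("P", "pe_correlation"),
                              c("H", "herd_correlation")), function(mc) {
    dplyr::bind_rows(pair_cor(mc[1], tl[1], "MY", mc[2]),
                     pair_cor(mc[1], tl[1], "SCS", mc[2]),
                     pair_cor(mc[1], "MY", "SCS", mc[2]))
  })
  resid_cor <- pair_cor("R", "MY", "SCS", "residual_correlation")
  dplyr::bind_rows(purrr::map_dfr(1:3, per_trait), cors, resid_cor)
}

#' Least-squares means on the probability scale
#'
#' For each level of a teat-trait fixed effect, the liability-scale
#' least-squares mean `eta` is formed at every stored draw (non-focal
#' fixed effects averaged with observed-frequency weights, or equal
#' weights) and transformed to the probability of exceeding a score
#' threshold: `P = 1 - Phi((t - eta) / sigma_e)`.  For the binary traits
#' the threshold is 0 (probability of the affected class); for the
#' 4-category trait `above` selects which cut is used (1: `P(TS > 1)`,
#' 2: `P(TS > 2)`, 3: `P(TS > 3)`).
#'
#' @param fit A [fit_thl()] object fitted with `store_effects = TRUE`.
#' @param effect `"quarter"`, `"hygiene"` or `"parity_stage"`.
#' @param above Score cut for the 4-category trait (ignored for binary).
#' @param weights `"observed"` class-frequency weights or `"equal"`.
#' @param level HPD mass.
#' @return Tibble: `level`, `estimate`, `conf.low`, `conf.high`.
#' @export
lsm_probability <- function(fit, effect = c("quarter", "hygiene",
                                            "parity_stage"),
                            above = 1, weights = c("observed", "equal"),
                            level = 0.95) {
  stopifnot(inherits(fit, "thl_fit"))
  effect <- match.arg(effect)
  weights <- match.arg(weights)
  if (is.null(fit$design_freq))
    stop("fit has no teat block or was run with store_effects = FALSE")
  tr <- fit$trait
  nd <- nrow(fit$draws)

  eff_draws <- function(which) {
    # matrix draws x levels, reference level = 0 for hygiene/quarter
    switch(which,
      ps = sapply(1:36, function(k)
        draw_col(fit, paste0("b[", tr, ",ps", k, "]"))),
      hygiene = cbind(0, sapply(2:4, function(k)
        draw_col(fit, paste0("b[", tr, ",hyg", k, "]")))),
      quarter = cbind(0, sapply(2:4, function(k)
        draw_col(fit, paste0("b[", tr, ",qtr", k, "]")))))
  }
  wts <- function(which) {
    w <- as.numeric(fit$design_freq[[switch(which, ps = "ps",
                                            hygiene = "hygiene",
                                            quarter = "quarter")]])
    if (weights == "equal") {
      pos <- w > 0 # equal weights over levels that occur at all
      w <- ifelse(pos, 1 / sum(pos), 0)
    }
    w
  }
  parts <- list(ps = eff_draws("ps") %*% wts("ps"),
                hygiene = eff_draws("hygiene") %*% wts("hygiene"),
                quarter = eff_draws("quarter") %*% wts("quarter"))
  focal <- switch(effect, quarter = "quarter", hygiene = "hygiene",
                  parity_stage = "ps")
  base <- rowSums(do.call(cbind, parts[setdiff(names(parts), focal)]))
  focal_mat <- eff_draws(focal)
  lev_names <- switch(focal, ps = as.character(1:36),
                      hygiene = as.character(1:4), quarter = quarter_levels())
  occurs <- as.numeric(fit$design_freq[[focal]]) > 0

  if (fit$K == 2L) {
    thr <- rep(0, nd)
  } else {
    stopifnot(above %in% 1:3)
    thr <- switch(above, rep(0, nd), rep(1, nd), draw_col(fit, "t3"))
  }
  sd_e <- sqrt(draw_col(fit, paste0("R[", tr, ",", tr, "]")))

  purrr::map_dfr(which(occurs), function(j) {
    eta <- base + focal_mat[, j]
    p <- 1 - pnorm((thr - eta) / sd_e)
    h <- hpd_interval(p, level)
    tibble::tibble(level = lev_names[j], estimate = mean(p),
                   conf.low = h[["lower"]], conf.high = h[["upper"]])
  })
}

#' @method tidy thl_fit
#' @export
tidy.thl_fit <- function(x, parameters = NULL, level = 0.95, ...) {
  nms <- setdiff(names(x$draws), ".iteration")
  if (!is.null(parameters)) nms <- intersect(nms, parameters)
  purrr::map_dfr(nms, function(nm) {
    dplyr::bind_cols(tibble::tibble(term = nm),
                     summarize_draws(x$draws[[nm]], level))
  })
}

#' @method glance thl_fit
#' @export
glance.thl_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_rows = unname(x$counts["n_rows"]),
                 n_teat = unname(x$counts["n_teat"]),
                 n_prod = unname(x$counts["n_prod"]),
                 n_herds = length(x$levels$herd),
                 n_cows = length(x$levels$cow),
                 n_sires = length(x$levels$sire),
                 n_iter = x$control$n_iter, burn_in = x$control$burn_in,
                 thin = x$control$thin,
                 n_stored = unname(x$counts["n_stored"]),
                 runtime_s = x$runtime_s)
}

#' Trace / density plot of stored draws
#'
#' @param object A `thl_fit`.
#' @param parameters Character vector of draw columns (default: the
#'   variance components of the teat trait).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thl_fit
#' @export
autoplot.thl_fit <- function(object, parameters = NULL, ...) {
  tr <- object$trait
  if (is.null(parameters))
    parameters <- c(paste0("S[", tr, ",", tr, "]"),
                    paste0("P[", tr, ",", tr, "]"),
                    paste0("H[", tr, ",", tr, "]"),
                    paste0("R[", tr, ",", tr, "]"))
  df <- object$draws |>
    dplyr::select(".iteration", dplyr::all_of(parameters)) |>
    tidyr::pivot_longer(-".iteration", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(.data$.iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stored iteration", y = "draw") +
    ggplot2::theme_minimal()
}
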