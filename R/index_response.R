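#' Assemble the sire genetic (co)variance matrix for (teat, MY, SCS)
#'
#' Builds the 3x3 matrix G from the three sire variances and the three
#' genetic correlations, `cov_ij = r_ij * sigma_i * sigma_j`, and checks
#' positive definiteness via the leading principal minors.
#'
#' @param var_teat,var_my,var_scs Sire variances (> 0).
#' @param r_teat_my,r_teat_scs Genetic correlations of the teat trait
#'   with MY and SCS.
#' @param r_my_scs Genetic correlation between MY and SCS (not printed
#'   in study tables; the correlated-response break-even is insensitive
#'   to it).
#' @param check_pd Require the full 3x3 matrix to be positive definite.
#'   Disable for sensitivity sweeps over `r_my_scs`: an index with zero
#'   teat weight only requires the MY-SCS block to be PD, and strongly
#'   negative `r_my_scs` values can violate full-G positive definiteness
#'   while leaving every computed response well defined.
#' @return A 3x3 symmetric matrix with dimnames `teat`, `MY`, `SCS`.
#' @examples
#' assemble_G(0.438, 0.958, 0.148, 0.86, 0.44)
#' @export
assemble_G <- function(var_teat, var_my, var_scs,
                       r_teat_my, r_teat_scs, r_my_scs = 0.1,
                       check_pd = TRUE) {
  v <- c(var_teat, var_my, var_scs)
  if (any(v <= 0)) stop("variances must be > 0")
  r <- c(r_teat_my, r_teat_scs, r_my_scs)
  if (any(abs(r) > 1))
    stop("correlations must lie in [-1, 1]; got ",
         paste(r[abs(r) > 1], collapse = ", "))
  sd <- sqrt(v)
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- r_teat_my
  C[1, 3] <- C[3, 1] <- r_teat_scs
  C[2, 3] <- C[3, 2] <- r_my_scs
  G <- C * tcrossprod(sd)
  kmax <- if (check_pd) 3 else 2
  for (k in seq_len(kmax)) {
    if (det(G[1:k, 1:k, drop = FALSE]) <= 0)
      stop("G is not positive definite: leading principal minor of order ",
           k, " is non-positive")
  }
  dimnames(G) <- list(c("teat", "MY", "SCS"), c("teat", "MY", "SCS"))
  G
}

#' Expected correlated genetic response of the teat trait under an index
#'
#' For index weights `w` applied to the sire breeding values of
#' (teat, MY, SCS), the correlated response of the teat trait per unit of
#' selection is `r = w' g1 / sqrt(w' G w)` with `g1` the first column of
#' G, expressed in sire genetic standard deviations of the teat trait
#' (division by `sqrt(G[1,1])`, or by twice that under
#' `genetic_sd = "additive"`).  `normalization = "gv"` divides by
#' `w' G w` instead of its square root (the typographically ambiguous
#' alternative reading of the response formula).
#'
#' @param w Numeric weight vector of length 3 (teat weight normally 0).
#' @param G Matrix from [assemble_G()].
#' @param normalization `"sd_units"` (default) or `"gv"`.
#' @param genetic_sd `"sire"` (default) or `"additive"` (2 x sire SD).
#' @return Scalar response.
#' @export
index_response <- function(w, G, normalization = c("sd_units", "gv"),
                           genetic_sd = c("sire", "additive")) {
  normalization <- match.arg(normalization)
  genetic_sd <- match.arg(genetic_sd)
  stopifnot(length(w) == 3, all(dim(G) == c(3, 3)))
  wGw <- drop(crossprod(w, G %*% w))
  if (wGw <= 0) stop("index has zero variance (w' G w <= 0)")
  num <- drop(crossprod(w, G[, 1]))
  sd1 <- sqrt(G[1, 1]) * if (genetic_sd == "additive") 2 else 1
  if (normalization == "sd_units") num / sqrt(wGw) / sd1 else num / wGw
}

#' Sweep the relative emphasis from milk yield to somatic cell score
#'
#' Emphasis `e` percent on MY (positive weight) leaves `100 - e` percent
#' on SCS with negative weight: `w = (0, e/100, -(1 - e/100))` on the
#' raw-covariance scale.  The sweep runs `e = 0..100` in 1% steps and
#' reports the correlated teat-trait response at each point plus the
#' break-even emphasis (smallest grid `e` with positive response).
#'
#' @param G Matrix from [assemble_G()].
#' @param grid Integer emphasis grid (default `0:100`).
#' @inheritParams index_response
#' @return Tibble `emphasis`, `response`, with attribute `breakeven`.
#' @export
emphasis_sweep <- function(G, grid = 0:100,
                           normalization = c("sd_units", "gv"),
                           genetic_sd = c("sire", "additive")) {
  normalization <- match.arg(normalization)
  genetic_sd <- match.arg(genetic_sd)
  resp <- vapply(grid, function(e) {
    w <- c(0, e / 100, -(1 - e / 100))
    index_response(w, G, normalization, genetic_sd)
  }, numeric(1))
  out <- tibble::tibble(emphasis = as.numeric(grid), response = resp)
  pos <- which(resp > 0)
  attr(out, "breakeven") <- if (length(pos)) as.numeric(grid[min(pos)])
                            else NA_real_
  out
}

#' Break-even emphasis in closed form
#'
#' The response numerator `e/100 * cov(teat, MY) - (1 - e/100) *
#' cov(teat, SCS)` changes sign at `e* = 100 * rho / (1 + rho)` with
#' `rho = cov(teat, SCS) / cov(teat, MY)`; on the 1% grid the break-even
#' is the smallest integer emphasis with a strictly positive numerator.
#' The value does not depend on the MY-SCS genetic covariance nor on the
#' normalization of the response.
#'
#' @param G Matrix from [assemble_G()].
#' @return Tibble with `breakeven_exact` (continuous `e*`) and
#'   `breakeven_grid` (smallest integer emphasis with positive response).
#' @export
breakeven_emphasis <- function(G) {
  cov_my <- G[2, 1]
  cov_scs <- G[3, 1]
  if (cov_my <= 0)
    stop("break-even undefined: cov(teat, MY) must be positive")
  rho <- cov_scs / cov_my
  estar <- max(0, 100 * rho / (1 + rho))
  # numerator is strictly positive from the next grid point past e*
  grid <- if (cov_scs < 0) 0 else floor(estar) + 1
  tibble::tibble(breakeven_exact = estar, breakeven_grid = grid)
}

#' Plot an emphasis-response curve
#'
#' @param object Output of [emphasis_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_emphasis_sweep <- function(object, ...) {
  be <- attr(object, "breakeven")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$emphasis, .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative emphasis on MY (%)",
                  y = "correlated response (sire genetic SD)") +
    ggplot2::theme_minimal()
  if (!is.na(be))
    p <- p + ggplot2::geom_vline(xintercept = be, linetype = 3)
  p
}
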