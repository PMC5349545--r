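## Reference trajectory: the curve traced in the plane of two normalized
## responses by the full agonist's CR curves. Closed form from the two
## 2-parameter logistic fits (parameters c, b and c', b'):
##   Y'(Y) = 1 / (1 + (c'/c)^b' ((1-Y)/Y)^(b'/b))
## It is the locus on which every unbiased ligand's intrinsic-activity pair
## must lie, whatever monotone amplification each pathway applies.

#' Build the reference trajectory linking two assays
#'
#' Fits a 2-parameter logistic to the (normalized) reference-agonist curve in
#' each assay and eliminates the concentration between the two fits, giving
#' the closed-form curve `Y' (assay B fraction)` as a function of
#' `Y (assay A fraction)`. The trajectory is strictly increasing from (0,0)
#' to (1,1). Asymptotic uncertainty of the two regressions is propagated by
#' the delta method into pointwise standard errors of the trajectory along
#' each axis.
#'
#' @param ref_curve_a,ref_curve_b [cr_curve]s of the same reference ligand in
#'   the two assays, normalized so their plateaus are about 1.
#' @param weights Passed to [fit_logistic2].
#' @return An object of class `reference_trajectory` with elements `fit_a`,
#'   `fit_b`, `fun(Y)` (the closed form), `inv(Yp)` (its inverse), and
#'   `se_y(Y)`, `se_x(Yp)` (delta-method SEs of the trajectory ordinate /
#'   abscissa).
#' @export
build_trajectory <- function(ref_curve_a, ref_curve_b, weights = "none") {
  stopifnot(inherits(ref_curve_a, "cr_curve"), inherits(ref_curve_b, "cr_curve"))
  if (ref_curve_a$ligand != ref_curve_b$ligand)
    stop("the two curves must belong to the same (reference) ligand")
  fit_a <- fit_logistic2(ref_curve_a, weights = weights)
  fit_b <- fit_logistic2(ref_curve_b, weights = weights)
  traj_closure(fit_a, fit_b)
}

traj_closure <- function(fit_a, fit_b) {
  lc <- fit_a$par[["ln_c"]]; b <- fit_a$par[["slope_b"]]
  lcp <- fit_b$par[["ln_c"]]; bp <- fit_b$par[["slope_b"]]
  # ln K(Y) = b'(ln c' - ln c) + (b'/b) ln((1-Y)/Y);  Y' = 1/(1+K)
  lnK <- function(y) bp * (lcp - lc) + (bp / b) * log((1 - y) / y)
  fun <- function(y) 1 / (1 + exp(lnK(y)))
  lnKi <- function(yp) b * (lc - lcp) + (b / bp) * log((1 - yp) / yp)
  inv <- function(yp) 1 / (1 + exp(lnKi(yp)))
  # delta method on (ln c, b) and (ln c', b'), independent fits
  var_lnK <- function(y) {
    g <- log((1 - y) / y)
    # d lnK / d(ln c) = -b' ; d lnK / d b = -b' g / b^2
    ga <- rbind(rep(-bp, length(y)), -bp * g / b^2)
    va <- colSums((fit_a$cov %*% ga) * ga)
    # d lnK / d(ln c') = b' ; d lnK / d b' = (ln c' - ln c) + g/b
    gbm <- rbind(rep(bp, length(y)), (lcp - lc) + g / b)
    vb <- colSums((fit_b$cov %*% gbm) * gbm)
    va + vb
  }
  se_y <- function(y) {
    yp <- fun(y)
    yp * (1 - yp) * sqrt(pmax(var_lnK(y), 0))
  }
  var_lnKi <- function(yp) {
    g <- log((1 - yp) / yp)
    gam <- rbind(rep(b, length(yp)), (lc - lcp) + g / bp)
    va <- colSums((fit_a$cov %*% gam) * gam)
    gbm <- rbind(rep(-b, length(yp)), -b * g / bp^2)
    vb <- colSums((fit_b$cov %*% gbm) * gbm)
    va + vb
  }
  se_x <- function(yp) {
    y <- inv(yp)
    y * (1 - y) * sqrt(pmax(var_lnKi(yp), 0))
  }
  structure(list(fit_a = fit_a, fit_b = fit_b, fun = fun, inv = inv,
                 se_y = se_y, se_x = se_x),
            class = "reference_trajectory")
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf(
    "<reference_trajectory> '%s': assay '%s' (c=%.3g M, b=%.3g) vs assay '%s' (c'=%.3g M, b'=%.3g)\n",
    x$fit_a$ligand, x$fit_a$assay, exp(x$fit_a$par[["ln_c"]]),
    x$fit_a$par[["slope_b"]], x$fit_b$assay, exp(x$fit_b$par[["ln_c"]]),
    x$fit_b$par[["slope_b"]]))
  invisible(x)
}

#' Project an observed intrinsic-activity pair onto the trajectory
#'
#' Finds the point on the reference trajectory nearest to the observed pair
#' under the anisotropic metric that weights displacement along each axis by
#' the inverse variance of the experimental error:
#' `d^2(Y) = (Y - ia_a)^2/sd_a^2 + (Y'(Y) - ia_b)^2/sd_b^2`,
#' minimized by bounded one-dimensional search (coarse grid + local
#' refinement).
#'
#' @param ia_a,ia_b Observed intrinsic activities in the two assays.
#' @param sd_a,sd_b Their standard deviations; both must be `> 0`.
#' @param traj A `reference_trajectory`.
#' @return List with `x`, `y` (projected point on the trajectory),
#'   `distance` (minimized metric, in SD units), and `y_par` (= `x`, the
#'   trajectory parameter).
#' @export
project_point <- function(ia_a, ia_b, sd_a, sd_b, traj) {
  if (!is.finite(sd_a) || !is.finite(sd_b) || sd_a <= 0 || sd_b <= 0)
    stop("projection requires positive uncertainties on both axes; supply ia_sd > 0")
  d2 <- function(y) (y - ia_a)^2 / sd_a^2 + (traj$fun(y) - ia_b)^2 / sd_b^2
  eps <- 1e-9
  grid <- seq(eps, 1 - eps, length.out = 512)
  v <- d2(grid)
  i <- which.min(v)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(d2, c(lo, hi), tol = 1e-12)
  y <- opt$minimum
  list(x = y, y = traj$fun(y), distance = sqrt(opt$objective), y_par = y)
}
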