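## Nonlinear regression of the 3- and 2-parameter logistic and the
## operational (Black-Leff) model, all in their log-concentration forms,
## with asymptotic covariance and pointwise confidence bands.

# slope-factor bounds keep the ill-identified regime finite
.N_LO <- 0.2
.N_HI <- 5
.LNTAU_LO <- -12
.LNTAU_HI <- 12

# central-difference jacobian of a vector-valued function of the parameters
num_jac <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

# multi-start Levenberg-Marquardt least squares; returns best converged fit
ls_multistart <- function(resid_fn, starts, lower, upper) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 1000)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$deviance < best$deviance))
      best <- f
  }
  if (is.null(best)) stop("nonlinear least-squares failed for all starts")
  best
}

# shared post-processing: covariance from the asymptotic linearization
finish_fit <- function(curve, par, pred_fn, wts, fixed_mask = NULL) {
  resid <- (curve$resp - pred_fn(par, log(curve$conc))) * sqrt(wts)
  rss <- sum(resid^2)
  free <- if (is.null(fixed_mask)) rep(TRUE, length(par)) else !fixed_mask
  dof <- length(curve$resp) - sum(free)
  J <- num_jac(function(p) pred_fn(p, log(curve$conc)) * sqrt(wts), par)
  Jf <- J[, free, drop = FALSE]
  s2 <- if (dof > 0) rss / dof else 0
  XtX <- crossprod(Jf)
  Vf <- tryCatch(solve(XtX), error = function(e) MASS::ginv(XtX)) * s2
  V <- matrix(0, length(par), length(par),
              dimnames = list(names(par), names(par)))
  V[free, free] <- Vf
  list(par = par, cov = V, rss = rss, dof = dof, s2 = s2)
}

fit_weights <- function(curve, weights) {
  if (identical(weights, "inverse_variance")) {
    w <- 1 / pmax(curve$resp_sd, 1e-12)^2
    w / mean(w)
  } else rep(1, length(curve$resp))
}

pred_logistic3 <- function(par, lconc)
  par[["e_max"]] / (1 + exp(par[["slope_n"]] * (par[["ln_ec50"]] - lconc)))

pred_logistic2 <- function(par, lconc)
  1 / (1 + exp(par[["slope_b"]] * (par[["ln_c"]] - lconc)))

pred_operational <- function(par, lconc) {
  # E([L]) = r_max (tau L)^n / ((L + Kd)^n + (tau L)^n), in log form
  a <- par[["slope_n"]] * log(exp(lconc) + exp(par[["ln_kd"]]))
  b <- par[["slope_n"]] * (par[["ln_tau"]] + lconc)
  par[["r_max"]] / (1 + exp(a - b))
}

logistic3_starts <- function(curve) {
  lconc <- log(curve$conc)
  emax0 <- max(curve$resp)
  half <- emax0 / 2
  i <- which(curve$resp >= half)[1]
  lec0 <- if (is.na(i) || i == 1L) stats::median(lconc) else
    stats::approx(curve$resp[(i - 1):i], lconc[(i - 1):i], xout = half,
                  ties = "ordered")$y
  if (!is.finite(lec0)) lec0 <- stats::median(lconc)
  list(c(e_max = emax0, slope_n = 1, ln_ec50 = lec0),
       c(e_max = emax0 * 1.1, slope_n = 1, ln_ec50 = lec0),
       c(e_max = emax0, slope_n = 0.5, ln_ec50 = lec0),
       c(e_max = emax0, slope_n = 2, ln_ec50 = lec0),
       c(e_max = emax0 * 1.5, slope_n = 1, ln_ec50 = lec0 + 2))
}

check_monotone <- function(curve) {
  if (stats::cor(log(curve$conc), curve$resp, method = "spearman") < 0 &&
      curve$resp[1] > curve$resp[length(curve$resp)])
    stop(sprintf(
      "curve '%s'/'%s' is monotone decreasing; antagonist-mode data not supported",
      curve$ligand, curve$assay))
}

new_cr_fit <- function(cls, curve, fin, extra = list(), warnings = character()) {
  structure(c(list(ligand = curve$ligand, assay = curve$assay,
                   par = fin$par, cov = fin$cov, rss = fin$rss,
                   dof = fin$dof, s2 = fin$s2, curve = curve,
                   warnings = warnings), extra),
            class = c(cls, "cr_fit"))
}

#' @export
print.cr_fit <- function(x, ...) {
  cat(sprintf("<%s> '%s'/'%s'\n", class(x)[1], x$ligand, x$assay))
  print(signif(x$par, 6))
  cat(sprintf("rss %.4g on %d dof\n", x$rss, x$dof))
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Fit a 3-parameter logistic concentration-response model
#'
#' Least-squares regression of `r = E_max / (1 + (EC50/[L])^n)` on the
#' natural-log concentration scale, with multi-start Levenberg-Marquardt
#' optimization and asymptotic (linearization) covariance.
#'
#' @param curve A [cr_curve].
#' @param weights `"none"` (default; the averaged curves are fit unweighted)
#'   or `"inverse_variance"` (weights `1/resp_sd^2`).
#' @param starts Optional list of named start vectors
#'   (`e_max`, `slope_n`, `ln_ec50`) overriding the built-in heuristics; a
#'   single-start list is used internally by the bootstrap for speed.
#' @return An object of class `logistic3_fit` with elements `par`
#'   (`e_max`, `slope_n`, `ln_ec50`), `cov`, `rss`, `dof` and `warnings`.
#'   Warnings are attached when the fitted EC50 lies outside the tested
#'   concentration range or the slope hits its bounds \eqn{[0.2, 5]}.
#' @export
fit_logistic3 <- function(curve, weights = "none", starts = NULL) {
  stopifnot(inherits(curve, "cr_curve"))
  check_monotone(curve)
  lconc <- log(curve$conc)
  wts <- fit_weights(curve, weights)
  sw <- sqrt(wts)
  resid_fn <- function(p) (curve$resp - pred_logistic3(p, lconc)) * sw
  lower <- c(e_max = 1e-9, slope_n = .N_LO, ln_ec50 = min(lconc) - 25)
  upper <- c(e_max = 100 * max(curve$resp), slope_n = .N_HI,
             ln_ec50 = max(lconc) + 25)
  if (is.null(starts)) starts <- logistic3_starts(curve)
  best <- ls_multistart(resid_fn, starts, lower, upper)
  par <- stats::setNames(best$par, c("e_max", "slope_n", "ln_ec50"))
  warn <- character()
  if (par["ln_ec50"] < min(lconc) || par["ln_ec50"] > max(lconc))
    warn <- c(warn, "fitted EC50 outside tested concentration range")
  if (par["e_max"] > pred_logistic3(par, max(lconc)) * 1.25)
    warn <- c(warn, "fitted E_max extrapolated beyond top tested concentration")
  if (par["slope_n"] <= .N_LO + 1e-9 || par["slope_n"] >= .N_HI - 1e-9)
    warn <- c(warn, "slope factor at bound")
  fin <- finish_fit(curve, par, pred_logistic3, wts)
  new_cr_fit("logistic3_fit", curve, fin, warnings = warn)
}

#' Fit a 2-parameter logistic to a reference-normalized curve
#'
#' As [fit_logistic3] but with the maximum pinned at 1, for reference-agonist
#' curves that have been normalized to their own fitted maximum. The fit
#' carries a closure `band(conc, level)` giving the pointwise asymptotic
#' confidence band of the fitted curve, needed by the trajectory-distance
#' diagnostic.
#'
#' @inheritParams fit_logistic3
#' @return An object of class `logistic2_fit` with `par` (`ln_c`, `slope_b`),
#'   `cov`, `rss`, `dof`, and `band`.
#' @export
fit_logistic2 <- function(curve, weights = "none", starts = NULL) {
  stopifnot(inherits(curve, "cr_curve"))
  check_monotone(curve)
  if (max(curve$resp) < 0.6 || max(curve$resp) > 1.6)
    warning(sprintf(
      "curve '%s'/'%s' plateau %.2f far from 1; is the panel normalized?",
      curve$ligand, curve$assay, max(curve$resp)))
  lconc <- log(curve$conc)
  wts <- fit_weights(curve, weights)
  sw <- sqrt(wts)
  resid_fn <- function(p) (curve$resp - pred_logistic2(p, lconc)) * sw
  lower <- c(ln_c = min(lconc) - 25, slope_b = .N_LO)
  upper <- c(ln_c = max(lconc) + 25, slope_b = .N_HI)
  if (is.null(starts)) {
    s3 <- logistic3_starts(curve)
    starts <- lapply(s3, function(p)
      c(ln_c = unname(p["ln_ec50"]), slope_b = unname(p["slope_n"])))
  }
  best <- ls_multistart(resid_fn, starts, lower, upper)
  par <- stats::setNames(best$par, c("ln_c", "slope_b"))
  fin <- finish_fit(curve, par, pred_logistic2, wts)
  fit <- new_cr_fit("logistic2_fit", curve, fin)
  tcrit <- if (fit$dof > 0) stats::qt(0.975, fit$dof) else 1.96
  fit$band <- function(conc, level = 0.95) {
    lc <- log(conc)
    yhat <- pred_logistic2(par, lc)
    g <- num_jac(function(p) pred_logistic2(p, lc), par)
    se <- sqrt(pmax(rowSums((g %*% fit$cov) * g), 0))
    tq <- if (identical(level, 0.95)) tcrit else
      stats::qt(1 - (1 - level) / 2, max(fit$dof, 1))
    data.frame(conc = conc, fit = yhat,
               lower = yhat - tq * se, upper = yhat + tq * se, se = se)
  }
  fit
}

operational_starts <- function(curve, ln_kd_fixed = NULL) {
  emax0 <- max(curve$resp)
  lk0 <- if (is.null(ln_kd_fixed)) log(stats::median(curve$conc)) else ln_kd_fixed
  taus <- c(0.3, 1, 3, 30, 300)
  out <- lapply(taus, function(tau) {
    rmax0 <- emax0 * (1 + tau) / tau
    p <- c(r_max = min(rmax0, emax0 * 4), slope_n = 1, ln_tau = log(tau))
    if (is.null(ln_kd_fixed)) p <- c(p, ln_kd = lk0)
    p
  })
  out
}

#' Fit the operational (Black-Leff) model
#'
#' Least-squares regression of
#' `E([L]) = r_max (tau [L])^n / (([L]+Kd)^n + (tau [L])^n)` in its
#' log-concentration form. With `kd` supplied the binding constant is held
#' fixed at the measured value and `tau` is reliably estimated (the fixed-Kd
#' strategy); with `kd = NULL` the binding constant is a free parameter and
#' only the composite `tau/Kd` is reliably identified for strong agonists, so
#' the fit also reports `ln_tau_over_kd` with a delta-method standard error.
#'
#' @param curve A [cr_curve].
#' @param kd A [ligand_kd] table or a single Kd in molar units; `NULL` leaves
#'   Kd free.
#' @param r_max Optional fixed system maximal response. With Kd free and a
#'   Hill slope near 1 the three parameters `r_max`, `tau`, `Kd` trade off
#'   along an exact ridge (any combination reproducing the same plateau and
#'   midpoint fits equally well), so the composite `tau/Kd` is only pinned
#'   down once the system maximum is constrained; fixing `r_max` to the
#'   reference agonist's fitted maximum is the standard resolution and leaves
#'   relative `tau/Kd` values exact.
#' @inheritParams fit_logistic3
#' @return An object of class `operational_fit` with `par`
#'   (`r_max`, `slope_n`, `ln_tau`, `ln_kd`), `cov`, `kd_fixed`,
#'   `ln_tau_over_kd`, `se_ln_tau_over_kd`.
#' @export
fit_operational <- function(curve, kd = NULL, r_max = NULL, weights = "none",
                            starts = NULL) {
  stopifnot(inherits(curve, "cr_curve"))
  check_monotone(curve)
  if (inherits(kd, "ligand_kd")) kd <- kd_lookup(kd, curve$ligand)
  kd_fixed <- !is.null(kd) && is.finite(kd)
  rmax_fixed <- !is.null(r_max) && is.finite(r_max)
  if (kd_fixed && kd <= 0) stop("fixed Kd must be positive")
  if (rmax_fixed && r_max <= 0) stop("fixed r_max must be positive")
  if (kd_fixed && kd < min(curve$conc) / 1e3)
    warning(sprintf("fixed Kd (%.3g M) is >1000-fold below the lowest tested concentration", kd))
  lconc <- log(curve$conc)
  wts <- fit_weights(curve, weights)
  sw <- sqrt(wts)
  pnames <- c("r_max", "slope_n", "ln_tau", "ln_kd")
  fixed_mask <- c(rmax_fixed, FALSE, FALSE, kd_fixed)
  names(fixed_mask) <- pnames
  fixed_vals <- c(r_max = if (rmax_fixed) r_max else NA_real_,
                  slope_n = NA_real_, ln_tau = NA_real_,
                  ln_kd = if (kd_fixed) log(kd) else NA_real_)
  lower_all <- c(r_max = 1e-9, slope_n = .N_LO, ln_tau = .LNTAU_LO,
                 ln_kd = log(1e-15))
  upper_all <- c(r_max = 100 * max(curve$resp), slope_n = .N_HI,
                 ln_tau = .LNTAU_HI, ln_kd = 0)
  free <- pnames[!fixed_mask]
  full_par <- function(p) {
    fp <- fixed_vals
    fp[free] <- p
    fp
  }
  resid_fn <- function(p) (curve$resp - pred_operational(full_par(p), lconc)) * sw
  if (is.null(starts))
    starts <- operational_starts(curve, if (kd_fixed) log(kd))
  starts <- lapply(starts, function(p) {
    fp <- c(r_max = max(curve$resp) * 1.05, slope_n = 1, ln_tau = 0,
            ln_kd = log(stats::median(curve$conc)))
    fp[intersect(names(p), pnames)] <- p[intersect(names(p), pnames)]
    fp[free]
  })
  best <- ls_multistart(resid_fn, starts, lower_all[free], upper_all[free])
  par <- full_par(stats::setNames(best$par, free))
  warn <- character()
  if (par["slope_n"] <= .N_LO + 1e-9 || par["slope_n"] >= .N_HI - 1e-9)
    warn <- c(warn, "slope factor at bound")
  if (!kd_fixed &&
      (par["ln_tau"] <= .LNTAU_LO + 1e-6 || par["ln_tau"] >= .LNTAU_HI - 1e-6))
    warn <- c(warn, "ln_tau at bound (tau and Kd not separately identified)")
  fin <- finish_fit(curve, par, pred_operational, wts, fixed_mask)
  ltk <- unname(par["ln_tau"] - par["ln_kd"])
  a <- c(0, 0, 1, -1)
  se_ltk <- sqrt(max(drop(t(a) %*% fin$cov %*% a), 0))
  new_cr_fit("operational_fit", curve, fin,
             extra = list(kd_fixed = kd_fixed, ln_tau_over_kd = ltk,
                          se_ln_tau_over_kd = se_ltk),
             warnings = warn)
}

#' Fitted-curve prediction for any concentration-response fit
#' @param object A `cr_fit`.
#' @param conc Molar concentrations.
#' @param ... Unused.
#' @return Numeric vector of fitted responses.
#' @export
predict.cr_fit <- function(object, conc = object$curve$conc, ...) {
  fn <- switch(class(object)[1],
               logistic3_fit = pred_logistic3,
               logistic2_fit = pred_logistic2,
               operational_fit = pred_operational)
  fn(object$par, log(conc))
}

#' Invert a fitted logistic at a response level
#'
#' Closed-form inverse of the 3-parameter logistic: the unique concentration
#' at which the fitted curve passes through `level`. Used to obtain
#' equi-effective concentrations for the null-method strategies.
#'
#' @param fit A `logistic3_fit` (or `logistic2_fit`).
#' @param level Response level, strictly between 0 and the fitted maximum.
#' @return Molar concentration.
#' @export
inverse_response <- function(fit, level) {
  stopifnot(inherits(fit, "cr_fit"))
  if (inherits(fit, "logistic3_fit")) {
    emax <- fit$par[["e_max"]]; n <- fit$par[["slope_n"]]
    lec <- fit$par[["ln_ec50"]]
  } else if (inherits(fit, "logistic2_fit")) {
    emax <- 1; n <- fit$par[["slope_b"]]; lec <- fit$par[["ln_c"]]
  } else stop("inverse_response needs a logistic fit")
  if (any(level <= 0 | level >= emax))
    stop(sprintf(
      "response level %s out of range (0, %.4g) for ligand '%s'",
      paste(signif(level, 4), collapse = ","), emax, fit$ligand))
  exp(lec - log(emax / level - 1) / n)
}
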