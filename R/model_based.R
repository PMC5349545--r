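## Bias-factor computation by the seven classical receptor-theory strategies:
## operational-model transduction ratios (1, 2), Emax/EC50 ratios (3),
## equi-effective occupancy ratios (4-6) and double-reciprocal slopes (7),
## plus the parametric-bootstrap null band and global performance summaries.
## All bias factors are log10 of the ratio, across the two assays, of the
## ligand's relative efficacy (test scaled to the reference agonist); the
## reference ligand's bias factor is identically 0.

LN10 <- log(10)

#' Configuration for bias computations
#'
#' Collects every tunable of the model-based and model-free diagnostics with
#' its default. Pass the result to the method functions, [run_all_methods]
#' or [monte_carlo_null_band].
#'
#' @param weights Residual weighting for all curve fits: `"none"` or
#'   `"inverse_variance"`.
#' @param slope_warn Method 3 attaches a warning to any ligand whose fitted
#'   Hill slope deviates from 1 by more than this (the Emax/EC50 equivalence
#'   to tau/Kd holds only near slope 1).
#' @param n_levels Number of response levels for the multi-level null-method
#'   strategies (5, 6) and for the double-reciprocal regression (7).
#' @param single_level_frac Method 4 evaluates occupancies at this fraction of
#'   the smallest fitted E_max among ligands sharing the comparison.
#' @param common_range Method 5 level span, as fractions of the smallest
#'   fitted E_max across the comparison.
#' @param pair_range Methods 6 and 7 level span, as fractions of each
#'   reference/test pair's own overlap of fitted dynamic ranges.
#' @param n_sim Parametric-bootstrap replicates for the null band.
#' @param n_mc Monte Carlo iterations for the rank-order diagnostic.
#' @param per_ligand_band If `TRUE`, the null band is computed per ligand
#'   instead of pooled across ligands.
#' @param ellipse_df Degrees of freedom of the chi-square quantile used for
#'   95% confidence ellipses (2 = joint bivariate convention, 1 = marginal).
#' @return A list of class `bias_config`.
#' @export
bias_config <- function(weights = "none", slope_warn = 0.3, n_levels = 10L,
                        single_level_frac = 0.5, common_range = c(0.2, 0.8),
                        pair_range = c(0.1, 0.9), n_sim = 1000L,
                        n_mc = 500000L, per_ligand_band = FALSE,
                        ellipse_df = 2L) {
  structure(list(weights = weights, slope_warn = slope_warn,
                 n_levels = as.integer(n_levels),
                 single_level_frac = single_level_frac,
                 common_range = common_range, pair_range = pair_range,
                 n_sim = as.integer(n_sim), n_mc = as.integer(n_mc),
                 per_ligand_band = per_ligand_band,
                 ellipse_df = as.integer(ellipse_df)),
            class = "bias_config")
}

check_pair <- function(panelA, panelB) {
  stopifnot(inherits(panelA, "assay_panel"), inherits(panelB, "assay_panel"))
  if (panelA$reference != panelB$reference)
    stop(sprintf("panels use different reference ligands ('%s' vs '%s')",
                 panelA$reference, panelB$reference))
  common <- intersect(ligands(panelA), ligands(panelB))
  if (length(common) < 2L)
    stop("panels share fewer than 2 ligands")
  common
}

# fit every curve of a panel with one model; failures recorded, not fatal
panel_fits <- function(panel, fitter, lig_ids, starts = NULL) {
  out <- list(); warn <- character()
  if (is.null(starts)) starts <- panel$start_hints
  for (lg in lig_ids) {
    st <- if (!is.null(starts) && !is.null(starts[[lg]])) list(starts[[lg]])
    f <- tryCatch(fitter(panel$curves[[lg]], st),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      warn <- c(warn, sprintf("assay '%s', ligand '%s': fit failed (%s)",
                              panel$assay, lg, f))
      out[lg] <- list(NULL)
    } else out[[lg]] <- f
  }
  attr(out, "warnings") <- warn
  out
}

# per-panel log10 relative efficacies for the operational strategies; with
# Kd free the system maximum is pinned to the reference's fitted plateau,
# which resolves the tau/Kd ridge while leaving the relative values exact
rel_log10_operational <- function(panel, lig_ids, kds, cfg, starts = NULL) {
  fixed <- !is.null(kds)
  r_max <- if (!fixed) {
    ref3 <- fit_logistic3(panel$curves[[panel$reference]],
                          weights = cfg$weights)
    unname(ref3$par["e_max"])
  }
  fitter <- function(cv, st)
    fit_operational(cv, kd = if (fixed) kd_lookup(kds, cv$ligand),
                    r_max = r_max, weights = cfg$weights, starts = st)
  fits <- panel_fits(panel, fitter, lig_ids, starts)
  qty <- vapply(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    if (fixed) f$par[["ln_tau"]] else f$ln_tau_over_kd
  }, numeric(1))
  rel <- (qty - qty[[panel$reference]]) / LN10
  attr(rel, "warnings") <- attr(fits, "warnings")
  attr(rel, "fits") <- fits
  rel
}

bias_from_rel <- function(relA, relB, lig_ids, reference, method_id,
                          assay_a, assay_b, warnings = character()) {
  bias <- relA[lig_ids] - relB[lig_ids]
  bias[reference] <- 0
  structure(
    data.frame(ligand = lig_ids, method = method_id,
               assay_a = assay_a, assay_b = assay_b,
               bias_factor = unname(bias),
               ci_low = NA_real_, ci_high = NA_real_, flagged = NA,
               warnings = vapply(lig_ids, function(lg) {
                 w <- grep(sprintf("'%s'", lg), warnings, value = TRUE)
                 paste(w, collapse = "; ")
               }, character(1)),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("bias_result", "data.frame"))
}

#' Method 1: operational transduction ratios with measured Kd
#'
#' Fits the operational model to every curve with the ligand's experimentally
#' measured Kd held fixed; the relative efficacy within each assay is the
#' ratio of transduction coefficients `tau` to the reference agonist's, and
#' the bias factor is the log10 ratio of relative efficacies across assays.
#'
#' @param panelA,panelB Two [assay_panel]s sharing the reference ligand.
#' @param kds A [ligand_kd] table covering the shared ligands; ligands without
#'   a Kd are skipped with a warning.
#' @param cfg A [bias_config].
#' @return A `bias_result` data frame (one row per shared ligand) with
#'   columns `ligand, method, assay_a, assay_b, bias_factor, ci_low, ci_high,
#'   flagged, warnings`. Confidence limits and flags are filled in by
#'   [apply_null_band].
#' @export
bias_method1 <- function(panelA, panelB, kds, cfg = bias_config()) {
  common <- check_pair(panelA, panelB)
  stopifnot(inherits(kds, "ligand_kd"))
  has_kd <- vapply(common, function(lg) is.finite(kd_lookup(kds, lg)), logical(1))
  warn <- character()
  if (!has_kd[[panelA$reference]])
    stop("reference ligand has no Kd; method 1 requires it")
  if (any(!has_kd))
    warn <- c(warn, sprintf("ligand '%s': skipped, no Kd available",
                            common[!has_kd]))
  use <- common[has_kd]
  relA <- rel_log10_operational(panelA, use, kds, cfg)
  relB <- rel_log10_operational(panelB, use, kds, cfg)
  bias_from_rel(relA, relB, use, panelA$reference, 1L,
                panelA$assay, panelB$assay,
                c(warn, attr(relA, "warnings"), attr(relB, "warnings")))
}

#' Method 2: operational tau/Kd composite ratios (Kd free)
#'
#' As method 1 but with the binding constant free in the regression, so that
#' only the composite `tau/Kd` (the transduction coefficient normalized by
#' affinity) is carried into the relative efficacies. This is the most widely
#' used strategy in the bias literature.
#'
#' @inheritParams bias_method1
#' @return A `bias_result` data frame; see [bias_method1].
#' @export
bias_method2 <- function(panelA, panelB, cfg = bias_config()) {
  common <- check_pair(panelA, panelB)
  relA <- rel_log10_operational(panelA, common, NULL, cfg)
  relB <- rel_log10_operational(panelB, common, NULL, cfg)
  bias_from_rel(relA, relB, common, panelA$reference, 2L,
                panelA$assay, panelB$assay,
                c(attr(relA, "warnings"), attr(relB, "warnings")))
}

rel_log10_emax_ec50 <- function(panel, lig_ids, cfg, starts = NULL) {
  fitter <- function(cv, st) fit_logistic3(cv, weights = cfg$weights, starts = st)
  fits <- panel_fits(panel, fitter, lig_ids, starts)
  warn <- attr(fits, "warnings")
  qty <- vapply(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    log10(f$par[["e_max"]]) - f$par[["ln_ec50"]] / LN10
  }, numeric(1))
  for (lg in lig_ids) {
    f <- fits[[lg]]
    if (!is.null(f) && abs(f$par[["slope_n"]] - 1) > cfg$slope_warn)
      warn <- c(warn, sprintf(
        "assay '%s', ligand '%s': slope %.2f far from 1; Emax/EC50 ~ tau/Kd equivalence degraded",
        panel$assay, lg, f$par[["slope_n"]]))
  }
  rel <- qty - qty[[panel$reference]]
  attr(rel, "warnings") <- warn
  attr(rel, "fits") <- fits
  rel
}

#' Method 3: Emax/EC50 ratio bias factors
#'
#' Relative efficacy within each assay is the ligand's `E_max/EC50` (from a
#' 3-parameter logistic fit) scaled to the reference agonist's; at Hill slope
#' 1 this equals the `tau/Kd` composite of method 2. Ligands whose fitted
#' slope deviates from 1 by more than `cfg$slope_warn` carry a warning.
#'
#' @inheritParams bias_method2
#' @return A `bias_result` data frame; see [bias_method1].
#' @export
bias_method3 <- function(panelA, panelB, cfg = bias_config()) {
  common <- check_pair(panelA, panelB)
  relA <- rel_log10_emax_ec50(panelA, common, cfg)
  relB <- rel_log10_emax_ec50(panelB, common, cfg)
  bias_from_rel(relA, relB, common, panelA$reference, 3L,
                panelA$assay, panelB$assay,
                c(attr(relA, "warnings"), attr(relB, "warnings")))
}

#' Relative efficacy from occupancies at equi-effective concentrations
#'
#' The Stephenson-Furchgott null argument: equal stimuli produce equal
#' responses, so at concentrations of reference and test agonist giving the
#' same response, `eps_t/eps_r = O_r/O_t` where `O = [L]/([L]+Kd)` is the
#' fractional occupancy. Determinations at several response levels are
#' combined as a geometric mean (the quantity is a ratio).
#'
#' @param fit_ref,fit_test `logistic3_fit` objects for reference and test
#'   ligand in one assay.
#' @param kd_ref,kd_test Dissociation constants in molar units.
#' @param levels Response levels; each must lie below both fitted maxima.
#' @return List with `rel_efficacy` (geometric-mean `eps_t/eps_r`) and a
#'   per-level data frame `levels`.
#' @export
equieffective_occupancy_ratio <- function(fit_ref, fit_test, kd_ref, kd_test,
                                          levels) {
  emax_r <- fit_ref$par[["e_max"]]; emax_t <- fit_test$par[["e_max"]]
  ok <- levels > 0 & levels < emax_r & levels < emax_t
  if (!any(ok))
    stop(sprintf("no feasible response level for pair '%s'/'%s'",
                 fit_ref$ligand, fit_test$ligand))
  levels <- levels[ok]
  l_ref <- inverse_response(fit_ref, levels)
  l_test <- inverse_response(fit_test, levels)
  occ_ref <- l_ref / (l_ref + kd_ref)
  occ_test <- l_test / (l_test + kd_test)
  ratio <- occ_ref / occ_test
  list(rel_efficacy = exp(mean(log(ratio))),
       levels = data.frame(level = levels, conc_ref = l_ref,
                           conc_test = l_test, occ_ref = occ_ref,
                           occ_test = occ_test, rel_efficacy = ratio))
}

null_method_levels <- function(strategy, cfg, emax_all, emax_pair) {
  switch(strategy,
         single_level = cfg$single_level_frac * min(emax_all),
         common_range = seq(cfg$common_range[1], cfg$common_range[2],
                            length.out = cfg$n_levels) * min(emax_all),
         optimized_range = seq(cfg$pair_range[1], cfg$pair_range[2],
                               length.out = cfg$n_levels) * min(emax_pair),
         stop("unknown level strategy: ", strategy))
}

rel_log10_null_method <- function(panel, lig_ids, kds, strategy, cfg,
                                  emax_all, fits) {
  warn <- attr(fits, "warnings")
  ref_fit <- fits[[panel$reference]]
  kd_ref <- kd_lookup(kds, panel$reference)
  rel <- vapply(lig_ids, function(lg) {
    f <- fits[[lg]]
    if (is.null(f) || is.null(ref_fit)) return(NA_real_)
    if (lg == panel$reference) return(0)
    levels <- null_method_levels(strategy, cfg, emax_all,
                                 c(ref_fit$par[["e_max"]], f$par[["e_max"]]))
    feasible <- levels < f$par[["e_max"]] & levels < ref_fit$par[["e_max"]]
    if (!any(feasible)) return(NA_real_)
    eor <- equieffective_occupancy_ratio(ref_fit, f, kd_ref,
                                         kd_lookup(kds, lg), levels[feasible])
    log10(eor$rel_efficacy)
  }, numeric(1))
  dropped <- lig_ids[is.na(rel) & !vapply(fits[lig_ids], is.null, logical(1))]
  if (length(dropped))
    warn <- c(warn, sprintf(
      "assay '%s', ligand '%s': excluded, E_max below the evaluation level",
      panel$assay, dropped))
  attr(rel, "warnings") <- warn
  rel
}

#' Methods 4-6: equi-effective occupancy-ratio bias factors
#'
#' Three variants of the null-method strategy differing only in how response
#' levels are chosen: a single level common to all agonists (method 4,
#' `strategy = "single_level"`), multiple levels within a range common to all
#' agonists (method 5, `"common_range"`), or multiple levels within a range
#' optimized per reference/test pair (method 6, `"optimized_range"`). In all
#' cases relative efficacy comes from [equieffective_occupancy_ratio] and the
#' bias factor is the log10 cross-assay ratio. Ligands whose fitted maximum
#' lies below the evaluation level are excluded with a warning.
#'
#' @inheritParams bias_method1
#' @param strategy One of `"single_level"`, `"common_range"`,
#'   `"optimized_range"`.
#' @return A `bias_result` data frame; see [bias_method1].
#' @export
bias_methods456 <- function(panelA, panelB, kds,
                            strategy = c("single_level", "common_range",
                                         "optimized_range"),
                            cfg = bias_config()) {
  strategy <- match.arg(strategy)
  common <- check_pair(panelA, panelB)
  stopifnot(inherits(kds, "ligand_kd"))
  has_kd <- vapply(common, function(lg) is.finite(kd_lookup(kds, lg)), logical(1))
  warn <- character()
  if (!has_kd[[panelA$reference]])
    stop("reference ligand has no Kd; the occupancy strategies require it")
  if (any(!has_kd))
    warn <- c(warn, sprintf("ligand '%s': skipped, no Kd available",
                            common[!has_kd]))
  use <- common[has_kd]
  fitter <- function(cv, st) fit_logistic3(cv, weights = cfg$weights, starts = st)
  fitsA <- panel_fits(panelA, fitter, use)
  fitsB <- panel_fits(panelB, fitter, use)
  emax_all <- unlist(lapply(c(fitsA, fitsB), function(f)
    if (!is.null(f)) f$par[["e_max"]]))
  relA <- rel_log10_null_method(panelA, use, kds, strategy, cfg, emax_all, fitsA)
  relB <- rel_log10_null_method(panelB, use, kds, strategy, cfg, emax_all, fitsB)
  mid <- c(single_level = 4L, common_range = 5L, optimized_range = 6L)[[strategy]]
  bias_from_rel(relA, relB, use, panelA$reference, mid,
                panelA$assay, panelB$assay,
                c(warn, attr(relA, "warnings"), attr(relB, "warnings")))
}

#' Double-reciprocal slope of equi-effective concentrations
#'
#' At equi-effective concentrations of reference and test agonist the
#' reciprocal concentrations are linearly related; the slope of
#' `1/[L_t]` regressed on `1/[L_r]` (free intercept) is the test ligand's
#' `eps/Kd` relative to the reference's.
#'
#' @param fit_ref,fit_test `logistic3_fit`s of reference and test ligand.
#' @param levels Response levels (at least 5) below both fitted maxima.
#' @return The fitted slope (may be non-positive for pathological fits).
#' @export
double_reciprocal_slope <- function(fit_ref, fit_test, levels) {
  if (length(levels) < 5L) stop("at least 5 response levels are required")
  x <- 1 / inverse_response(fit_ref, levels)
  y <- 1 / inverse_response(fit_test, levels)
  stats::lsfit(x, y)$coefficients[["X"]]
}

rel_log10_reciprocal <- function(panel, lig_ids, cfg, fits) {
  warn <- attr(fits, "warnings")
  ref_fit <- fits[[panel$reference]]
  rel <- vapply(lig_ids, function(lg) {
    f <- fits[[lg]]
    if (is.null(f) || is.null(ref_fit)) return(NA_real_)
    if (lg == panel$reference) return(0)
    top <- min(ref_fit$par[["e_max"]], f$par[["e_max"]])
    levels <- seq(cfg$pair_range[1], cfg$pair_range[2],
                  length.out = max(cfg$n_levels, 5L)) * top
    slope <- double_reciprocal_slope(ref_fit, f, levels)
    if (!is.finite(slope) || slope <= 0) return(NA_real_)
    log10(slope)
  }, numeric(1))
  bad <- lig_ids[is.na(rel) & !vapply(fits[lig_ids], is.null, logical(1))]
  if (length(bad))
    warn <- c(warn, sprintf(
      "assay '%s', ligand '%s': non-positive double-reciprocal slope, invalid",
      panel$assay, bad))
  attr(rel, "warnings") <- warn
  rel
}

#' Method 7: double-reciprocal slope-ratio bias factors
#'
#' Under the null method there is a linear relation between the reciprocal
#' equi-effective concentrations of test and reference agonist whose slope is
#' the test ligand's `eps/Kd` relative to the reference's. Per assay, the
#' reciprocal test concentrations are regressed on the reciprocal reference
#' concentrations (free intercept) over `cfg$n_levels` levels spanning the
#' pair's shared response range; the bias factor is the log10 cross-assay
#' slope ratio. No Kd values are needed.
#'
#' @inheritParams bias_method2
#' @return A `bias_result` data frame; see [bias_method1]. Ligands with a
#'   non-positive fitted slope are flagged invalid (NA bias factor).
#' @export
bias_method7 <- function(panelA, panelB, cfg = bias_config()) {
  common <- check_pair(panelA, panelB)
  fitter <- function(cv, st) fit_logistic3(cv, weights = cfg$weights, starts = st)
  fitsA <- panel_fits(panelA, fitter, common)
  fitsB <- panel_fits(panelB, fitter, common)
  relA <- rel_log10_reciprocal(panelA, common, cfg, fitsA)
  relB <- rel_log10_reciprocal(panelB, common, cfg, fitsB)
  bias_from_rel(relA, relB, common, panelA$reference, 7L,
                panelA$assay, panelB$assay,
                c(attr(relA, "warnings"), attr(relB, "warnings")))
}

# dispatcher used by the bootstrap and by run_all_methods
compute_bias <- function(panelA, panelB, method_id, kds = NULL,
                         cfg = bias_config()) {
  switch(as.character(method_id),
         `1` = bias_method1(panelA, panelB, kds, cfg),
         `2` = bias_method2(panelA, panelB, cfg),
         `3` = bias_method3(panelA, panelB, cfg),
         `4` = bias_methods456(panelA, panelB, kds, "single_level", cfg),
         `5` = bias_methods456(panelA, panelB, kds, "common_range", cfg),
         `6` = bias_methods456(panelA, panelB, kds, "optimized_range", cfg),
         `7` = bias_method7(panelA, panelB, cfg),
         stop("method_id must be 1..7"))
}

# redraw every curve's responses about its fitted values; the original
# parameter estimates seed the bootstrap refits (single-start fast path)
resample_panel <- function(panel, fits) {
  panel$curves <- lapply(panel$curves, function(cv) {
    f <- fits[[cv$ligand]]
    mu <- if (is.null(f)) cv$resp else predict(f, cv$conc)
    cv$resp <- mu + stats::rnorm(length(mu), 0, cv$resp_sd)
    cv
  })
  panel$start_hints <- lapply(fits, function(f) if (!is.null(f)) f$par)
  panel
}

#' Parametric-bootstrap null band for bias factors
#'
#' Builds the no-bias 95% confidence band against which bias factors are
#' judged: each curve's responses are redrawn from
#' `Normal(fitted value, resp_sd)`, all bias factors recomputed, and the
#' 2.5th/97.5th percentiles of the pooled null distribution (reference ligand
#' excluded) returned. The original curve fits seed each bootstrap refit.
#' Deterministic given `seed`.
#'
#' @inheritParams bias_method1
#' @param method_id Which method (1-7) to bootstrap.
#' @param n_sim Number of bootstrap replicates; at least 100.
#' @param seed Integer RNG seed.
#' @return Numeric vector `c(ci_low, ci_high)` (pooled), or a data frame of
#'   per-ligand bands when `cfg$per_ligand_band` is `TRUE`. The pooled null
#'   draws are attached as attribute `"draws"`.
#' @export
monte_carlo_null_band <- function(panelA, panelB, method_id, kds = NULL,
                                  n_sim = 1000L, seed = 1L,
                                  cfg = bias_config()) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  common <- check_pair(panelA, panelB)
  if (all(vapply(c(panelA$curves, panelB$curves),
                 function(cv) all(cv$resp_sd == 0), logical(1))))
    return(structure(c(ci_low = 0, ci_high = 0), draws = numeric(0)))
  gen_fitter <- function(panel) {
    fitter <- switch(as.character(method_id),
      `1` = function(cv, st) fit_operational(cv, kd = kd_lookup(kds, cv$ligand),
                                             weights = cfg$weights, starts = st),
      `2` = function(cv, st) fit_operational(cv, weights = cfg$weights, starts = st),
      function(cv, st) fit_logistic3(cv, weights = cfg$weights, starts = st))
    panel_fits(panel, fitter, ligands(panel))
  }
  fitsA <- gen_fitter(panelA)
  fitsB <- gen_fitter(panelB)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- panelA$reference
  draws <- vector("list", n_sim)
  for (s in seq_len(n_sim)) {
    pa <- resample_panel(panelA, fitsA)
    pb <- resample_panel(panelB, fitsB)
    res <- tryCatch(compute_bias(pa, pb, method_id, kds, cfg),
                    error = function(e) NULL)
    if (is.null(res)) next
    keep <- res$ligand != ref
    draws[[s]] <- stats::setNames(res$bias_factor[keep], res$ligand[keep])
  }
  draws <- draws[!vapply(draws, is.null, logical(1))]
  if (!length(draws)) stop("all bootstrap replicates failed")
  if (cfg$per_ligand_band) {
    ligs <- setdiff(common, ref)
    out <- do.call(rbind, lapply(ligs, function(lg) {
      v <- unlist(lapply(draws, `[`, lg))
      q <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      data.frame(ligand = lg, ci_low = q[1], ci_high = q[2])
    }))
    attr(out, "draws") <- unlist(draws, use.names = FALSE)
    out
  } else {
    pooled <- unlist(draws, use.names = FALSE)
    q <- stats::quantile(pooled, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    structure(c(ci_low = q[1], ci_high = q[2]), draws = pooled)
  }
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Attach a null band to bias results and call significance
#'
#' Marks each ligand as biased (`flagged`) when its bias factor falls outside
#' the null band; the reference ligand is never flagged.
#'
#' @param results A `bias_result` data frame.
#' @param band Output of [monte_carlo_null_band] (pooled vector or per-ligand
#'   data frame).
#' @param reference Reference ligand id (never flagged).
#' @return `results` with `ci_low`, `ci_high` and `flagged` filled in.
#' @export
apply_null_band <- function(results, band, reference) {
  if (is.data.frame(band)) {
    i <- match(results$ligand, band$ligand)
    results$ci_low <- band$ci_low[i]
    results$ci_high <- band$ci_high[i]
  } else {
    results$ci_low <- band[["ci_low"]]
    results$ci_high <- band[["ci_high"]]
  }
  results$flagged <- !is.na(results$bias_factor) &
    (results$bias_factor < results$ci_low | results$bias_factor > results$ci_high)
  results$flagged[results$ligand == reference] <- FALSE
  results
}

#' Global performance indicators for a set of bias results
#'
#' The two indicators used to rate methods against each other: the
#' root-mean-square departure of the bias factors from zero bias, and the
#' average positive-hit rate (total flagged calls divided by the number of
#' agonists and the number of assay comparisons they appear in). The
#' reference ligand (bias identically 0) is excluded from both.
#'
#' @param results A `bias_result` data frame, possibly pooling several
#'   comparisons.
#' @param reference Reference ligand id to exclude.
#' @return A data frame with one row per method: `method`, `rms_deviation`,
#'   `hit_rate`, `n_ligands`, `n_comparisons`.
#' @export
summarize_methods <- function(results, reference = NULL) {
  if (!nrow(results)) stop("empty bias results")
  if (!is.null(reference)) results <- results[results$ligand != reference, ]
  sp <- split(results, results$method)
  out <- do.call(rbind, lapply(sp, function(d) {
    cmp <- unique(paste(d$assay_a, d$assay_b, sep = "|"))
    b <- d$bias_factor[is.finite(d$bias_factor)]
    data.frame(method = d$method[1],
               rms_deviation = if (length(b)) sqrt(mean(b^2)) else NA_real_,
               hit_rate = sum(d$flagged, na.rm = TRUE) /
                 (length(unique(d$ligand)) * length(cmp)),
               n_ligands = length(unique(d$ligand)),
               n_comparisons = length(cmp))
  }))
  row.names(out) <- NULL
  out
}
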