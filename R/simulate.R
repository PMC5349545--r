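## Synthetic concentration-response generator: a panel of agonists with
## graded intrinsic efficacies observed through two different saturating
## transfer functions. This is the "system bias without ligand bias"
## negative-control construct used to challenge every diagnostic, with an
## optional per-ligand efficacy perturbation in pathway B to inject true
## ligand bias.
##
## Mechanism: occupancy O([L]) = [L]/([L]+Kd); stimulus s = eps * bias * O;
## response r = f(s) through the pathway's transfer function. With the Hill
## family f(s) = r_max s^n / (K_E^n + s^n) the curves are exactly
## operational with tau = eps/K_E, so the classical methods are
## well-specified on these data; the "log" family f(s) = r_max log(1+s/K_E)
## emulates realistic model misspecification.

#' Simulation configuration
#'
#' Defaults are the package's canonical study conditions: a reference full
#' agonist (efficacy 1) plus 11 test agonists with efficacies log-spaced over
#' 0.05-0.8, binding constants log-spaced around 1 uM, both pathways Hill
#' transfer functions with slope 1 but 10-fold different amplification
#' (`K_E` 0.03 vs 0.3) and different ceilings (`r_max` 1 vs 0.8), 10
#' log-spaced concentrations from 0.1 nM to 1 mM, 3 replicates, and replicate
#' noise SD 0.03 on the normalized response.
#'
#' @param n_ligands Total number of ligands including the reference.
#' @param efficacy Per-ligand intrinsic efficacies; the first entry is the
#'   reference and must be the maximum.
#' @param kd Per-ligand dissociation constants (molar).
#' @param transfer_a,transfer_b Transfer functions: lists with `r_max`,
#'   `k_e`, `n`, and optionally `type` (`"hill"` or `"log"`).
#' @param bias Named per-ligand multiplicative efficacy perturbation applied
#'   in pathway B only (1 = unbiased); the reference must be 1.
#' @param noise_sd Gaussian replicate noise SD on the normalized response.
#' @param conc Assay concentrations (molar).
#' @param n_replicates Replicate curves averaged per ligand.
#' @param ligand_ids Optional ligand names; default `REF`, `L01`, `L02`, ...
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ligands = 12L,
                       efficacy = NULL,
                       kd = NULL,
                       transfer_a = list(r_max = 1, k_e = 0.03, n = 1),
                       transfer_b = list(r_max = 0.8, k_e = 0.3, n = 1),
                       bias = NULL,
                       noise_sd = 0.03,
                       conc = 10^seq(-10, -3, length.out = 10),
                       n_replicates = 3L,
                       ligand_ids = NULL) {
  n_ligands <- as.integer(n_ligands)
  if (is.null(ligand_ids))
    ligand_ids <- c("REF", sprintf("L%02d", seq_len(n_ligands - 1L)))
  stopifnot(length(ligand_ids) == n_ligands)
  if (is.null(efficacy))
    efficacy <- c(1, 10^seq(log10(0.05), log10(0.8),
                            length.out = n_ligands - 1L))
  stopifnot(length(efficacy) == n_ligands, all(efficacy > 0))
  if (which.max(efficacy) != 1L)
    warning("reference (first) ligand is not the top-efficacy ligand; the trajectory assumes a full agonist")
  if (is.null(kd))
    kd <- 10^seq(-6.5, -5.5, length.out = n_ligands)
  stopifnot(length(kd) == n_ligands, all(kd > 0))
  b <- stats::setNames(rep(1, n_ligands), ligand_ids)
  if (!is.null(bias)) {
    stopifnot(!is.null(names(bias)), all(names(bias) %in% ligand_ids))
    b[names(bias)] <- bias
  }
  if (b[[ligand_ids[1]]] != 1)
    stop("the reference ligand's bias entry must be 1")
  for (tf in list(transfer_a, transfer_b))
    stopifnot(tf$r_max > 0, tf$k_e > 0, tf$n > 0)
  stopifnot(noise_sd >= 0, all(conc > 0), n_replicates >= 1L)
  structure(list(n_ligands = n_ligands, ligand_ids = ligand_ids,
                 efficacy = stats::setNames(efficacy, ligand_ids),
                 kd = stats::setNames(kd, ligand_ids),
                 transfer_a = transfer_a, transfer_b = transfer_b,
                 bias = b, noise_sd = noise_sd, conc = conc,
                 n_replicates = as.integer(n_replicates)),
            class = "sim_config")
}

transfer_fun <- function(tf) {
  type <- if (is.null(tf$type)) "hill" else tf$type
  switch(type,
         hill = function(s) tf$r_max * s^tf$n / (tf$k_e^tf$n + s^tf$n),
         log = function(s) tf$r_max * log1p(s / tf$k_e),
         stop("unknown transfer type: ", type))
}

#' Simulate a pair of assay panels with shared ligand efficacies
#'
#' Generates the two-pathway construct described in [sim_config]: identical
#' per-ligand efficacies viewed through two different transfer functions
#' (pure system bias), plus any injected efficacy perturbation in pathway B,
#' Gaussian replicate noise, and reference normalization of both panels.
#' Stored `resp_sd` is the SD of the mean response,
#' `noise_sd/sqrt(n_replicates)`. Bit-reproducible given `seed`.
#'
#' @param cfg A [sim_config].
#' @param seed Integer RNG seed.
#' @param normalize Normalize both panels to the reference's fitted maximum
#'   (default `TRUE`).
#' @return List with `panel_a`, `panel_b` ([assay_panel]s, assays `"A"` and
#'   `"B"`), `kds` (a [ligand_kd] table), and `truth` (data frame of ligand,
#'   efficacy, injected bias factor `log10(bias)`, and `biased` flag).
#' @export
simulate_panels <- function(cfg, seed = 1L, normalize = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fa <- transfer_fun(cfg$transfer_a)
  fb <- transfer_fun(cfg$transfer_b)
  sd_mean <- cfg$noise_sd / sqrt(cfg$n_replicates)
  make_curve <- function(lg, assay, f, bias_mult) {
    occ <- cfg$conc / (cfg$conc + cfg$kd[[lg]])
    mu <- f(cfg$efficacy[[lg]] * bias_mult * occ)
    reps <- matrix(stats::rnorm(length(mu) * cfg$n_replicates, mu,
                                cfg$noise_sd),
                   length(mu), cfg$n_replicates)
    cr_curve(lg, assay, cfg$conc, rowMeans(reps),
             rep(sd_mean, length(mu)), cfg$n_replicates)
  }
  ref <- cfg$ligand_ids[1]
  curves_a <- lapply(cfg$ligand_ids, make_curve, assay = "A", f = fa,
                     bias_mult = 1)
  curves_b <- lapply(cfg$ligand_ids, function(lg)
    make_curve(lg, "B", fb, cfg$bias[[lg]]))
  pa <- assay_panel(curves_a, ref)
  pb <- assay_panel(curves_b, ref)
  if (normalize) {
    pa <- normalize_panel(pa)
    pb <- normalize_panel(pb)
  }
  truth <- data.frame(ligand = cfg$ligand_ids,
                      efficacy = unname(cfg$efficacy),
                      kd = unname(cfg$kd),
                      bias_mult = unname(cfg$bias[cfg$ligand_ids]),
                      true_bias_factor = -log10(unname(cfg$bias[cfg$ligand_ids])),
                      biased = unname(cfg$bias[cfg$ligand_ids]) != 1,
                      stringsAsFactors = FALSE)
  list(panel_a = pa, panel_b = pb,
       kds = ligand_kd(cfg$ligand_ids, log10(unname(cfg$kd))),
       truth = truth)
}

#' Intrinsic activities of a panel
#'
#' Fits a 3-parameter logistic to every ligand and reports each fitted
#' maximum as a fraction of the reference agonist's, with a delta-method SD.
#' The reference ligand's IA is 1 by construction. Ligands whose fitted
#' maximum is extrapolated well beyond the top tested concentration carry a
#' warning (their IA is poorly determined).
#'
#' @param panel An [assay_panel] (normalized or not; IA is scale-free).
#' @param weights Passed to [fit_logistic3].
#' @return Data frame with columns `ligand, assay, ia, ia_sd, warnings`.
#' @export
compute_ia <- function(panel, weights = "none") {
  stopifnot(inherits(panel, "assay_panel"))
  fits <- panel_fits(panel, function(cv, st)
    fit_logistic3(cv, weights = weights, starts = st), ligands(panel))
  ref_fit <- fits[[panel$reference]]
  if (is.null(ref_fit))
    stop(sprintf("reference '%s' fit failed in assay '%s'",
                 panel$reference, panel$assay))
  ref_emax <- ref_fit$par[["e_max"]]
  rows <- lapply(ligands(panel), function(lg) {
    f <- fits[[lg]]
    if (is.null(f))
      return(data.frame(ligand = lg, assay = panel$assay, ia = NA_real_,
                        ia_sd = NA_real_, warnings = "fit failed",
                        stringsAsFactors = FALSE))
    data.frame(ligand = lg, assay = panel$assay,
               ia = f$par[["e_max"]] / ref_emax,
               ia_sd = sqrt(max(f$cov["e_max", "e_max"], 0)) / ref_emax,
               warnings = paste(f$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ia[out$ligand == panel$reference] <- 1
  out
}

#' Write the canonical simulated fixture suite
#'
#' Emits three panel pairs as plain-text CSVs under `dir`: `unbiased` (the
#' default two-pathway system-bias construct), `biased` (one mid-efficacy
#' ligand given a 10-fold efficacy reduction in pathway B), and `duplicate`
#' (the same transfer function in both pathways, independent noise draws -- a
#' negative control mirroring measurement of one response by two analytical
#' means). Also writes the Kd table, per-assay IA tables, and a ground-truth
#' manifest JSON. Files are byte-identical on rerun with the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param biased_ligand Ligand receiving the injected bias.
#' @param bias_mult Efficacy multiplier applied to it in pathway B.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(dir, seed = 1L, biased_ligand = "L06",
                               bias_mult = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- list(
    unbiased = sim_config(),
    biased = sim_config(bias = stats::setNames(bias_mult, biased_ligand)),
    duplicate = sim_config(transfer_b = list(r_max = 1, k_e = 0.03, n = 1)))
  manifest <- list(seed = seed, sets = list())
  for (nm in names(cfgs)) {
    sim <- simulate_panels(cfgs[[nm]], seed = seed + match(nm, names(cfgs)))
    write_cr_csv(list(sim$panel_a, sim$panel_b),
                 file.path(dir, paste0(nm, "_cr.csv")))
    ia <- rbind(compute_ia(sim$panel_a)[, 1:4], compute_ia(sim$panel_b)[, 1:4])
    utils::write.csv(
      data.frame(ligand = ia$ligand, assay = ia$assay,
                 ia = fmt_num(ia$ia), ia_sd = fmt_num(ia$ia_sd)),
      file.path(dir, paste0(nm, "_ia.csv")), row.names = FALSE, quote = FALSE)
    manifest$sets[[nm]] <- list(
      seed = seed + match(nm, names(cfgs)),
      biased_ligands = sim$truth$ligand[sim$truth$biased],
      true_bias_factor = sim$truth$true_bias_factor[sim$truth$biased])
  }
  write_kd_csv(simulate_panels(cfgs$unbiased, seed = seed)$kds,
               file.path(dir, "kd.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
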