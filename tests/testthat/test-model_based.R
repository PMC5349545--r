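# Methods 1-7 share the invariants: zero bias on system-bias-only panels,
# log10(rho) recovery of an injected efficacy ratio rho, exact antisymmetry
# under swapping the two assays, and bias 0 for the reference ligand.

run_method <- function(sim, m) compute_bias(sim$panel_a, sim$panel_b, m, sim$kds)

test_that("system bias alone produces no bias factors (noiseless null)", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 1)
  for (m in 1:7) {
    r <- run_method(sim, m)
    expect_lt(max(abs(r$bias_factor)), 1e-3, label = paste("method", m))
    expect_identical(r$bias_factor[r$ligand == "REF"], 0)
  }
})

test_that("an injected 10-fold efficacy ratio is recovered as bias 1, antisymmetrically", {
  sim <- simulate_panels(small_cfg(noise_sd = 0, bias = c(L04 = 0.1)), seed = 2)
  for (m in 1:7) {
    r <- run_method(sim, m)
    expect_equal(r$bias_factor[r$ligand == "L04"], 1, tolerance = 1e-3,
                 label = paste("method", m))
    expect_lt(max(abs(r$bias_factor[r$ligand != "L04"])), 1e-3)
    # swapping the panels negates every bias factor exactly
    rs <- compute_bias(sim$panel_b, sim$panel_a, m, sim$kds)
    expect_equal(rs$bias_factor, -r$bias_factor, tolerance = 1e-12)
  }
})

test_that("methods 2 and 3 coincide when all Hill slopes are 1", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 3)
  r2 <- bias_method2(sim$panel_a, sim$panel_b)
  r3 <- bias_method3(sim$panel_a, sim$panel_b)
  expect_lt(max(abs(r2$bias_factor - r3$bias_factor)), 1e-3)
})

test_that("method 3 warns when a slope is far from 1", {
  cfg <- small_cfg(noise_sd = 0, transfer_a = list(r_max = 1, k_e = 0.1, n = 2))
  sim <- simulate_panels(cfg, seed = 4)
  r <- bias_method3(sim$panel_a, sim$panel_b)
  expect_true(any(grepl("far from 1", r$warnings)))
})

test_that("identical panels give exactly zero bias for logistic-based methods", {
  sim <- simulate_panels(small_cfg(noise_sd = 0.03), seed = 5)
  for (m in c(3L, 7L)) {
    r <- compute_bias(sim$panel_a, sim$panel_a, m, sim$kds)
    expect_equal(r$bias_factor, rep(0, nrow(r)), tolerance = 1e-12)
  }
})

test_that("equi-effective occupancy ratios recover relative efficacy", {
  f <- fit_logistic3(make_logistic3_curve(e_max = 0.9, ec50 = 1e-7))
  # identical fits and Kd: relative efficacy 1 at every level
  eor <- equieffective_occupancy_ratio(f, f, 1e-6, 1e-6, c(0.2, 0.4, 0.6))
  expect_equal(eor$rel_efficacy, 1, tolerance = 1e-12)
  expect_equal(eor$levels$rel_efficacy, rep(1, 3), tolerance = 1e-12)
  # occupancy at [L] = Kd is one half
  l_eq <- eor$levels$conc_ref[1]
  expect_equal(l_eq / (l_eq + l_eq), 0.5)
  # operational curves with eps_t/eps_r = 0.2, equal Kd and K_E
  kd <- 1e-6; ke <- 0.2
  fr <- fit_logistic3(make_operational_curve(tau = 1 / ke, kd = kd, ligand = "R"))
  ft <- fit_logistic3(make_operational_curve(tau = 0.2 / ke, kd = kd, ligand = "T"))
  eor2 <- equieffective_occupancy_ratio(fr, ft, kd, kd,
                                        seq(0.05, 0.4, length.out = 8))
  expect_equal(eor2$rel_efficacy, 0.2, tolerance = 1e-3)
  expect_error(equieffective_occupancy_ratio(fr, ft, kd, kd, 2), "feasible")
})

test_that("level strategies 4, 5 and 6 agree on noiseless data", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 6)
  r4 <- bias_methods456(sim$panel_a, sim$panel_b, sim$kds, "single_level")
  r5 <- bias_methods456(sim$panel_a, sim$panel_b, sim$kds, "common_range")
  r6 <- bias_methods456(sim$panel_a, sim$panel_b, sim$kds, "optimized_range")
  expect_lt(max(abs(r4$bias_factor - r5$bias_factor)), 1e-6)
  expect_lt(max(abs(r5$bias_factor - r6$bias_factor)), 1e-6)
})

test_that("double-reciprocal slopes measure relative eps/Kd", {
  # test ligand with (eps/Kd)_t = 3 (eps/Kd)_r in both pathways
  kd_r <- 1e-6; kd_t <- 2e-7; eps_t <- 0.6   # 0.6/2e-7 = 3 * 1/1e-6
  for (ke in c(0.05, 0.4)) {
    fr <- fit_logistic3(make_operational_curve(tau = 1 / ke, kd = kd_r, ligand = "R"))
    ft <- fit_logistic3(make_operational_curve(tau = eps_t / ke, kd = kd_t, ligand = "T"))
    top <- min(fr$par[["e_max"]], ft$par[["e_max"]])
    slope <- double_reciprocal_slope(fr, ft, seq(0.1, 0.9, length.out = 10) * top)
    expect_equal(slope, 3, tolerance = 1e-3)
  }
  # identical ligand: slope 1
  f <- fit_logistic3(make_operational_curve(tau = 5, kd = 1e-6))
  expect_equal(double_reciprocal_slope(f, f, seq(0.1, 0.7, length.out = 6)), 1,
               tolerance = 1e-9)
  expect_error(double_reciprocal_slope(f, f, c(0.2, 0.4)), "at least 5")
})

test_that("the bootstrap null band collapses without noise and refuses tiny n_sim", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 7)
  band <- monte_carlo_null_band(sim$panel_a, sim$panel_b, 3, sim$kds,
                                n_sim = 200, seed = 1)
  expect_equal(as.numeric(band), c(0, 0))
  expect_error(monte_carlo_null_band(sim$panel_a, sim$panel_b, 3, sim$kds,
                                     n_sim = 50), "at least 100")
})

test_that("the pooled null band is roughly symmetric about zero and seed-stable", {
  cfg4 <- sim_config(n_ligands = 4L, efficacy = c(1, 0.2, 0.4, 0.7),
                     kd = rep(1e-6, 4), noise_sd = 0.03,
                     conc = 10^seq(-10, -3, length.out = 8))
  sim <- simulate_panels(cfg4, seed = 8)
  band <- monte_carlo_null_band(sim$panel_a, sim$panel_b, 3,
                                n_sim = 2000, seed = 9)
  half <- (band[["ci_high"]] - band[["ci_low"]]) / 2
  centre <- (band[["ci_high"]] + band[["ci_low"]]) / 2
  expect_lt(abs(centre), 0.35 * half)
  band2 <- monte_carlo_null_band(sim$panel_a, sim$panel_b, 3,
                                 n_sim = 2000, seed = 9)
  expect_identical(band, band2)
})

test_that("flags and summaries follow their definitions", {
  res <- structure(data.frame(
    ligand = rep(c("REF", "a", "b", "c", "d", "e"), 2),
    method = 4L,
    assay_a = rep(c("A", "A"), each = 6), assay_b = rep(c("B", "C"), each = 6),
    bias_factor = c(0, 1, -1, 0.1, -0.1, 0.2, 0, 0.6, -0.2, 0.1, 0, 0),
    ci_low = NA_real_, ci_high = NA_real_, flagged = NA,
    warnings = "", stringsAsFactors = FALSE),
    class = c("bias_result", "data.frame"))
  flagged <- apply_null_band(res, c(ci_low = -0.5, ci_high = 0.5), "REF")
  expect_equal(sum(flagged$flagged), 3)   # +1, -1, 0.6
  s <- summarize_methods(flagged, "REF")
  expect_equal(s$hit_rate, 3 / (5 * 2))   # 3 hits / (5 ligands x 2 comparisons)
  two <- summarize_methods(structure(data.frame(
    ligand = c("a", "b"), method = 1L, assay_a = "A", assay_b = "B",
    bias_factor = c(1, -1), ci_low = NA_real_, ci_high = NA_real_,
    flagged = FALSE, warnings = "", stringsAsFactors = FALSE),
    class = c("bias_result", "data.frame")))
  expect_equal(two$rms_deviation, 1)
  expect_error(summarize_methods(res[0, ]), "empty")
})

test_that("ligands without a Kd are skipped with a warning by method 1", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 10)
  kds <- sim$kds[sim$kds$ligand != "L03", ]
  class(kds) <- c("ligand_kd", "data.frame")
  r <- bias_method1(sim$panel_a, sim$panel_b, kds)
  expect_false("L03" %in% r$ligand)
  r2 <- bias_methods456(sim$panel_a, sim$panel_b, kds, "common_range")
  expect_false("L03" %in% r2$ligand)
})

test_that("mismatched reference ligands are a hard error", {
  sim <- simulate_panels(small_cfg(noise_sd = 0), seed = 11)
  pb <- sim$panel_b
  pb$reference <- "L05"
  expect_error(bias_method2(sim$panel_a, pb), "different reference")
})
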