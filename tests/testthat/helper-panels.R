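# Shared fixtures, built in code.

# noiseless logistic3 curve from known parameters
make_logistic3_curve <- function(e_max = 1, n = 1, ec50 = 1e-7,
                                 conc = 10^seq(-10, -4, length.out = 8),
                                 ligand = "L", assay = "X", sd = 0) {
  resp <- e_max / (1 + (ec50 / conc)^n)
  cr_curve(ligand, assay, conc, resp, rep(sd, length(conc)))
}

# noiseless operational-model curve
make_operational_curve <- function(r_max = 1, n = 1, tau = 10, kd = 1e-6,
                                   conc = 10^seq(-10, -3, length.out = 10),
                                   ligand = "L", assay = "X", sd = 0) {
  resp <- r_max * (tau * conc)^n / ((conc + kd)^n + (tau * conc)^n)
  cr_curve(ligand, assay, conc, resp, rep(sd, length(conc)))
}

# small (6-ligand) system-bias-only configuration for fast tests
small_cfg <- function(...) {
  sim_config(n_ligands = 6L,
             efficacy = c(1, 0.08, 0.15, 0.3, 0.5, 0.75),
             kd = 10^seq(-6.3, -5.7, length.out = 6), ...)
}

expect_sigdigits <- function(est, truth, digits = 6) {
  expect_lt(abs(est - truth) / abs(truth), 10^(-digits))
}
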