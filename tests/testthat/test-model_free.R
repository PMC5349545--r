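# Reference trajectory, anisotropic projection, rank-order Monte Carlo and
# ellipse-distance diagnostics.

make_traj <- function(c_a = 1e-8, b_a = 1, c_b = 1e-8, b_b = 1, sd = 0.01,
                      conc = 10^seq(-11, -5, length.out = 9)) {
  mk <- function(assay, c0, b0) {
    resp <- 1 / (1 + (c0 / conc)^b0)
    cr_curve("REF", assay, conc, resp, rep(sd, length(conc)))
  }
  build_trajectory(mk("A", c_a, b_a), mk("B", c_b, b_b))
}

test_that("identical reference curves give the identity trajectory", {
  tr <- make_traj()
  y <- seq(0.05, 0.95, by = 0.05)
  expect_equal(tr$fun(y), y, tolerance = 1e-6)
})

test_that("the closed form matches hand algebra and a parametric sweep", {
  # b = b' = 1, c' = 10 c: Y'(0.5) = 1/11
  tr <- make_traj(c_a = 1e-8, c_b = 1e-7)
  expect_equal(tr$fun(0.5), 1 / 11, tolerance = 1e-6)
  # dense sweep: push concentrations through both fitted logistics and
  # compare with the eliminated closed form
  tr2 <- make_traj(c_a = 3e-9, b_a = 1.4, c_b = 4e-8, b_b = 0.8)
  L <- 10^seq(-12, -4, length.out = 1000)
  y <- predict(tr2$fit_a, L)
  yp <- predict(tr2$fit_b, L)
  expect_lt(max(abs(tr2$fun(y) - yp)), 1e-10)
  # inverse really inverts
  expect_equal(tr2$inv(tr2$fun(0.37)), 0.37, tolerance = 1e-10)
})

test_that("trajectories are monotone with endpoints (0,0) and (1,1)", {
  set.seed(31)
  for (i in 1:20) {
    tr <- make_traj(c_a = 10^runif(1, -9, -7), b_a = runif(1, 0.5, 3),
                    c_b = 10^runif(1, -9, -7), b_b = runif(1, 0.5, 3))
    y <- seq(1e-6, 1 - 1e-6, length.out = 200)
    v <- tr$fun(y)
    expect_true(all(diff(v) > 0))
    expect_identical(tr$fun(0), 0)   # interpolates the endpoints exactly
    expect_identical(tr$fun(1), 1)
  }
})

test_that("projection minimizes the anisotropic distance", {
  tr <- make_traj()   # identity
  # a point on the trajectory projects onto itself
  p0 <- project_point(0.4, 0.4, 0.02, 0.02, tr)
  expect_equal(p0$x, 0.4, tolerance = 1e-5)
  expect_lt(p0$distance, 1e-4)
  # symmetric case: (0.6, 0.4) with equal sds projects to (0.5, 0.5)
  p1 <- project_point(0.6, 0.4, 0.05, 0.05, tr)
  expect_equal(p1$x, 0.5, tolerance = 1e-6)
  expect_equal(p1$distance^2, 2 * (0.1 / 0.05)^2, tolerance = 1e-6)
  expect_error(project_point(0.6, 0.4, 0, 0.05, tr), "positive uncertainties")
})

test_that("the optimizer is never beaten materially by a dense grid search", {
  set.seed(17)
  tr <- make_traj(c_a = 3e-9, b_a = 1.6, c_b = 2e-8, b_b = 0.9)
  grid <- seq(1e-7, 1 - 1e-7, length.out = 1e5)
  ty <- tr$fun(grid)
  for (i in 1:25) {
    ia <- runif(1, 0.05, 1.05); ib <- runif(1, 0.05, 1.05)
    sa <- runif(1, 0.01, 0.1); sb <- runif(1, 0.01, 0.1)
    pr <- project_point(ia, ib, sa, sb, tr)
    brute <- min((grid - ia)^2 / sa^2 + (ty - ib)^2 / sb^2)
    expect_lt(pr$distance^2 - brute, 1e-8)
  }
})

unbiased_pairs <- function(tr, n = 10, sd = 1e-6) {
  y <- seq(0.15, 0.95, length.out = n)
  data.frame(ligand = sprintf("L%02d", seq_len(n)),
             ia_a = y, sd_a = sd, ia_b = tr$fun(y), sd_b = sd,
             stringsAsFactors = FALSE)
}

test_that("rank-order diagnostic: vanishing error keeps all ranks on the diagonal", {
  tr <- make_traj(c_a = 1e-8, c_b = 6e-8, b_b = 1.3)
  pr <- unbiased_pairs(tr)
  r8 <- method8_rank_order(pr, tr, n_mc = 2000, seed = 3)
  expect_equal(unname(r8$observed_ranks[, "rank_a"]),
               unname(r8$observed_ranks[, "rank_b"]))
  expect_false(any(r8$flagged))
  expect_error(method8_rank_order(pr, tr, n_mc = 500), "at least 1000")
})

test_that("rank-order Monte Carlo is bit-reproducible given the seed", {
  tr <- make_traj(c_a = 1e-8, c_b = 6e-8)
  pr <- unbiased_pairs(tr, sd = 0.05)
  a <- method8_rank_order(pr, tr, n_mc = 5000, seed = 12)
  b <- method8_rank_order(pr, tr, n_mc = 5000, seed = 12)
  expect_identical(a$joint_density, b$joint_density)
  expect_identical(a$flagged, b$flagged)
})

test_that("both model-free methods detect a strongly displaced ligand", {
  sim <- simulate_panels(sim_config(noise_sd = 0.02, bias = c(L11 = 0.1)),
                         seed = 21)
  tr <- build_trajectory(sim$panel_a$curves$REF, sim$panel_b$curves$REF)
  pr <- ia_pairs(compute_ia(sim$panel_a), compute_ia(sim$panel_b), "REF")
  r8 <- method8_rank_order(pr, tr, n_mc = 20000, seed = 22)
  expect_true(r8$flagged[["L11"]])
  r9 <- method9_distance(pr, tr)
  expect_true(r9$flagged[r9$ligand == "L11"])
  expect_false(any(r9$flagged[r9$ligand != "L11"]))
})

test_that("distance diagnostic: coincident points are never flagged and it works singly", {
  tr <- make_traj(c_a = 1e-8, c_b = 5e-8, sd = 0.02)
  y0 <- 0.6
  one <- data.frame(ligand = "X", ia_a = y0, sd_a = 0.03,
                    ia_b = tr$fun(y0), sd_b = 0.03, stringsAsFactors = FALSE)
  r <- method9_distance(one, tr)
  expect_equal(nrow(r), 1L)
  expect_false(r$flagged)
  expect_lt(r$distance, 1e-4)
})

test_that("distance flags are invariant under swapping the two assays", {
  sim <- simulate_panels(sim_config(noise_sd = 0.03, bias = c(L09 = 0.15)),
                         seed = 33)
  tr <- build_trajectory(sim$panel_a$curves$REF, sim$panel_b$curves$REF)
  trs <- build_trajectory(sim$panel_b$curves$REF, sim$panel_a$curves$REF)
  ia_a <- compute_ia(sim$panel_a); ia_b <- compute_ia(sim$panel_b)
  r <- method9_distance(ia_pairs(ia_a, ia_b, "REF"), tr)
  rs <- method9_distance(ia_pairs(ia_b, ia_a, "REF"), trs)
  expect_equal(r$flagged[order(r$ligand)], rs$flagged[order(rs$ligand)])
})

test_that("ellipse intersection verdicts are exact on simple geometry", {
  expect_false(ellipses_intersect(c(0, 0), c(1, 1), c(3, 0), c(1, 1)))
  expect_true(ellipses_intersect(c(0, 0), c(1, 1), c(1.5, 0), c(1, 1)))
  expect_true(ellipses_intersect(c(0, 0), c(1, 1), c(2, 0), c(1, 1)))  # touch
  # containment counts as overlap
  expect_true(ellipses_intersect(c(0, 0), c(5, 5), c(1, 0), c(0.5, 0.5)))
  expect_true(ellipses_intersect(c(1, 0), c(0.5, 0.5), c(0, 0), c(5, 5)))
})

test_that("ellipse intersection matches boundary-sampling brute force", {
  brute <- function(c1, ab1, c2, ab2, k = 3600) {
    th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    b2_in_1 <- any(((c2[1] + ab2[1] * cos(th) - c1[1]) / ab1[1])^2 +
                     ((c2[2] + ab2[2] * sin(th) - c1[2]) / ab1[2])^2 <= 1)
    b1_in_2 <- any(((c1[1] + ab1[1] * cos(th) - c2[1]) / ab2[1])^2 +
                     ((c1[2] + ab1[2] * sin(th) - c2[2]) / ab2[2])^2 <= 1)
    ctr <- ((c1[1] - c2[1]) / ab2[1])^2 + ((c1[2] - c2[2]) / ab2[2])^2 <= 1 ||
      ((c2[1] - c1[1]) / ab1[1])^2 + ((c2[2] - c1[2]) / ab1[2])^2 <= 1
    b2_in_1 || b1_in_2 || ctr
  }
  set.seed(41)
  bad <- 0L
  for (i in 1:1000) {
    c1 <- runif(2, -1, 1); c2 <- runif(2, -1, 1)
    ab1 <- runif(2, 0.05, 0.8); ab2 <- runif(2, 0.05, 0.8)
    if (ellipses_intersect(c1, ab1, c2, ab2) != brute(c1, ab1, c2, ab2))
      bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})
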