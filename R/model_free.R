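## The two model-free intrinsic-activity diagnostics: rank-order Monte Carlo
## (method 8) and trajectory-distance with confidence ellipses (method 9).
## Both take per-ligand IA pairs with uncertainties and a reference
## trajectory; outputs are categorical biased/unbiased calls, never a bias
## magnitude.

# ranks of every row of a matrix, ties broken by column (ligand) order;
# vectorized via a single order() call
row_ranks <- function(X) {
  n <- ncol(X); m <- nrow(X)
  o <- order(row(X), X)
  r <- integer(length(X))
  r[o] <- rep.int(seq_len(n), m)
  matrix(r, m, n)
}

#' Assemble an intrinsic-activity pair table for two assays
#'
#' Joins two per-assay IA tables (columns `ligand, assay, ia, ia_sd`, as
#' produced by [compute_ia] or [read_ia_csv]) on ligand id, dropping the
#' reference ligand (it defines the trajectory and is not a test point).
#'
#' @param ia_a,ia_b IA tables for the two assays.
#' @param reference Reference ligand id to drop.
#' @return Data frame with columns `ligand, ia_a, sd_a, ia_b, sd_b`, sorted
#'   by ligand id (the stable tie-break order).
#' @export
ia_pairs <- function(ia_a, ia_b, reference) {
  m <- merge(ia_a[, c("ligand", "ia", "ia_sd")],
             ia_b[, c("ligand", "ia", "ia_sd")],
             by = "ligand", suffixes = c("_a", "_b"))
  names(m) <- c("ligand", "ia_a", "sd_a", "ia_b", "sd_b")
  m <- m[m$ligand != reference, , drop = FALSE]
  m[order(m$ligand), , drop = FALSE]
}

#' Method 8: rank-order Monte Carlo bias diagnostic
#'
#' Projects every test ligand's IA pair onto the reference trajectory; the
#' projected points, lying on a monotone curve, have rank pairs on the
#' identity line. The null sampling distribution of the rank pairs is then
#' simulated: each iteration perturbs the projected coordinates with
#' uncorrelated Gaussian noise matching the ligands' own SDs, re-sorts, and
#' records the resulting rank pair of every position. A ligand is called
#' biased when its observed rank pair falls outside the 95% highest-density
#' region of its own simulated joint rank distribution.
#'
#' @param pairs Data frame from [ia_pairs] (at least ~6 ligands spanning a
#'   range of IA are needed for the ranking to resolve).
#' @param traj A `reference_trajectory`.
#' @param n_mc Monte Carlo iterations (default 500000; at least 1000).
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @param level Mass of the highest-density rank region (default 0.95).
#' @return An object of class `rank_order_result`: `observed_ranks` (per
#'   ligand, ranks of the observed IA in each assay), `projected_ranks`,
#'   `joint_density` (list of rank-pair frequency matrices per ligand),
#'   `contour` (logical matrices marking the HDR), `flagged`, and the
#'   projections.
#' @export
method8_rank_order <- function(pairs, traj, n_mc = 500000L, seed = 1L,
                               level = 0.95) {
  if (n_mc < 1000L) stop("n_mc must be at least 1000")
  n <- nrow(pairs)
  if (n < 3L) stop("rank-order analysis needs at least 3 test ligands")
  if (n < 6L)
    warning("fewer than 6 test ligands; rank-order resolution will be poor")
  proj <- lapply(seq_len(n), function(i)
    project_point(pairs$ia_a[i], pairs$ia_b[i], pairs$sd_a[i], pairs$sd_b[i],
                  traj))
  px <- vapply(proj, `[[`, numeric(1), "x")
  py <- vapply(proj, `[[`, numeric(1), "y")
  # observed and projected ranks; ties broken by stable ligand-id order
  obs_ra <- rank(pairs$ia_a, ties.method = "first")
  obs_rb <- rank(pairs$ia_b, ties.method = "first")
  proj_r <- rank(px, ties.method = "first")
  counts <- lapply(seq_len(n), function(i) matrix(0L, n, n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chunk <- 50000L
  done <- 0L
  while (done < n_mc) {
    m <- min(chunk, n_mc - done)
    X <- matrix(px, m, n, byrow = TRUE) +
      matrix(stats::rnorm(m * n), m, n) *
      matrix(pairs$sd_a, m, n, byrow = TRUE)
    Y <- matrix(py, m, n, byrow = TRUE) +
      matrix(stats::rnorm(m * n), m, n) *
      matrix(pairs$sd_b, m, n, byrow = TRUE)
    RX <- row_ranks(X); RY <- row_ranks(Y)
    for (i in seq_len(n)) {
      idx <- (RX[, i] - 1L) * n + RY[, i]
      tab <- tabulate(idx, nbins = n * n)
      counts[[i]] <- counts[[i]] + matrix(tab, n, n, byrow = TRUE)
    }
    done <- done + m
  }
  dens <- lapply(counts, function(cm) cm / n_mc)
  contour <- lapply(dens, function(dm) {
    o <- order(dm, decreasing = TRUE)
    cs <- cumsum(dm[o])
    k <- which(cs >= level)[1]
    inc <- logical(length(dm)); inc[o[seq_len(k)]] <- TRUE
    matrix(inc, n, n)
  })
  flagged <- vapply(seq_len(n), function(i)
    !contour[[i]][obs_ra[i], obs_rb[i]], logical(1))
  structure(list(ligand = pairs$ligand,
                 observed_ranks = cbind(rank_a = obs_ra, rank_b = obs_rb),
                 projected_ranks = proj_r,
                 joint_density = dens, contour = contour,
                 flagged = stats::setNames(flagged, pairs$ligand),
                 projection = data.frame(ligand = pairs$ligand, x = px, y = py),
                 n_mc = n_mc, seed = seed, level = level),
            class = "rank_order_result")
}

#' @export
print.rank_order_result <- function(x, ...) {
  cat(sprintf("<rank_order_result> %d ligands, %d MC iterations\n",
              length(x$ligand), x$n_mc))
  hits <- names(x$flagged)[x$flagged]
  cat("biased calls:", if (length(hits)) paste(hits, collapse = ", ") else "none", "\n")
  invisible(x)
}

# --- confidence-ellipse geometry (axis-aligned ellipses) ------------------

#' Do two axis-aligned ellipses intersect?
#'
#' Exact test: the first ellipse is affinely scaled to the unit circle (the
#' second stays axis-aligned under the diagonal map), the minimum scaled
#' distance from the circle's centre to the second ellipse's boundary is
#' found by one-dimensional optimization, and containment of either centre is
#' checked so that nested ellipses count as intersecting (overlapping sets).
#'
#' @param c1,c2 Centres, numeric length-2.
#' @param ab1,ab2 Semi-axes `(a, b)` along x and y, all positive.
#' @return `TRUE` if the ellipses (as filled sets) overlap or touch.
#' @export
ellipses_intersect <- function(c1, ab1, c2, ab2) {
  stopifnot(all(ab1 > 0), all(ab2 > 0))
  p <- (c2 - c1) / ab1          # centre of E2 in scaled frame
  A <- ab2[1] / ab1[1]; B <- ab2[2] / ab1[2]
  bnd <- function(th) sqrt((p[1] + A * cos(th))^2 + (p[2] + B * sin(th))^2)
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  v <- bnd(th)
  i <- which.min(v)
  lo <- th[if (i == 1L) length(th) else i - 1L]
  hi <- th[if (i == length(th)) 1L else i + 1L]
  if (lo > hi) { lo <- lo - 2 * pi }
  opt <- stats::optimize(bnd, c(lo, hi), tol = 1e-12)
  dmin <- min(opt$objective, v[i])
  if (dmin <= 1) return(TRUE)
  # no boundary contact: overlapping only if one ellipse contains the other
  origin_in_e2 <- (p[1] / A)^2 + (p[2] / B)^2 <= 1
  center2_in_e1 <- sqrt(sum(p^2)) <= 1
  origin_in_e2 || center2_in_e1
}

#' Method 9: trajectory-distance diagnostic with confidence ellipses
#'
#' Tests, per ligand, whether the observed IA pair deviates significantly
#' from its projection on the reference trajectory. The observed point gets
#' an axis-aligned 95% ellipse from its own SDs (uncorrelated axes); the
#' projected point gets one from the delta-method trajectory band evaluated
#' at the projection. A ligand is called biased when the two ellipses are
#' disjoint. Works for a single test ligand.
#'
#' @param pairs Data frame from [ia_pairs].
#' @param traj A `reference_trajectory`.
#' @param level Ellipse confidence level (default 0.95).
#' @param df Chi-square degrees of freedom of the ellipse radius convention:
#'   2 (default, joint bivariate coverage) or 1 (marginal).
#' @return An object of class `distance_result`: a data frame per ligand with
#'   observed/projected centres, semi-axes, the anisotropic distance, and
#'   `flagged`; plus attributes `level`, `df`.
#' @export
method9_distance <- function(pairs, traj, level = 0.95, df = 2L) {
  k <- sqrt(stats::qchisq(level, df))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- project_point(pairs$ia_a[i], pairs$ia_b[i], pairs$sd_a[i],
                        pairs$sd_b[i], traj)
    if (pr$x < 1e-3 || pr$x > 1 - 1e-3)
      warning(sprintf(
        "ligand '%s': projection at trajectory boundary (Y = %.3g); band ill-defined there",
        pairs$ligand[i], pr$x))
    sx <- max(traj$se_x(pr$y), 1e-12)
    sy <- max(traj$se_y(pr$x), 1e-12)
    obs_ab <- k * c(pairs$sd_a[i], pairs$sd_b[i])
    prj_ab <- k * c(sx, sy)
    inter <- ellipses_intersect(c(pairs$ia_a[i], pairs$ia_b[i]), obs_ab,
                                c(pr$x, pr$y), prj_ab)
    data.frame(ligand = pairs$ligand[i],
               ia_a = pairs$ia_a[i], ia_b = pairs$ia_b[i],
               proj_x = pr$x, proj_y = pr$y, distance = pr$distance,
               obs_semi_x = obs_ab[1], obs_semi_y = obs_ab[2],
               proj_semi_x = prj_ab[1], proj_semi_y = prj_ab[2],
               intersects = inter, flagged = !inter,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, level = level, df = df,
            class = c("distance_result", "data.frame"))
}
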