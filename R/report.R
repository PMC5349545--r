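## End-to-end orchestration: run every applicable diagnostic on a pair of
## panels, attach null bands, summarize, and record provenance so any result
## is regenerable bit-for-bit.

#' Run all bias diagnostics on a pair of assay panels
#'
#' Computes bias factors by every applicable classical method (1-7; the
#' Kd-requiring methods 1, 4, 5, 6 are skipped with a notice when `kds` is
#' absent), attaches the parametric-bootstrap null band and significance
#' flags per method, runs the two model-free diagnostics on the panels'
#' intrinsic activities, and reports the global performance indicators and
#' the inter-method Pearson correlation matrix of bias factors.
#'
#' @param panel_a,panel_b Two [assay_panel]s sharing the reference ligand.
#' @param kds Optional [ligand_kd] table.
#' @param cfg A [bias_config].
#' @param seed Integer seed driving the null band and the rank-order Monte
#'   Carlo.
#' @param methods Which classical methods to run (subset of 1:7).
#' @param model_free Run methods 8 and 9 as well (default `TRUE`).
#' @return An object of class `bias_report`: `results` (pooled `bias_result`
#'   rows for methods 1-7), `bands`, `summary`, `correlations`, `rank_order`,
#'   `distance`, `ia`, `notices`, and a `provenance` block (package version,
#'   seed, config hash).
#' @export
run_all_methods <- function(panel_a, panel_b, kds = NULL,
                            cfg = bias_config(), seed = 1L,
                            methods = 1:7, model_free = TRUE) {
  check_pair(panel_a, panel_b)
  notices <- character()
  need_kd <- c(1L, 4L, 5L, 6L)
  if (is.null(kds) && any(methods %in% need_kd)) {
    skip <- intersect(methods, need_kd)
    notices <- c(notices, sprintf(
      "method %d skipped: requires a ligand Kd table", skip))
    methods <- setdiff(methods, skip)
  }
  results <- list(); bands <- list()
  for (m in methods) {
    res <- compute_bias(panel_a, panel_b, m, kds, cfg)
    band <- monte_carlo_null_band(panel_a, panel_b, m, kds,
                                  n_sim = cfg$n_sim, seed = seed + m, cfg = cfg)
    results[[as.character(m)]] <- apply_null_band(res, band, panel_a$reference)
    bands[[as.character(m)]] <- band
  }
  pooled <- if (length(results)) do.call(rbind, c(results, make.row.names = FALSE))
  rank_res <- dist_res <- NULL
  ia <- NULL
  if (model_free) {
    ia_a <- compute_ia(panel_a, weights = cfg$weights)
    ia_b <- compute_ia(panel_b, weights = cfg$weights)
    ia <- rbind(ia_a, ia_b)
    pairs <- ia_pairs(ia_a, ia_b, panel_a$reference)
    pairs <- pairs[is.finite(pairs$ia_a) & is.finite(pairs$ia_b), , drop = FALSE]
    traj <- build_trajectory(panel_a$curves[[panel_a$reference]],
                             panel_b$curves[[panel_b$reference]],
                             weights = cfg$weights)
    rank_res <- tryCatch(
      method8_rank_order(pairs, traj, n_mc = cfg$n_mc, seed = seed + 8L),
      error = function(e) {
        notices <<- c(notices, paste("method 8 skipped:", conditionMessage(e)))
        NULL
      })
    dist_res <- method9_distance(pairs, traj, df = cfg$ellipse_df)
  }
  correlations <- method_correlations(pooled)
  prov <- list(package = "biasdx",
               version = as.character(utils::packageVersion("biasdx")),
               seed = seed,
               config = unclass(cfg),
               config_hash = config_hash(cfg))
  structure(list(results = pooled, bands = bands,
                 summary = if (!is.null(pooled))
                   summarize_methods(pooled, panel_a$reference),
                 correlations = correlations,
                 rank_order = rank_res, distance = dist_res, ia = ia,
                 notices = notices, provenance = prov),
            class = "bias_report")
}

# Pearson correlations between methods' bias factors over shared ligands;
# zero-variance columns (e.g. duplicate-panel inputs) are reported as NA
method_correlations <- function(pooled) {
  if (is.null(pooled)) return(NULL)
  wide <- stats::reshape(
    pooled[, c("ligand", "assay_a", "assay_b", "method", "bias_factor")],
    idvar = c("ligand", "assay_a", "assay_b"), timevar = "method",
    direction = "wide")
  mat <- as.matrix(wide[, -(1:3), drop = FALSE])
  colnames(mat) <- sub("bias_factor.", "method", colnames(mat))
  if (ncol(mat) < 2L) return(NULL)
  suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report>\n")
  if (!is.null(x$summary)) {
    cat("method summaries (RMS deviation from zero bias; hit rate):\n")
    print(x$summary, row.names = FALSE)
  }
  if (!is.null(x$rank_order)) {
    hits <- names(x$rank_order$flagged)[x$rank_order$flagged]
    cat("rank-order (method 8) biased calls:",
        if (length(hits)) paste(hits, collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$distance)) {
    hits <- x$distance$ligand[x$distance$flagged]
    cat("distance (method 9) biased calls:",
        if (length(hits)) paste(hits, collapse = ", ") else "none", "\n")
  }
  for (n in x$notices) cat("notice:", n, "\n")
  cat(sprintf("provenance: biasdx %s, seed %d, config %s\n",
              x$provenance$version, x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}

#' Write a bias report to CSV and JSON
#'
#' The per-ligand, per-method table goes to `<stem>.csv` (columns
#' `ligand,method,assay_a,assay_b,bias_factor,ci_low,ci_high,flagged,warnings`);
#' summaries, correlations, model-free calls and provenance go to
#' `<stem>.json`.
#'
#' @param report A `bias_report`.
#' @param stem Output path stem (without extension).
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "bias_report"))
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  if (!is.null(report$results))
    utils::write.csv(report$results, csv, row.names = FALSE)
  payload <- list(
    summary = report$summary,
    correlations = report$correlations,
    rank_order_flags = if (!is.null(report$rank_order))
      as.list(report$rank_order$flagged),
    distance_flags = if (!is.null(report$distance))
      stats::setNames(as.list(report$distance$flagged),
                      report$distance$ligand),
    notices = report$notices,
    provenance = report$provenance)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(c(csv, js))
}
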