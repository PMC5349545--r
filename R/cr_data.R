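#' Construct a concentration-response curve
#'
#' A `cr_curve` holds one ligand's averaged concentration-response data in one
#' assay: molar concentrations, mean normalized responses, and the standard
#' deviation of each mean across replicate experiments.
#'
#' @param ligand Ligand identifier (single string).
#' @param assay Assay / pathway identifier (single string).
#' @param conc Numeric vector of molar concentrations, strictly positive.
#' @param resp Numeric vector of mean responses (normalized, dimensionless).
#' @param resp_sd Numeric vector of standard deviations of the mean responses,
#'   same length as `resp`, all `>= 0`. Defaults to zeros (noise-free data).
#' @param n_replicates Number of replicate experiments averaged into `resp`.
#'
#' @details Points are stored sorted by increasing concentration. At least 4
#'   distinct concentrations are required so that a 3-parameter model retains
#'   one residual degree of freedom.
#'
#' @return An object of class `cr_curve`.
#' @export
cr_curve <- function(ligand, assay, conc, resp, resp_sd = NULL,
                     n_replicates = 1L) {
  stopifnot(is.character(ligand), length(ligand) == 1L,
            is.character(assay), length(assay) == 1L)
  conc <- as.numeric(conc); resp <- as.numeric(resp)
  if (is.null(resp_sd)) resp_sd <- numeric(length(resp))
  resp_sd <- as.numeric(resp_sd)
  if (length(conc) != length(resp) || length(conc) != length(resp_sd))
    stop("conc, resp and resp_sd must have equal length")
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be finite and strictly positive (molar)")
  if (any(!is.finite(resp)))
    stop("responses must be finite")
  if (any(resp_sd < 0) || any(!is.finite(resp_sd)))
    stop("resp_sd must be finite and >= 0")
  if (length(unique(conc)) < 4L)
    stop("at least 4 distinct concentrations are required")
  o <- order(conc)
  structure(
    list(ligand = ligand, assay = assay,
         conc = conc[o], resp = resp[o], resp_sd = resp_sd[o],
         n_replicates = as.integer(n_replicates)),
    class = "cr_curve")
}

#' @export
print.cr_curve <- function(x, ...) {
  cat(sprintf("<cr_curve> ligand '%s', assay '%s': %d points, [%g, %g] M\n",
              x$ligand, x$assay, length(x$conc), min(x$conc), max(x$conc)))
  invisible(x)
}

#' Construct an assay panel
#'
#' An `assay_panel` bundles the concentration-response curves of several
#' ligands measured in one assay, together with the identity of the reference
#' (full) agonist used for normalization and bias-factor scaling.
#'
#' @param curves List of [cr_curve] objects, all sharing the same assay id.
#' @param reference Ligand id of the reference agonist; must appear in
#'   `curves`.
#' @return An object of class `assay_panel`. Curves are stored in a named list
#'   keyed by ligand id.
#' @export
assay_panel <- function(curves, reference) {
  stopifnot(is.list(curves), length(curves) > 0L)
  if (!all(vapply(curves, inherits, logical(1), "cr_curve")))
    stop("curves must be a list of cr_curve objects")
  assays <- unique(vapply(curves, `[[`, character(1), "assay"))
  if (length(assays) != 1L)
    stop("all curves in a panel must share one assay id, got: ",
         paste(assays, collapse = ", "))
  ids <- vapply(curves, `[[`, character(1), "ligand")
  if (anyDuplicated(ids))
    stop("duplicate ligand ids in panel: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(curves) <- ids
  if (!reference %in% ids)
    stop(sprintf("reference ligand '%s' not present in panel '%s'",
                 reference, assays))
  structure(list(assay = assays, curves = curves, reference = reference),
            class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel> assay '%s': %d ligands (reference '%s')\n",
              x$assay, length(x$curves), x$reference))
  invisible(x)
}

#' @export
ligands.assay_panel <- function(x, ...) names(x$curves)

#' Ligand ids of an object
#' @param x An object with ligand identifiers (e.g. [assay_panel]).
#' @param ... Unused.
#' @return Character vector of ligand ids.
#' @export
ligands <- function(x, ...) UseMethod("ligands")

#' Ligand dissociation-constant table
#'
#' Equilibrium dissociation constants from binding assays performed in the
#' absence of receptor-transducer interaction, used to constrain the
#' operational-model regression (method 1) and to compute fractional
#' occupancies (methods 4-6).
#'
#' @param ligand Character vector of ligand ids.
#' @param log_kd `log10` of the dissociation constant in molar units.
#' @return A data frame of class `ligand_kd` with columns `ligand`, `log_kd`.
#' @export
ligand_kd <- function(ligand, log_kd) {
  stopifnot(length(ligand) == length(log_kd))
  log_kd <- as.numeric(log_kd)
  if (any(!is.finite(log_kd))) stop("log_kd must be finite")
  bad <- log_kd >= 0
  if (any(bad))
    warning("Kd >= 1 M for ligand(s) ", paste(ligand[bad], collapse = ", "),
            "; implausible but accepted")
  structure(data.frame(ligand = as.character(ligand), log_kd = log_kd,
                       stringsAsFactors = FALSE),
            class = c("ligand_kd", "data.frame"))
}

kd_lookup <- function(kds, ligand) {
  i <- match(ligand, kds$ligand)
  if (is.na(i)) return(NA_real_)
  10^kds$log_kd[i]
}

#' Normalize an assay panel to its reference agonist's fitted maximum
#'
#' Fits a 3-parameter logistic to the reference agonist's curve and divides
#' every response (and every response SD) in the panel by the fitted maximum,
#' so that the reference's fitted E_max becomes 1. The operation is idempotent
#' to within fit tolerance and equivariant under rescaling of the raw data.
#'
#' @param panel An [assay_panel].
#' @param ... Passed to [fit_logistic3] (e.g. `weights`).
#' @return A normalized [assay_panel].
#' @export
normalize_panel <- function(panel, ...) {
  stopifnot(inherits(panel, "assay_panel"))
  ref <- panel$curves[[panel$reference]]
  fit <- tryCatch(fit_logistic3(ref, ...), error = function(e)
    stop(sprintf("normalization failed: reference '%s' fit in assay '%s': %s",
                 panel$reference, panel$assay, conditionMessage(e)),
         call. = FALSE))
  emax <- unname(fit$par["e_max"])
  if (!is.finite(emax) || emax <= 0)
    stop(sprintf("normalization failed: non-finite reference E_max in assay '%s'",
                 panel$assay))
  panel$curves <- lapply(panel$curves, function(cv) {
    cv$resp <- cv$resp / emax
    cv$resp_sd <- cv$resp_sd / emax
    cv
  })
  panel
}

#' Read concentration-response curves from CSV
#'
#' Expects columns `ligand,assay,conc_M,response,resp_sd` and optionally
#' `replicate`. When a `replicate` column is present, rows are averaged over
#' replicates per (ligand, assay, concentration) and `resp_sd` is taken as the
#' standard deviation of the replicate means divided by `sqrt(n)` (SD of the
#' mean); otherwise `resp_sd` is read as given.
#'
#' @param path CSV file path.
#' @param reference Reference ligand id, applied to every panel in the file.
#' @return A named list of [assay_panel] objects, one per assay id.
#' @export
read_cr_csv <- function(path, reference) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "assay", "conc_M", "response")
  if (!all(need %in% names(df)))
    stop("CR CSV must have columns ", paste(need, collapse = ", "))
  if ("replicate" %in% names(df)) {
    sp <- split(df, list(df$ligand, df$assay, df$conc_M), drop = TRUE)
    df <- do.call(rbind, lapply(sp, function(d)
      data.frame(ligand = d$ligand[1], assay = d$assay[1], conc_M = d$conc_M[1],
                 response = mean(d$response),
                 resp_sd = if (nrow(d) > 1)
                   stats::sd(d$response) / sqrt(nrow(d)) else 0,
                 stringsAsFactors = FALSE)))
  } else if (!"resp_sd" %in% names(df)) {
    df$resp_sd <- 0
  }
  panels <- lapply(split(df, df$assay), function(da) {
    curves <- lapply(split(da, da$ligand), function(dl)
      cr_curve(dl$ligand[1], dl$assay[1], dl$conc_M, dl$response, dl$resp_sd))
    assay_panel(unname(curves), reference)
  })
  panels[order(names(panels))]
}

#' Write one or more assay panels to CSV
#'
#' Inverse of [read_cr_csv] for averaged data: columns
#' `ligand,assay,conc_M,response,resp_sd`. Numbers are written with 15
#' significant digits so that a read/write round trip reproduces the panel on
#' the stored decimal representation.
#'
#' @param panels An [assay_panel] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cr_csv <- function(panels, path) {
  if (inherits(panels, "assay_panel")) panels <- list(panels)
  rows <- do.call(rbind, lapply(panels, function(p)
    do.call(rbind, lapply(p$curves, function(cv)
      data.frame(ligand = cv$ligand, assay = cv$assay,
                 conc_M = fmt_num(cv$conc), response = fmt_num(cv$resp),
                 resp_sd = fmt_num(cv$resp_sd), stringsAsFactors = FALSE)))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' Read a ligand Kd table from CSV
#'
#' Expects columns `ligand,log10_Kd_M`.
#'
#' @param path CSV file path.
#' @return A [ligand_kd] table.
#' @export
read_kd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "log10_Kd_M") %in% names(df)))
    stop("Kd CSV must have columns ligand, log10_Kd_M")
  ligand_kd(df$ligand, df$log10_Kd_M)
}

#' Write a ligand Kd table to CSV
#' @param kds A [ligand_kd] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kd_csv <- function(kds, path) {
  utils::write.csv(
    data.frame(ligand = kds$ligand, log10_Kd_M = fmt_num(kds$log_kd)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intrinsic-activity table from CSV
#'
#' Expects columns `ligand,assay,ia,ia_sd`.
#' @param path CSV file path.
#' @return Data frame with those columns.
#' @export
read_ia_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "assay", "ia", "ia_sd") %in% names(df)))
    stop("IA CSV must have columns ligand, assay, ia, ia_sd")
  df
}
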