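#' Read a household survey dataset from CSV
#'
#' Expects one row per individual with columns `household`, `person`,
#' items `y1`..`y12` coded 1-4 (or `NA`), and any of the predictor
#' columns.  Coding violations are reported with row numbers; unknown
#' columns are kept with a warning; household-level predictors must be
#' constant within a household.
#'
#' @param path CSV path (comma-separated, header, UTF-8, `NA` marker).
#' @return A `household_data` data frame.
#' @export
read_household_csv <- function(path) {
  d <- utils::read.csv(path, na.strings = "NA")
  known <- c("household", "person", paste0("y", 1:12),
             .ind_predictors(), .hh_predictors())
  req <- c("household", "person", paste0("y", 1:12))
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(d), known)
  if (length(extra)) warning("unknown columns kept as-is: ",
                             paste(extra, collapse = ", "))
  for (p in paste0("y", 1:12)) {
    bad <- which(!is.na(d[[p]]) & !(d[[p]] %in% 1:4))
    if (length(bad))
      stop(sprintf("invalid codes in column %s (must be 1-4 or NA): rows %s",
                   p, paste(utils::head(bad, 10), collapse = ", ")))
  }
  for (zc in intersect(.hh_predictors(), names(d))) {
    nun <- tapply(d[[zc]], d$household,
                  function(v) length(unique(v[!is.na(v)])))
    if (any(nun > 1, na.rm = TRUE))
      stop(sprintf("household-level column %s varies within household(s): %s",
                   zc, paste(utils::head(names(nun)[which(nun > 1)], 5),
                             collapse = ", ")))
  }
  class(d) <- c("household_data", "data.frame")
  d
}

#' Write a household survey dataset to CSV
#'
#' One row per individual, `NA` as the missing marker.  When the data
#' carry simulation ground truth and `truth_path` is given, the
#' generating parameters and seed are written to a JSON sidecar.
#'
#' @param data A `household_data` data frame.
#' @param path Output CSV path.
#' @param truth_path Optional JSON path for the ground-truth sidecar.
#' @export
write_household_csv <- function(data, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "NA")
  if (!is.null(truth_path)) {
    tr <- attr(data, "truth"); cfg <- attr(data, "config")
    if (is.null(tr)) stop("data carry no ground truth to write")
    side <- list(seed = cfg$seed,
                 loadings = tr$loadings, thresholds = tr$thresholds,
                 theta = tr$theta, psi_ind = tr$psi_ind, psi_hh = tr$psi_hh,
                 beta = as.list(tr$beta), gamma = as.list(tr$gamma))
    jsonlite::write_json(side, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Filter households to the analysis population
#'
#' Drops households containing any member under `min_age` (when an age
#' column is present) and households with fewer than two members, in that
#' order, returning the retained data and per-reason exclusion counts.
#' Exclusions plus retained households always add up to the input.
#'
#' @param data A `household_data` data frame.
#' @param min_age Adult age cut-off (default 16).
#' @return List with `data`, `exclusions` (named counts of households:
#'   `child`, `single`), and `retained` (household count).
#' @export
filter_households <- function(data, min_age = 16) {
  hh <- unique(data$household)
  child_hh <- if ("age" %in% names(data))
    unique(data$household[!is.na(data$age) & data$age < min_age])
  else c()
  d1 <- data[!data$household %in% child_hh, , drop = FALSE]
  size <- table(d1$household)
  single_hh <- names(size)[size < 2]
  out <- d1[!d1$household %in% single_hh, , drop = FALSE]
  if (nrow(out) == 0) warning("all households excluded")
  list(data = out,
       exclusions = c(child = length(child_hh), single = length(single_hh)),
       retained = length(unique(out$household)))
}

#' Listwise deletion over the analysis variables
#'
#' Removes every individual with a missing value on any analysis
#' variable, then drops households reduced below two members — one
#' global policy applied once so every downstream table uses the same
#' analysis set.
#'
#' @param data A `household_data` data frame.
#' @param columns Analysis columns (default: items plus all predictors
#'   present in the data).
#' @return List with `data`, `dropped_individuals`,
#'   `dropped_households_small`.
#' @export
listwise_complete <- function(data, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(c(paste0("y", 1:12), .ind_predictors(),
                           .hh_predictors()), names(data))
  keep <- stats::complete.cases(data[, columns, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  size <- table(d$household)
  small <- names(size)[size < 2]
  out <- d[!d$household %in% small, , drop = FALSE]
  list(data = out, dropped_individuals = sum(!keep),
       dropped_households_small = length(small))
}

# deterministic 32-bit FNV-1a hash of a character scalar, for provenance
.fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply in doubles (split to keep exact arithmetic)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow on a household dataset (or on data
#' simulated from a configuration): population filtering, one global
#' listwise deletion, threshold and polychoric estimation, the DWLS
#' measurement fit with stepwise freeing of error covariances, the
#' structural null model (latent and indicator ICCs), the full two-level
#' structural model, explained variance at both levels, directional
#' hypothesis tests, and collinearity diagnostics.  Deterministic for a
#' fixed seed.
#'
#' @param data A `household_data` data frame, or `NULL` to simulate.
#' @param config A [sim_config()] used when `data` is `NULL`.
#' @param seed Seed recorded in the report and used for simulation when
#'   `config` is `NULL`.
#' @param nodes Quadrature nodes for the structural fits.
#' @param mi_threshold Stepwise modification-index stopping threshold.
#' @param max_free Cap on stepwise-freed error covariances.
#' @param structural If `FALSE`, stop after the null model and ICC
#'   sections (no structural fit or predictor diagnostics).
#' @param indicator_icc_nodes Quadrature nodes for the per-item ICC fits.
#' @return Object of class `msem_report`.
#' @export
run_full_analysis <- function(data = NULL, config = NULL, seed = 1,
                              nodes = 15, mi_threshold = 3.84,
                              max_free = 20, structural = TRUE,
                              indicator_icc_nodes = 15) {
  if (is.null(data)) {
    if (is.null(config)) config <- sim_config(seed = seed)
    data <- simulate_households(config)
    seed <- config$seed
  }
  n0 <- nrow(data); h0 <- length(unique(data$household))
  flt <- filter_households(data)
  lw <- listwise_complete(flt$data)
  d <- lw$data
  items <- paste0("y", 1:12)

  freq <- t(vapply(items, function(p) tabulate(d[[p]], 4), integer(4)))
  colnames(freq) <- paste0("cat", 1:4)

  polymat <- polychoric(d, items)
  sw <- stepwise_free_covariances(polymat, threshold = mi_threshold,
                                  max_steps = max_free)
  meas_fit <- sw$fit
  meas <- measurement_from_cfa(meas_fit, polymat)

  nullfit <- msem_null(d, meas, nodes = nodes)
  icc_latent <- latent_icc(nullfit$psi[["hh"]], nullfit$psi[["ind"]])
  icc_items <- vapply(items, function(p)
    as.numeric(indicator_icc(d, p, nodes = indicator_icc_nodes)), 0)

  report <- list(
    data_summary = list(
      input = c(individuals = n0, households = h0),
      exclusions = flt$exclusions,
      listwise_dropped = lw$dropped_individuals,
      households_below_two = lw$dropped_households_small,
      analysed = c(individuals = nrow(d),
                   households = length(unique(d$household))),
      response_frequencies = freq),
    polychoric = polymat,
    measurement = list(fit = meas_fit, stepwise_trail = sw$trail,
                       freed_covariances = sw$free_cov,
                       indices = meas_fit$indices),
    null_model = list(psi_ind = nullfit$psi[["ind"]],
                      psi_hh = nullfit$psi[["hh"]],
                      fit = nullfit),
    icc = list(latent = icc_latent, indicators = icc_items,
               indicator_complements = 1 - icc_items),
    provenance = list(seed = seed,
                      config_hash = .fnv1a(paste(deparse(
                        if (is.null(config)) "external-data" else
                          unclass(config)), collapse = "")),
                      package_version =
                        as.character(utils::packageVersion("mlsem")),
                      timestamp = NA))
  if (structural) {
    fullfit <- msem(d, meas, nodes = nodes)
    ev_ind <- explained_variance(nullfit$psi[["ind"]], fullfit$psi[["ind"]])
    ev_hh <- explained_variance(nullfit$psi[["hh"]], fullfit$psi[["hh"]])
    report$structural <- list(fit = fullfit, summary = summary(fullfit)$table,
                              hypotheses = hypothesis_tests(fullfit),
                              standardized = standardized_coefs(fullfit))
    report$explained_variance <- list(individual = ev_ind, household = ev_hh)
    report$diagnostics <- list(
      collinearity = collinearity(d),
      correlations = predictor_correlations(d))
  }
  class(report) <- "msem_report"
  report
}

#' @export
print.msem_report <- function(x, digits = 3, ...) {
  cat("==== Multilevel latent-morbidity analysis report ====\n")
  ds <- x$data_summary
  cat(sprintf("Data: %d individuals / %d households analysed (input %d/%d;\n",
              ds$analysed["individuals"], ds$analysed["households"],
              ds$input["individuals"], ds$input["households"]))
  cat(sprintf("  excluded households: %d with children, %d single;",
              ds$exclusions["child"], ds$exclusions["single"]))
  cat(sprintf(" %d individuals listwise-deleted)\n", ds$listwise_dropped))
  cat("\n-- Measurement model (DWLS) --\n")
  print(x$measurement$fit)
  cat(sprintf("  stepwise-freed error covariances: %d\n",
              nrow(x$measurement$fit$error_cov)))
  cat("\n-- Variance decomposition (null model) --\n")
  cat(sprintf("  psi_ind(null) = %.4f, psi_hh(null) = %.4f, latent ICC = %.3f\n",
              x$null_model$psi_ind, x$null_model$psi_hh, x$icc$latent))
  cat(sprintf("  indicator ICCs: %.3f - %.3f\n",
              min(x$icc$indicators), max(x$icc$indicators)))
  if (!is.null(x$structural)) {
    cat("\n-- Structural model --\n")
    print(x$structural$fit)
    cat(sprintf("  explained variance: individual %.1f%%, household %.1f%%\n",
                100 * x$explained_variance$individual,
                100 * x$explained_variance$household))
  }
  cat(sprintf("\nSeed %s; config hash %s; mlsem %s\n", x$provenance$seed,
              x$provenance$config_hash, x$provenance$package_version))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (numeric results), `polychoric.csv` (the
#' correlation matrix), and `report.md` (the printed human-readable
#' report) under `dir`.
#'
#' @param report An `msem_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(
    data_summary = report$data_summary[c("input", "exclusions",
                                         "listwise_dropped", "analysed")],
    measurement = list(
      loadings = as.list(report$measurement$fit$loadings),
      std_loadings = as.list(report$measurement$fit$std_loadings),
      psi = report$measurement$fit$psi,
      chisq = report$measurement$fit$chisq, df = report$measurement$fit$df,
      indices = unclass(report$measurement$fit$indices),
      n_freed_covariances = nrow(report$measurement$fit$error_cov)),
    null_model = report$null_model[c("psi_ind", "psi_hh")],
    icc = list(latent = report$icc$latent,
               indicators = as.list(report$icc$indicators)),
    provenance = report$provenance)
  if (!is.null(report$structural)) {
    f <- report$structural$fit
    js$structural <- list(coefficients = as.list(coef(f)),
                          se = as.list(f$se),
                          psi_ind = f$psi[["ind"]], psi_hh = f$psi[["hh"]],
                          loglik = f$loglik, aic = f$aic, bic = f$bic)
    js$explained_variance <- report$explained_variance
    js$diagnostics <- list(
      vif = as.list(stats::setNames(report$diagnostics$collinearity$vif,
                                    report$diagnostics$collinearity$predictor)),
      tolerance = as.list(stats::setNames(
        report$diagnostics$collinearity$tolerance,
        report$diagnostics$collinearity$predictor)),
      max_abs_predictor_correlation = max(abs(
        report$diagnostics$correlations[lower.tri(
          report$diagnostics$correlations)]), na.rm = TRUE))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$polychoric$rho, file.path(dir, "polychoric.csv"))
  md <- utils::capture.output(print(report))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
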