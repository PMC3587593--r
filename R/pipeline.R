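#' Whole-city occupancy analysis
#'
#' Fits the two whole-city candidate models — constant
#' `psi(.)p(.)` and habitat cell-means `psi(Habitat)p(.)` — ranks them by
#' AICc, evaluates the top model's in-sample AUC, and projects occupied
#' area over the habitat extents.
#'
#' @param data An [occu_data] object containing all five habitats.
#' @param habitat_areas Hectares per habitat; defaults to the areas stored
#'   on `data`, if any.
#' @param options [fit_options()] for the underlying fits.
#' @return An `occu_report`: list with `comparison` (ranked table), `fits`,
#'   `estimates` (per-habitat psi and p of the top model), `projection`
#'   (occupied-area table), `auc`, `naive`, and `provenance`.
#' @export
run_all_habitats_analysis <- function(data, habitat_areas = data$habitat_areas,
                                      options = fit_options()) {
  stopifnot(inherits(data, "occu_data"))
  present <- as.character(unique(data$sites$habitat))
  absent <- setdiff(habitat_levels(), present)
  if (length(absent)) {
    stop("missing habitat level(s): ", paste(absent, collapse = ", "),
      call. = FALSE)
  }
  build_report(data, all_habitats_model_set(), habitat_areas, options,
    analysis = "all_habitats")
}

#' Residential-subset occupancy analysis
#'
#' Subsets the data to the three residential habitat classes (dropping
#' forest and amenity sites, whose food covariate is structurally zero and
#' would cause separation), fits the eight candidate covariate models with
#' constant detection, ranks them by AICc, and reports the top model's
#' coefficients, AUC, and occupied-area projection over the residential
#' extents.
#'
#' @inheritParams run_all_habitats_analysis
#' @return An `occu_report` (see [run_all_habitats_analysis()]), with an
#'   additional `coefficients` table for the top model.
#' @export
run_residential_analysis <- function(data, habitat_areas = data$habitat_areas,
                                     options = fit_options()) {
  stopifnot(inherits(data, "occu_data"))
  keep <- data$sites$habitat %in% residential_levels()
  if (!any(keep)) stop("no residential sites in data", call. = FALSE)
  sub <- occu_data(
    data$sites[keep, , drop = FALSE],
    habitat_areas = {
      ha <- habitat_areas
      if (!is.null(ha)) ha[names(ha) %in% residential_levels()] else NULL
    }
  )
  if (is.null(sub$sites$food) || is.null(sub$sites$forest_area)) {
    stop("residential analysis requires food and forest_area covariates",
      call. = FALSE)
  }
  build_report(sub, residential_model_set(), sub$habitat_areas, options,
    analysis = "residential")
}

# shared report assembly for both analyses
build_report <- function(data, specs, habitat_areas, options, analysis) {
  fits <- lapply(specs, function(s) {
    f <- fit_occu(data, s, options = options)
    message(sprintf(
      "fitted %-35s logL = %9.3f  converged = %s  boundary = %d",
      s$name, f$logL, f$converged, sum(f$boundary)
    ))
    f
  })
  names(fits) <- vapply(specs, `[[`, character(1), "name")
  comparison <- rank_models(fits)
  top <- fits[[comparison$name[1]]]

  estimates <- psi_by_habitat(top, data)
  if (!is.null(top$p_estimate)) {
    estimates$p <- top$p_estimate["estimate"]
    estimates$p_se <- top$p_estimate["se"]
  }

  projection <- if (!is.null(habitat_areas)) {
    occupied_area_table(estimates, habitat_areas)
  }
  auc <- evaluate_fit_auc(top, data)

  structure(
    list(
      analysis = analysis,
      comparison = comparison,
      fits = fits,
      top_model = comparison$name[1],
      estimates = estimates,
      coefficients = data.frame(
        coefficient = names(top$coefficients),
        estimate = as.numeric(top$coefficients),
        se = as.numeric(top$se),
        boundary = top$boundary,
        stringsAsFactors = FALSE
      ),
      projection = projection,
      auc = auc,
      naive = detection_summary(data),
      provenance = list(
        n_sites = nrow(data$sites), J = data$J,
        options = options,
        package_version = as.character(utils::packageVersion("occufit"))
      )
    ),
    class = "occu_report"
  )
}

#' @export
print.occu_report <- function(x, ...) {
  cat(sprintf(
    "occupancy analysis (%s): %d sites, %d replicates\n\n",
    x$analysis, x$provenance$n_sites, x$provenance$J
  ))
  cat("model comparison (AICc):\n")
  print(format_comparison(x$comparison), row.names = FALSE)
  cat("\ntop model:", x$top_model, "\n")
  est <- x$estimates
  est$psi <- round(est$psi, 2)
  est$se <- round(est$se, 2)
  if (!is.null(est$p)) {
    est$p <- round(est$p, 2)
    est$p_se <- round(est$p_se, 2)
  }
  print(est, row.names = FALSE)
  if (!is.null(x$projection)) {
    cat("\noccupied-area projection:\n")
    proj <- x$projection
    proj$psi <- round(proj$psi, 2)
    proj$occupied_ha <- round(proj$occupied_ha, 1)
    print(proj, row.names = FALSE)
  }
  cat(sprintf("\nin-sample AUC of top model: %.3f\n", x$auc$auc))
  invisible(x)
}

#' Write an analysis report to delimited files
#'
#' Emits `comparison.csv`, `estimates.csv`, `projection.csv` (when areas
#' were supplied), `naive.csv`, `coefficients.csv` and a `manifest.txt`
#' recording seed-relevant provenance.
#'
#' @param report An `occu_report`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "occu_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(dir, file),
      sep = ",", row.names = FALSE, quote = FALSE, na = "NA"
    )
  }
  wr(report$comparison, "comparison.csv")
  wr(report$estimates, "estimates.csv")
  if (!is.null(report$projection)) wr(report$projection, "projection.csv")
  wr(report$naive, "naive.csv")
  wr(report$coefficients, "coefficients.csv")
  writeLines(c(
    sprintf("analysis: %s", report$analysis),
    sprintf("top_model: %s", report$top_model),
    sprintf("auc: %.6f", report$auc$auc),
    sprintf("n_sites: %d", report$provenance$n_sites),
    sprintf("J: %d", report$provenance$J),
    sprintf("fit_seed: %d", report$provenance$options$seed),
    sprintf("occufit_version: %s", report$provenance$package_version)
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}
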