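#' Naive occupancy: fraction of sites with at least one detection
#'
#' The naive estimate ignores imperfect detection, so it is biased downward
#' relative to the model-based psi whenever the per-replicate detection
#' probability is below one.
#'
#' @param x An [occu_data] object, or a [detection_summary()] data frame
#'   (columns `habitat`, `sites`, `detected`).
#' @param by_habitat If `TRUE`, return one proportion per habitat; else the
#'   overall proportion.
#' @return Named numeric vector (per habitat) or a single proportion.
#' @examples
#' s <- data.frame(
#'   habitat = c("Forest", "Res1"), sites = c(30, 30), detected = c(28, 12)
#' )
#' naive_occupancy(s) # 40/60
#' @export
naive_occupancy <- function(x, by_habitat = FALSE) {
  if (inherits(x, "occu_data")) {
    x <- detection_summary(x)
  }
  stopifnot(is.data.frame(x), all(c("habitat", "sites", "detected") %in% names(x)))
  if (any(x$sites == 0)) stop("empty habitat group", call. = FALSE)
  if (by_habitat) {
    stats::setNames(x$detected / x$sites, x$habitat)
  } else {
    sum(x$detected) / sum(x$sites)
  }
}

#' Rank-based (Mann-Whitney) area under the ROC curve
#'
#' The probability that a randomly chosen detected site receives a higher
#' score than a randomly chosen undetected site, with tied pairs counted
#' one half. Computed from midranks, which is exactly the all-pairs
#' concordance count; ties matter here because model scores are constant
#' within a habitat.
#'
#' @param scores Numeric per-site scores (e.g. predicted psi).
#' @param labels Binary per-site outcome (1 = detected at least once).
#' @return List of class `occu_auc` with `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc # 1
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg), class = "occu_auc")
}

#' @export
print.occu_auc <- function(x, ...) {
  cat(sprintf(
    "ROC AUC = %.3f  (%d detected vs %d undetected sites)\n",
    x$auc, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' In-sample AUC of a fitted occupancy model
#'
#' Scores every site by its fitted psi and labels it by observed detection
#' (at least one positive replicate), then calls [roc_auc()].
#'
#' @param fit An `occu_fit` object.
#' @param data The [occu_data] the model was fitted to.
#' @return An `occu_auc` object.
#' @export
evaluate_fit_auc <- function(fit, data) {
  stopifnot(inherits(fit, "occu_fit"), inherits(data, "occu_data"))
  roc_auc(fit$psi, as.numeric(site_detected(data)))
}

#' Project occupied area from habitat extents
#'
#' Multiplies each habitat's occupancy estimate by its extent in hectares,
#' `occupied_ha = psi * area_ha`, and appends a total row (summed on
#' unrounded values).
#'
#' @param psi Named numeric vector of occupancy estimates per habitat, or
#'   a data frame with columns `habitat`, `psi` (optionally `se`).
#' @param habitat_areas Named numeric vector of hectares per habitat.
#' @return Data frame with columns `habitat`, `area_ha`, `psi`,
#'   `occupied_ha`; the last row is the total.
#' @examples
#' occupied_area_table(
#'   c(Res2 = 0.23),
#'   c(Res2 = 1921)
#' ) # 441.83 ha
#' @export
occupied_area_table <- function(psi, habitat_areas) {
  if (is.data.frame(psi)) {
    psi <- stats::setNames(psi$psi, psi$habitat)
  }
  if (any(habitat_areas < 0)) stop("negative habitat area", call. = FALSE)
  habs <- names(habitat_areas)
  missing_psi <- setdiff(habs, names(psi))
  if (length(missing_psi)) {
    stop("no psi estimate for habitat(s): ",
      paste(missing_psi, collapse = ", "), call. = FALSE)
  }
  psi <- psi[habs]
  out <- data.frame(
    habitat = habs,
    area_ha = as.numeric(habitat_areas),
    psi = as.numeric(psi),
    occupied_ha = as.numeric(psi) * as.numeric(habitat_areas),
    stringsAsFactors = FALSE
  )
  total <- data.frame(
    habitat = "Total",
    area_ha = sum(out$area_ha),
    psi = NA_real_,
    occupied_ha = sum(out$occupied_ha),
    stringsAsFactors = FALSE
  )
  rbind(out, total)
}
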