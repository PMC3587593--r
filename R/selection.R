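#' Small-sample corrected Akaike information criterion
#'
#' `AICc = deviance + 2K + 2K(K + 1) / (n - K - 1)`, where `deviance` is
#' -2 times the maximised log-likelihood and `n` is the effective sample
#' size. For replicated occupancy surveys the effective sample size is the
#' number of sites, not site-by-replicate observations.
#'
#' @param deviance -2 logL of the fitted model.
#' @param K Number of estimated parameters.
#' @param n Effective sample size (sites); must exceed `K + 1`.
#' @return The corrected criterion value.
#' @examples
#' aicc(133.92, 6, 90) # 146.93
#' @export
aicc <- function(deviance, K, n) {
  if (any(n <= K + 1)) {
    stop("AICc undefined: need n > K + 1", call. = FALSE)
  }
  deviance + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank candidate models by AICc
#'
#' Computes AICc differences (`delta = AICc - min AICc`), model likelihoods
#' `exp(-delta / 2)` and Akaike weights (model likelihoods normalised to
#' sum to one), and sorts ascending by AICc with ties broken by smaller
#' `K`, then name.
#'
#' @param models Either a list of `occu_fit` objects or a data frame with
#'   columns `name`, `K`, `deviance` (AICc computed internally from `n`)
#'   or columns `name` and `AICc` (used as given).
#' @param n Effective sample size, required when AICc must be computed
#'   from deviances; for a list of fits it defaults to each fit's own `n`.
#' @return Data frame with columns `name`, `AICc`, `delta`, `weight`,
#'   `model_likelihood`, `K`, `deviance`, sorted by AICc.
#' @examples
#' rank_models(data.frame(
#'   name = c("a", "b"), AICc = c(146.93, 147.96),
#'   K = c(6, 4), deviance = c(133.92, 139.49)
#' ))
#' @export
rank_models <- function(models, n = NULL) {
  if (is.list(models) && !is.data.frame(models) &&
    all(vapply(models, inherits, logical(1), "occu_fit"))) {
    rows <- data.frame(
      name = vapply(models, function(f) f$spec$name, character(1)),
      K = vapply(models, `[[`, numeric(1), "K"),
      deviance = vapply(models, `[[`, numeric(1), "deviance"),
      stringsAsFactors = FALSE
    )
    nn <- if (is.null(n)) vapply(models, `[[`, numeric(1), "n") else n
    rows$AICc <- aicc(rows$deviance, rows$K, nn)
  } else {
    rows <- as.data.frame(models, stringsAsFactors = FALSE)
    if (is.null(rows$AICc)) {
      if (is.null(n)) stop("n required to compute AICc from deviances",
        call. = FALSE)
      rows$AICc <- aicc(rows$deviance, rows$K, n)
    }
  }
  if (nrow(rows) < 1L) stop("at least one model required", call. = FALSE)
  if (any(!is.finite(rows$AICc))) stop("non-finite AICc", call. = FALSE)
  if (is.null(rows$K)) rows$K <- NA_real_
  if (is.null(rows$deviance)) rows$deviance <- NA_real_

  rows$delta <- rows$AICc - min(rows$AICc)
  rows$model_likelihood <- exp(-rows$delta / 2)
  rows$weight <- rows$model_likelihood / sum(rows$model_likelihood)
  ord <- order(rows$AICc, rows$K, rows$name)
  rows <- rows[ord, c(
    "name", "AICc", "delta", "weight", "model_likelihood", "K", "deviance"
  )]
  rownames(rows) <- NULL
  rows
}

#' Format a model-comparison table for display
#'
#' Rounds to the conventional precision (AICc/delta/deviance 2 dp,
#' weights 2 dp, model likelihood 4 dp); full precision is retained in the
#' [rank_models()] output itself.
#'
#' @param ranking Output of [rank_models()].
#' @return Data frame of formatted columns.
#' @export
format_comparison <- function(ranking) {
  data.frame(
    Model = ranking$name,
    AICc = sprintf("%.2f", ranking$AICc),
    delta = sprintf("%.2f", ranking$delta),
    weight = sprintf("%.2f", ranking$weight),
    model_likelihood = sprintf("%.4f", ranking$model_likelihood),
    K = ranking$K,
    deviance = sprintf("%.2f", ranking$deviance),
    stringsAsFactors = FALSE
  )
}
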