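#' Numerically stable inverse logit
#'
#' Maps a logit-scale value to a probability, `1 / (1 + exp(-x))`, without
#' overflow for large `|x|`.
#'
#' @param x Numeric vector of finite values.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' inverse_logit(0)     # 0.5
#' inverse_logit(40)    # 1 to machine precision
#' @export
inverse_logit <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  stats::plogis(x)
}

#' Log-likelihood of one site's detection history
#'
#' The single-season occupancy likelihood marginalises the latent occupancy
#' state: a history with at least one detection can only come from an
#' occupied site and contributes
#' `psi * prod(p_j^y_j * (1 - p_j)^(1 - y_j))`; an all-zero history is a
#' mixture of an occupied-but-undetected site and an unoccupied one,
#' `psi * prod(1 - p_j) + (1 - psi)`. Missing replicates are skipped.
#'
#' @param y Detection history: vector over replicates with elements 0, 1 or
#'   `NA`.
#' @param psi Occupancy probability for the site.
#' @param p Detection probability per replicate; scalar or length of `y`.
#' @return The log of the site's marginal likelihood.
#' @examples
#' site_log_likelihood(c(1, 0, 1), psi = 1, p = 0.5)  # log(0.125)
#' @export
site_log_likelihood <- function(y, psi, p) {
  if (psi < 0 || psi > 1 || any(p < 0 | p > 1)) {
    stop("psi and p must lie in [0, 1]", call. = FALSE)
  }
  p <- rep_len(p, length(y))
  obs <- !is.na(y)
  y <- y[obs]
  p <- p[obs]
  cond <- prod(ifelse(y == 1, p, 1 - p)) # detection prob given occupied
  if (any(y == 1)) {
    log(psi * cond)
  } else {
    log(psi * cond + (1 - psi))
  }
}

# Vectorised negative log-likelihood machinery -------------------------------

# Precompute the pieces of the dataset likelihood that do not depend on the
# parameters, so the optimiser's objective is cheap.
likelihood_context <- function(data, spec) {
  dm <- build_design_matrices(data, spec)
  Y <- detection_matrix(data)
  obs <- !is.na(Y)
  list(
    X_psi = dm$X_psi,
    X_p = dm$X_p,
    K = dm$K,
    q = ncol(dm$X_psi),
    Y = Y,
    obs = obs,
    ndet = rowSums(Y == 1, na.rm = TRUE), # detections per site
    nmiss0 = rowSums(obs & Y == 0), # observed non-detections per site
    singular = c(attr(dm$X_psi, "singular"), attr(dm$X_p, "singular"))
  )
}

# Dataset log-likelihood from a context and a coefficient vector
# params = (beta over X_psi columns, alpha over X_p columns).
# fix_p: optional probability overriding the p linear predictor entirely.
context_log_likelihood <- function(params, ctx, fix_p = NULL) {
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  beta <- params[seq_len(ctx$q)]
  psi <- stats::plogis(drop(ctx$X_psi %*% beta))
  if (is.null(fix_p)) {
    alpha <- params[-seq_len(ctx$q)]
    p <- stats::plogis(drop(ctx$X_p %*% alpha))
  } else {
    # fixed p is clamped just inside (0, 1): at p exactly 1 a mixed history
    # has probability zero for every psi, but the limit keeps the argmax
    # (the vanishing factor is constant in psi)
    p <- rep_len(min(max(fix_p, 1e-12), 1 - 1e-9), nrow(ctx$X_psi))
  }
  # p is per site, shared across replicates; binomial kernel given occupied
  log_cond <- ctx$ndet * log(p) + ctx$nmiss0 * log1p(-p)
  cond <- exp(log_cond)
  lik <- ifelse(ctx$ndet > 0, psi * cond, psi * cond + (1 - psi))
  sum(log(lik))
}

#' Dataset log-likelihood at given coefficients
#'
#' Sums [site_log_likelihood()] over sites, with
#' `psi_i = inverse_logit(X_psi[i, ] %*% beta)` and
#' `p_i = inverse_logit(X_p[i, ] %*% alpha)` shared across the site's
#' replicates. Sites are independent (replicate detectors are spaced to
#' avoid one animal triggering several).
#'
#' @param params Coefficient vector of length `K`: the psi coefficients in
#'   design-column order followed by the p coefficients.
#' @param data An [occu_data] object.
#' @param spec An [model_spec()] object or model-name string.
#' @return The dataset log-likelihood (a scalar).
#' @export
dataset_log_likelihood <- function(params, data, spec) {
  ctx <- suppressWarnings(likelihood_context(data, spec))
  if (length(params) != ctx$K) {
    stop(sprintf("params must have length K = %d", ctx$K), call. = FALSE)
  }
  context_log_likelihood(params, ctx)
}
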