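#' Optimiser settings for occupancy fits
#'
#' @param starts Number of optimisation starts: the first is all-zero
#'   coefficients, the rest are seeded random perturbations.
#' @param bound Box constraint on every coefficient, on the logit scale.
#'   Keeps the likelihood finite under complete separation (a habitat with
#'   all, or no, detections); a coefficient ending on the bound is reported
#'   as a boundary estimate rather than an interior MLE.
#' @param factr Convergence tolerance passed to `optim`'s L-BFGS-B
#'   (`factr * .Machine$double.eps` on the objective; the default
#'   corresponds to ~1e-8 absolute on log-likelihoods of this magnitude).
#' @param seed Integer seed for the random starts.
#' @param boundary_tol A coefficient within this distance of the box is
#'   flagged as boundary.
#' @return List of settings for [fit_occu()].
#' @export
fit_options <- function(starts = 5L, bound = 15, factr = 1e4, seed = 1L,
                        boundary_tol = 1e-3) {
  stopifnot(starts >= 1L, bound > 0, factr > 0)
  list(
    starts = as.integer(starts), bound = bound, factr = factr,
    seed = as.integer(seed), boundary_tol = boundary_tol
  )
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Maximises the zero-inflated binomial occupancy likelihood over
#' logit-scale coefficients constrained to `[-bound, bound]`, using
#' L-BFGS-B with numerical gradients and multiple starts. Standard errors
#' come from the numerically differentiated observed information at the
#' optimum; coefficients on the box (separation, e.g. a habitat with no
#' detections) are flagged as boundary estimates and their standard errors
#' reported as 0. Ties between equally good starts are broken by the
#' smaller coefficient norm.
#'
#' @param data An [occu_data] object.
#' @param spec An [model_spec()] object or `"psi(...),p(.)"` name string.
#' @param options Settings from [fit_options()].
#' @param fix_p Optional known detection probability; when given, only the
#'   psi coefficients are estimated (used for design diagnostics such as
#'   the perfect-detection limit, where the psi MLE equals naive
#'   occupancy).
#' @return An object of class `occu_fit`: coefficients (`beta` for psi,
#'   `alpha` for p), `logL`, `deviance` (= -2 logL), `K`, `n`, `vcov`
#'   (zeroed on boundary rows/columns), `se`, `boundary` flags,
#'   `converged`, per-site fitted `psi` and `p`, and the probability-scale
#'   `p_estimate` with delta-method SE.
#' @examples
#' d <- simulate_occu(default_config(), seed = 7)
#' f <- fit_occu(d, "psi(Habitat)p(.)")
#' f
#' @export
fit_occu <- function(data, spec, options = fit_options(), fix_p = NULL) {
  if (is.character(spec)) spec <- parse_model_name(spec)
  ctx <- withCallingHandlers(
    likelihood_context(data, spec),
    warning = function(w) invokeRestart("muffleWarning")
  )
  n <- nrow(ctx$X_psi)
  q <- ctx$q
  npar <- if (is.null(fix_p)) ctx$K else q

  nll <- function(par) {
    ll <- context_log_likelihood(par, ctx, fix_p = fix_p)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # deterministic multi-start; leave the caller's RNG untouched
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(options$seed)
  start_points <- c(
    list(rep(0, npar)),
    lapply(seq_len(options$starts - 1L), function(i) {
      stats::rnorm(npar, 0, 2)
    })
  )

  runs <- lapply(start_points, function(s) {
    tryCatch(
      stats::optim(s, nll,
        method = "L-BFGS-B",
        lower = rep(-options$bound, npar), upper = rep(options$bound, npar),
        control = list(factr = options$factr, maxit = 500L)
      ),
      error = function(e) list(value = Inf, par = s, convergence = 99L)
    )
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best_val <- min(vals)
  # equal optima (within objective tolerance): prefer smallest coef norm
  near <- which(vals <= best_val + 1e-8)
  norms <- vapply(runs[near], function(r) sqrt(sum(r$par^2)), numeric(1))
  best <- runs[[near[which.min(norms)]]]
  converged <- is.finite(best$value) && best$convergence == 0L

  par <- best$par
  boundary <- abs(abs(par) - options$bound) <= options$boundary_tol
  names(boundary) <- NULL

  coef_names <- c(
    paste0("psi_", colnames(ctx$X_psi)),
    if (is.null(fix_p)) paste0("p_", colnames(ctx$X_p))
  )
  names(par) <- coef_names

  # observed information over interior coefficients only; boundary
  # coefficients have no interior curvature to invert
  vcov <- matrix(0, npar, npar, dimnames = list(coef_names, coef_names))
  se <- rep(0, npar)
  free <- which(!boundary)
  if (length(free) && converged) {
    nll_free <- function(th) {
      full <- par
      full[free] <- th
      nll(full)
    }
    H <- tryCatch(stats::optimHess(par[free], nll_free), error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(V))) {
      vcov[free, free] <- V
      se[free] <- sqrt(pmax(diag(as.matrix(V)), 0))
    }
  }
  names(se) <- coef_names

  beta <- par[seq_len(q)]
  alpha <- if (is.null(fix_p)) par[-seq_len(q)] else numeric(0)
  psi_hat <- stats::plogis(drop(ctx$X_psi %*% beta))
  p_hat <- if (is.null(fix_p)) {
    stats::plogis(drop(ctx$X_p %*% alpha))
  } else {
    rep_len(fix_p, n)
  }

  logL <- -best$value
  p_estimate <- if (is.null(fix_p) && ncol(ctx$X_p) == 1L) {
    pe <- stats::plogis(alpha[1])
    pse <- if (boundary[q + 1L]) 0 else pe * (1 - pe) * se[q + 1L]
    c(estimate = unname(pe), se = unname(pse))
  }

  structure(
    list(
      spec = spec, coefficients = par, beta = beta, alpha = alpha,
      logL = logL, deviance = -2 * logL, K = npar, n = n,
      vcov = vcov, se = se, boundary = boundary, converged = converged,
      psi = psi_hat, p = p_hat, p_estimate = p_estimate,
      fix_p = fix_p, options = options,
      singular = ctx$singular
    ),
    class = "occu_fit"
  )
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("single-season occupancy fit:", x$spec$name, "\n")
  cat(sprintf(
    "  n = %d sites, K = %d, logL = %.3f, deviance = %.3f%s\n",
    x$n, x$K, x$logL, x$deviance,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  tab <- data.frame(
    estimate = round(x$coefficients, 4),
    se = round(x$se, 4),
    boundary = ifelse(x$boundary, "*", "")
  )
  print(tab)
  if (!is.null(x$p_estimate)) {
    cat(sprintf(
      "  detection probability p = %.3f (SE %.3f)\n",
      x$p_estimate["estimate"], x$p_estimate["se"]
    ))
  }
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$coefficients

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$logL, df = object$K, nobs = object$n, class = "logLik")
}

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' Predict occupancy probabilities for site covariates
#'
#' Evaluates `psi = inverse_logit(x' beta)` for new sites under a fitted
#' model, with first-order (delta-method) standard errors
#' `psi (1 - psi) sqrt(x' V x)`. Predictions driven by boundary-flagged
#' coefficients inherit their zero variance, so saturated cells report
#' SE = 0.
#'
#' @param fit An `occu_fit` object.
#' @param newdata Data frame with the covariates the fit's spec requires
#'   (`habitat`, and/or `food`, `forest_area`).
#' @return Data frame with columns `psi` and `se`, one row per row of
#'   `newdata`.
#' @export
predict_psi <- function(fit, newdata) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!fit$converged) {
    warning("prediction from a non-converged fit", call. = FALSE)
  }
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  if (!is.null(newdata$habitat)) {
    canon <- canonical_habitat(newdata$habitat)
    if (any(is.na(canon))) stop("unknown habitat in newdata", call. = FALSE)
    newdata$habitat <- factor(canon, levels = habitat_levels())
  }
  pseudo <- list(sites = newdata)
  X <- do.call(cbind, lapply(fit$spec$psi_terms, term_columns, data = pseudo))
  want <- names(fit$beta)
  have <- paste0("psi_", colnames(X))
  if (!identical(sort(have), sort(want))) {
    # habitat cell-means columns depend on levels present; align by name,
    # zero-filling levels absent from newdata
    Xa <- matrix(0, nrow(X), length(want), dimnames = list(NULL, want))
    ok <- intersect(have, want)
    Xa[, ok] <- X[, match(ok, have), drop = FALSE]
    if (any(rowSums(abs(Xa)) == 0 & rowSums(abs(X)) > 0)) {
      stop("newdata contains habitat levels not in the fitted model",
        call. = FALSE)
    }
    X <- Xa
  } else {
    colnames(X) <- have
    X <- X[, want, drop = FALSE]
  }
  eta <- drop(X %*% fit$beta)
  psi <- stats::plogis(eta)
  Vb <- fit$vcov[seq_along(fit$beta), seq_along(fit$beta), drop = FALSE]
  var_eta <- rowSums((X %*% Vb) * X)
  se <- psi * (1 - psi) * sqrt(pmax(var_eta, 0))
  data.frame(psi = psi, se = se)
}

#' Per-habitat occupancy estimates from a fitted model
#'
#' Averages the fitted psi over the sites of each habitat (for a pure
#' cell-means model this is exactly the cell estimate), with the cell
#' prediction's delta-method SE where the model is cell-means and the
#' empirical SD of fitted psi otherwise.
#'
#' @param fit An `occu_fit` object.
#' @param data The [occu_data] the model was fitted to.
#' @return Data frame with columns `habitat`, `psi`, `se`.
#' @export
psi_by_habitat <- function(fit, data) {
  stopifnot(inherits(fit, "occu_fit"), inherits(data, "occu_data"))
  hab <- droplevels(data$sites$habitat)
  lev <- levels(hab)
  psi <- as.numeric(tapply(fit$psi, hab, mean))
  cellmeans <- identical(fit$spec$psi_terms, "Habitat") ||
    identical(fit$spec$psi_terms, "Residential")
  if (cellmeans) {
    pr <- predict_psi(fit, data.frame(habitat = lev))
    se <- pr$se
  } else {
    # covariate model: spatial-average psi; spread of site predictions
    se <- as.numeric(tapply(fit$psi, hab, stats::sd))
  }
  data.frame(habitat = lev, psi = psi, se = se, stringsAsFactors = FALSE)
}
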