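test_that("inverse logit is correct, symmetric and saturation-stable", {
  expect_equal(inverse_logit(0), 0.5)
  expect_lt(abs(inverse_logit(40) - 1), 1e-15)
  expect_equal(inverse_logit(-0.04001), 0.49, tolerance = 1e-5)
  expect_equal(inverse_logit(800), 1) # no overflow
  expect_error(inverse_logit(Inf), "finite")
  # inverse of the logit on random points
  x <- seq(-10, 10, length.out = 41)
  expect_equal(log(inverse_logit(x) / (1 - inverse_logit(x))), x)
})

test_that("site log-likelihood matches its closed forms", {
  expect_equal(site_log_likelihood(c(1, 0, 1), 1, 0.5), log(0.125))
  expect_equal(site_log_likelihood(c(0, 0, 0), 0, 0.46), 0)
  expect_equal(
    site_log_likelihood(c(0, 0, 0), 0.47, 0.46),
    log(0.47 * 0.54^3 + 0.53)
  )
  # missing replicates drop out of the product
  expect_equal(
    site_log_likelihood(c(1, NA, 0), 1, 0.5),
    site_log_likelihood(c(1, 0), 1, 0.5)
  )
  expect_error(site_log_likelihood(c(1, 0, 0), 1.2, 0.5), "\\[0, 1\\]")
  expect_error(site_log_likelihood(c(1, 0, 0), 0.5, -0.1), "\\[0, 1\\]")
})

test_that("exp(site log-likelihood) equals latent-state enumeration", {
  set.seed(101)
  for (i in 1:200) {
    J <- sample(1:4, 1)
    y <- sample(c(0L, 1L, NA), J, replace = TRUE)
    psi <- runif(1)
    p <- runif(J)
    expect_equal(
      exp(site_log_likelihood(y, psi, p)),
      oracle_site_likelihood(y, psi, p),
      tolerance = 1e-12
    )
  }
})

test_that("dataset log-likelihood is additive and matches enumeration", {
  one <- occu_data(data.frame(
    site_id = "a", habitat = "Res1", y1 = 1, y2 = 0, y3 = 0,
    food = 1, forest_area = 0.2
  ))
  two <- occu_data(rbind(one$sites, transform(one$sites, site_id = "b")))
  th <- c(0.3, -0.2)
  expect_equal(
    dataset_log_likelihood(th, two, "psi(.),p(.)"),
    2 * dataset_log_likelihood(th, one, "psi(.),p(.)")
  )

  # brute-force product over latent-state enumeration on the 6-site toy
  d <- toy6_data()
  spec <- model_spec(c("Residential", "Food", "Area"))
  d$sites$food <- c(1, 0, 1, 0, 1, 0)
  d$sites$forest_area <- seq(0.1, 0.6, by = 0.1)
  d <- occu_data(d$sites)
  dm <- build_design_matrices(d, spec)
  set.seed(7)
  for (r in 1:20) {
    th <- rnorm(dm$K)
    psi <- inverse_logit(drop(dm$X_psi %*% th[1:ncol(dm$X_psi)]))
    p <- inverse_logit(drop(dm$X_p %*% th[-(1:ncol(dm$X_psi))]))
    expected <- sum(log(vapply(1:6, function(i) {
      oracle_site_likelihood(
        as.numeric(d$sites[i, c("y1", "y2", "y3")]), psi[i], p[i]
      )
    }, numeric(1))))
    expect_equal(dataset_log_likelihood(th, d, spec), expected,
      tolerance = 1e-12)
  }

  expect_error(dataset_log_likelihood(c(NaN, 0), one, "psi(.),p(.)"),
    "finite|length")
  expect_error(dataset_log_likelihood(1, one, "psi(.),p(.)"), "length")
})

test_that("design matrices follow cell-means and intercept conventions", {
  d <- simulate_occu(default_config(), seed = 3)
  dm <- build_design_matrices(d, "psi(Habitat)p(.)")
  expect_equal(dim(dm$X_psi), c(150L, 5L))
  expect_true(all(rowSums(dm$X_psi) == 1)) # one-hot
  expect_equal(colnames(dm$X_psi), habitat_levels())
  expect_equal(unique(as.vector(dm$X_p)), 1)
  expect_equal(dm$K, 6L)

  dm0 <- build_design_matrices(d, "psi(.),p(.)")
  expect_equal(ncol(dm0$X_psi), 1L)
  expect_equal(dm0$K, 2L)

  res <- occu_data(d$sites[d$sites$habitat %in% residential_levels(), ])
  dmr <- build_design_matrices(res, "psi(Residential+Food+Area),p(.)")
  expect_equal(colnames(dmr$X_psi), c("Res1", "Res2", "Res3", "Food", "Area"))
  expect_equal(dmr$K, 6L)
  expect_equal(nrow(dmr$X_psi), 90L)
})

test_that("an all-zero covariate column raises a separation warning", {
  d <- simulate_occu(default_config(), seed = 3)
  forest_only <- occu_data(d$sites[d$sites$habitat == "Forest", ])
  forest_only$sites$food <- 0 # structurally zero, as outside residential
  expect_warning(
    dm <- build_design_matrices(occu_data(forest_only$sites), "psi(Food),p(.)"),
    "separation"
  )
  expect_equal(attr(dm$X_psi, "singular"), "Food")
})

test_that("the toy-survey MLE matches exhaustive grid search", {
  d <- toy6_data()
  f <- fit_occu(d, "psi(.),p(.)")
  grid <- oracle_grid_mle(ndet = c(2, 0, 1, 0, 2, 0), J = 3)
  expect_true(f$converged)
  expect_equal(inverse_logit(unname(f$beta)), unname(grid["psi"]),
    tolerance = 1e-3)
  expect_equal(inverse_logit(unname(f$alpha)), unname(grid["p"]),
    tolerance = 1e-3)
  expect_gte(f$logL, grid[["logL"]] - 1e-8)
  expect_equal(f$deviance, -2 * f$logL)
})

test_that("saturated data drive both parameters to the boundary", {
  d <- occu_data(data.frame(
    site_id = 1:8, habitat = rep(habitat_levels()[1:4], 2),
    y1 = 1, y2 = 1, y3 = 1
  ))
  f <- fit_occu(d, "psi(.),p(.)")
  expect_true(all(f$boundary))
  expect_equal(inverse_logit(unname(f$beta)), 1, tolerance = 1e-6)
  expect_equal(unname(f$p_estimate["estimate"]), 1, tolerance = 1e-6)
  expect_equal(unname(f$se), c(0, 0)) # SEs suppressed at the boundary
})

test_that("with perfect detection the psi MLE is exactly naive occupancy", {
  d <- simulate_occu(default_config(), seed = 11)
  f <- fit_occu(d, model_spec("."), fix_p = 1)
  expect_equal(inverse_logit(unname(f$beta)), naive_occupancy(d),
    tolerance = 1e-7)
})

test_that("constant-model psi exceeds naive occupancy when p < 1", {
  for (s in c(2, 9, 21)) {
    d <- simulate_occu(default_config(), seed = s)
    f <- fit_occu(d, "psi(.),p(.)")
    expect_true(f$converged)
    expect_lt(unname(f$p_estimate["estimate"]), 1)
    expect_gte(inverse_logit(unname(f$beta)), naive_occupancy(d) - 1e-8)
  }
})

test_that("complete separation in one habitat is a flagged boundary fit", {
  cfg <- default_config()
  cfg$psi_by_habitat["Res3"] <- 0 # exact-zero option
  d <- simulate_occu(cfg, seed = 4)
  f <- fit_occu(d, "psi(Habitat)p(.)")
  expect_true(f$converged)
  expect_true(f$boundary[which(names(f$beta) == "psi_Res3")])
  expect_lt(inverse_logit(f$beta[["psi_Res3"]]), 1e-4)
  expect_equal(f$se[["psi_Res3"]], 0)
})

test_that("fits are bit-identical under fixed data, spec and options", {
  d <- simulate_occu(default_config(), seed = 13)
  f1 <- fit_occu(d, "psi(Habitat)p(.)", options = fit_options(seed = 2))
  f2 <- fit_occu(d, "psi(Habitat)p(.)", options = fit_options(seed = 2))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$logL, f2$logL)
  expect_identical(f1$vcov, f2$vcov)
})

test_that("predict_psi reproduces cell estimates and respects the link", {
  d <- simulate_occu(default_config(), seed = 17)
  f <- fit_occu(d, "psi(Habitat)p(.)")
  pr <- predict_psi(f, data.frame(habitat = habitat_levels()))
  expect_equal(pr$psi, unname(inverse_logit(f$beta)))

  # boundary cells inherit zero variance
  expect_equal(pr$se[f$boundary[1:5]], rep(0, sum(f$boundary[1:5])))

  res <- occu_data(d$sites[d$sites$habitat %in% residential_levels(), ])
  fr <- fit_occu(res, "psi(Residential+Food+Area),p(.)")
  b_area <- fr$beta[["psi_Area"]]
  nd <- data.frame(
    habitat = "Res1", food = 1,
    forest_area = c(0.05, 0.2, 0.6)
  )
  p3 <- predict_psi(fr, nd)$psi
  # psi strictly monotone in the covariate, in the coefficient's direction
  expect_true(all(diff(p3) * sign(b_area) > 0) || b_area == 0)

  expect_error(predict_psi(fr, data.frame(habitat = "Res1", food = 1)),
    "forest_area")
})

test_that("monotone link: psi increases with each beta times its covariate", {
  set.seed(23)
  X <- cbind(1, matrix(runif(30, -1, 1), 10, 3))
  for (r in 1:20) {
    beta <- rnorm(4)
    eps <- 0.05
    for (k in 1:4) {
      up <- beta
      up[k] <- up[k] + eps
      d_eta <- (X %*% up - X %*% beta)[, 1]
      d_psi <- inverse_logit(drop(X %*% up)) - inverse_logit(drop(X %*% beta))
      expect_true(all(sign(d_psi) == sign(d_eta) | d_eta == 0))
    }
  }
})
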