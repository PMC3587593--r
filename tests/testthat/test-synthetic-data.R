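test_that("the default configuration encodes the study design", {
  cfg <- default_config()
  expect_equal(cfg$p, 0.49)
  expect_equal(unname(cfg$psi_by_habitat["Forest"]), 1.00)
  expect_equal(unname(cfg$psi_by_habitat[c("Amenity", "Res1", "Res2")]),
    c(0.50, 0.46, 0.23))
  expect_equal(cfg$sites_per_habitat * length(cfg$psi_by_habitat), 150)
  expect_equal(cfg$J, 3L)
  # food prevalence: OR of fruit / vegetables / compost under independence
  expect_equal(unname(cfg$food_prevalence["Res1"]), 1 - 0.8 * 0.7 * 0.73)
  expect_equal(unname(cfg$food_prevalence["Res2"]), 1 - 0.8 * 0.57 * 0.77)
  expect_equal(unname(cfg$food_prevalence["Res3"]), 1 - 0.8 * 0.9 * 0.993)
  expect_equal(unname(cfg$food_prevalence[c("Forest", "Amenity")]), c(0, 0))
})

test_that("invalid configurations fail before any draw", {
  cfg <- default_config()
  cfg$p <- 1.2
  expect_error(simulate_occu(cfg, seed = 1), "\\[0, 1\\]")
  cfg <- default_config()
  cfg$sites_per_habitat <- 0L
  expect_error(simulate_occu(cfg, seed = 1), "sites_per_habitat")
  cfg <- default_config()
  cfg$psi_mode <- "linear"
  expect_error(simulate_occu(cfg, seed = 1), "psi_coef")
  expect_error(simulate_occu(default_config()), "seed")
})

test_that("generation is deterministic in the seed", {
  d1 <- simulate_occu(default_config(), seed = 99)
  d2 <- simulate_occu(default_config(), seed = 99)
  expect_identical(d1$sites, d2$sites)
  d3 <- simulate_occu(default_config(), seed = 100)
  expect_false(identical(d1$sites, d3$sites))
})

test_that("degenerate occupancy and detection produce degenerate histories", {
  cfg <- default_config()
  cfg$psi_by_habitat[] <- 0
  d <- simulate_occu(cfg, seed = 1)
  expect_true(all(as.matrix(d$sites[, c("y1", "y2", "y3")]) == 0))

  cfg$psi_by_habitat[] <- 1
  cfg$p <- 1
  d <- simulate_occu(cfg, seed = 1)
  expect_true(all(as.matrix(d$sites[, c("y1", "y2", "y3")]) == 1))
})

test_that("detection frequencies converge to psi * (1 - (1-p)^J)", {
  cfg <- default_config()
  cfg$sites_per_habitat <- 20000L # 1e5 sites total
  d <- simulate_occu(cfg, seed = 12)
  s <- detection_summary(d)
  expected <- cfg$psi_by_habitat[s$habitat] * (1 - (1 - cfg$p)^cfg$J)
  expect_equal(s$naive, unname(expected), tolerance = 0.01)
  # amenity expectation scaled to the survey size: ~13 of 30 sites
  amen <- s$naive[s$habitat == "Amenity"] * 30
  expect_equal(amen, 30 * 0.5 * (1 - 0.51^3), tolerance = 0.02)
})

test_that("covariates follow their habitat-specific distributions", {
  cfg <- default_config()
  cfg$sites_per_habitat <- 5000L
  d <- simulate_occu(cfg, seed = 21)
  s <- d$sites
  expect_true(all(s$forest_area >= 0 & s$forest_area <= 1))
  prev <- tapply(s$food, s$habitat, mean)
  expect_equal(as.numeric(prev[c("Forest", "Amenity")]), c(0, 0))
  expect_equal(as.numeric(prev[residential_levels()]),
    unname(cfg$food_prevalence[residential_levels()]),
    tolerance = 0.03)
  means <- tapply(s$forest_area, s$habitat, mean)
  shape_mean <- vapply(cfg$forest_area_shapes, function(x) x[1] / sum(x),
    numeric(1))
  expect_equal(as.numeric(means[names(shape_mean)]), unname(shape_mean),
    tolerance = 0.02)
  # declared ordering of forest proximity across habitats
  expect_true(all(diff(means[habitat_levels()]) < 0))
})

test_that("linear psi mode drives occupancy through the logit predictor", {
  cfg <- default_config()
  cfg$sites_per_habitat <- 4000L
  cfg$psi_mode <- "linear"
  cfg$psi_coef <- list(
    habitat = c(Forest = 2, Amenity = 0, Res1 = -0.5, Res2 = -1, Res3 = -2),
    food = 1.5, area = 2
  )
  d <- simulate_occu(cfg, seed = 31)
  s <- d$sites
  detected <- site_detected(d)
  capture <- 1 - (1 - cfg$p)^cfg$J
  # empirical detection frequency per habitat-by-food cell matches the
  # logit-linear occupancy times the capture probability
  for (h in c("Res1", "Res2", "Res3")) {
    for (fd in 0:1) {
      cell <- s$habitat == h & s$food == fd
      eta <- cfg$psi_coef$habitat[[h]] + cfg$psi_coef$food * fd +
        cfg$psi_coef$area * s$forest_area[cell]
      q <- mean(plogis(eta)) * capture
      mc_sd <- sqrt(q * (1 - q) / sum(cell))
      expect_lt(abs(mean(detected[cell]) - q), 4 * mc_sd)
    }
  }
  # and the food effect raises detection within each residential habitat
  for (h in c("Res1", "Res2", "Res3")) {
    cell1 <- s$habitat == h & s$food == 1
    cell0 <- s$habitat == h & s$food == 0
    expect_gt(mean(detected[cell1]), mean(detected[cell0]))
  }
})
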