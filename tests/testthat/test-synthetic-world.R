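test_that("default landscape matches the study-area layout", {
  land <- generate_landscape(landscape_spec(), seed = 9)
  expect_equal(nrow(land$cells), 900)
  expect_equal(as.vector(table(land$cells$region)), c(360, 180, 360))
  hh_means <- tapply(land$cells$n_households, land$cells$region, mean)
  expect_equal(as.numeric(hh_means), c(40, 100, 65), tolerance = 0.05)
  # region 1 high V1 / low V2, region 2 the reverse, region 3 intermediate
  v1 <- tapply(land$cells$V1, land$cells$region, mean)
  v2 <- tapply(land$cells$V2, land$cells$region, mean)
  expect_true(v1[1] > v1[3] && v1[3] > v1[2])
  expect_true(v2[2] > v2[3] && v2[3] > v2[1])
  # V3 levels ~ 30/70
  expect_equal(mean(land$households$v3 == "a"), 0.3, tolerance = 0.02)
  expect_equal(mean(land$households$ame), 5, tolerance = 0.05)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_landscape(landscape_spec(), seed = 5)
  b <- generate_landscape(landscape_spec(), seed = 5)
  expect_identical(a$cells, b$cells)
  expect_identical(a$households, b$households)
  w1 <- synthetic_survey(landscape_spec(n_cells = 100,
                                        region_sizes = c(40, 20, 40),
                                        household_count_means = c(8, 20, 13)),
                         observation_spec(coverage = 0.2), seed = 11)
  w2 <- synthetic_survey(landscape_spec(n_cells = 100,
                                        region_sizes = c(40, 20, 40),
                                        household_count_means = c(8, 20, 13)),
                         observation_spec(coverage = 0.2), seed = 11)
  expect_identical(w1$survey$recalls, w2$survey$recalls)
  expect_identical(w1$survey$households, w2$survey$households)
})

test_that("degenerate truth settings behave as closed forms dictate", {
  spec <- landscape_spec(n_cells = 36, region_sizes = c(15, 6, 15),
                         household_count_means = c(3, 5, 4),
                         gp_params = list(zeta = 0, rho = 0.015))
  land <- generate_landscape(spec, seed = 2)
  truth <- simulate_truth(land, seed = 2)
  expect_equal(truth$cells$eps, rep(0, 36))    # zeta = 0 switches the GP off
  # zero intercepts and slopes give pi = 0.5 everywhere
  rp0 <- spec$region_params
  rp0$a0 <- rp0$a1 <- c(0, 0, 0); rp0$a2 <- 0
  t0 <- simulate_truth(land, seed = 2, region_params = rp0,
                       gp_params = list(zeta = 0, rho = 1))
  expect_equal(t0$households$pi, rep(0.5, nrow(t0$households)))
})

test_that("simulated spatial effects decay with distance like the kernel", {
  spec <- landscape_spec(n_cells = 25, region_sizes = c(10, 5, 10),
                         household_count_means = c(2, 2, 2))
  land <- generate_landscape(spec, seed = 4)
  D <- build_distance_matrix(data.frame(location_id = land$cells$cell_id,
                                        lon = land$cells$lon,
                                        lat = land$cells$lat))
  zeta <- 0.8; rho <- 0.015
  set.seed(99)
  draws <- replicate(3000, gp_eps(zeta, rho, D, rnorm(25)))
  # empirical covariance vs closed form at three distances
  pairs <- list(c(1, 2), c(1, 5), c(1, 25))
  for (p in pairs) {
    emp <- cov(draws[p[1], ], draws[p[2], ])
    theo <- zeta^2 * exp(-rho^2 * D[p[1], p[2]]^2)
    expect_equal(emp, theo, tolerance = 0.05 * zeta^2 + 0.02)
  }
})

test_that("observation respects the coverage and reporting fractions", {
  w <- make_fixtures("small", seed = 21)
  expect_equal(nrow(w$survey$locations), 90)        # 10% of 900 cells
  expect_equal(length(w$frequency_cells), 72)       # 80% of 90
  expect_equal(length(w$quantity_cells), 45)        # 50% of 90
  frac_miss <- mean(is.na(w$survey$households$ame))
  expect_lt(abs(frac_miss - 0.20), 0.05)            # binomial error
  expect_error(observe(tiny_world()$truth,
                       observation_spec(coverage = 1e-4), seed = 1),
               "zero surveyed")
})

test_that("generated tables pass ingestion with zero exclusions", {
  for (w in list(tiny_world(), make_fixtures("small", seed = 21))) {
    expect_equal(length(w$survey$report$exclusions), 0)
    expect_equal(nrow(w$survey$recalls), w$survey$report$counts$recalls)
  }
})

test_that("with monitoring noise off, observed equals true frequency", {
  spec <- landscape_spec(n_cells = 100, region_sizes = c(40, 20, 40),
                         household_count_means = c(8, 20, 13), sigma = 0)
  land <- generate_landscape(spec, seed = 6)
  truth <- simulate_truth(land, seed = 6)
  w <- observe(truth, observation_spec(coverage = 0.3), seed = 6)
  hh <- w$survey$households
  obs <- hh[!is.na(hh$frequency), ]
  tru <- truth$households$phi[match(obs$household_id,
                                    truth$households$household_id)]
  expect_equal(obs$frequency, tru, tolerance = 1e-12)
})

test_that("empirical recall means converge to the generative truth", {
  # law-of-large-numbers check: ~1e4 recalls, noise-free frequencies
  spec <- landscape_spec(n_cells = 64, region_sizes = c(26, 12, 26),
                         household_count_means = c(4, 8, 6), sigma = 0)
  land <- generate_landscape(spec, seed = 8)
  truth <- simulate_truth(land, seed = 8)
  w <- observe(truth, observation_spec(coverage = 1,
                                       household_sampling_fraction = 1,
                                       frac_quantity_studies = 1,
                                       frac_missing_ame = 1e-9), seed = 8)
  rc <- w$survey$recalls
  expect_gt(nrow(rc), 1e4)
  hh_truth <- truth$households
  m <- match(rc$household_id, hh_truth$household_id)
  # overall consumption proportion vs mean true pi (recall-weighted)
  expect_equal(mean(rc$consumed), mean(hh_truth$pi[m]), tolerance = 0.02)
  # quantity per AME on consumption days vs true mu
  qr <- rc[!is.na(rc$quantity_kg) & rc$quantity_kg > 0, ]
  mq <- match(qr$household_id, hh_truth$household_id)
  expect_equal(mean(qr$quantity_kg / hh_truth$ame[mq]),
               mean(hh_truth$mu[mq]), tolerance = 0.05)
})

test_that("true tonnes agree between cell-sum and household-sum routes", {
  truth <- tiny_world()$truth
  by_household <- sum(truth$households$rate * truth$households$ame) *
    365 / 1000
  by_cell <- sum(truth$cells$rate * truth$cells$ame_total) * 365 / 1000
  expect_equal(by_cell, by_household, tolerance = 1e-12)
  expect_equal(truth$summary$total_tonnes, by_household, tolerance = 1e-12)
})
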