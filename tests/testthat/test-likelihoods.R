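# Oracle tests: every likelihood term is compared with an independent
# textbook implementation evaluated point by point.

manual_loglik <- function(st, md) {
  # consumption: per-group binomial mass written out directly
  eps <- if ("consumption" %in% md$spatial)
    gp_eps(st$zeta_c, st$rho_c, md$D, st$eta_c) else rep(0, md$n_loc)
  lp <- as.vector(md$cons$X %*% st$alpha) + eps[md$cons$loc]
  p <- 1 / (1 + exp(-lp))
  cons <- sum(md$cons$events * log(p) +
                (md$cons$trials - md$cons$events) * log(1 - p))
  # frequency: Beta density + standard-normal tau, written out
  phib <- as.vector(md$freq$X %*% st$beta)
  phi <- 1 / (1 + exp(-(phib + st$sigma * (365 - md$freq$mdays) * st$tau)))
  a <- phi * st$kappa; b <- (1 - phi) * st$kappa
  freq <- sum(lgamma(a + b) - lgamma(a) - lgamma(b) +
                (a - 1) * log(md$freq$y) + (b - 1) * log(1 - md$freq$y)) +
    sum(-0.5 * st$tau^2 - 0.5 * log(2 * pi))
  # quantity: Gamma shape-rate density written out
  ame <- md$quant$ame
  ame[md$quant$imput_id > 0] <- st$ame_mis[md$quant$imput_id[md$quant$imput_id > 0]]
  mu <- exp(as.vector(md$quant$X %*% st$gamma) + st$gamma_ame * ame)
  sh <- mu * st$theta
  y <- md$quant$q / ame
  quant <- sum(sh * log(st$theta) - lgamma(sh) + (sh - 1) * log(y) -
                 st$theta * y)
  list(consumption = cons, frequency = freq, quantity = quant)
}

test_that("likelihood terms match independent density implementations", {
  md <- tiny_mdata()
  for (seed in 1:20) {
    st <- random_state(md, seed)
    ref <- manual_loglik(st, md)
    expect_equal(loglik_consumption(st, md), ref$consumption,
                 tolerance = 1e-10)
    expect_equal(loglik_frequency(st, md), ref$frequency, tolerance = 1e-10)
    expect_equal(loglik_quantity(st, md), ref$quantity, tolerance = 1e-10)
  }
})

test_that("GP covariance follows the exponentiated-quadratic closed form", {
  D <- matrix(c(0, 1, 1, 0), 2)
  g <- gp_build(1, 1, D)
  expect_equal(g$X[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(g$X), rep(1 + 1e-9, 2))          # zeta^2 + delta
  expect_equal(g$LX %*% t(g$LX), g$X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # large rho: covariance collapses to the diagonal
  g2 <- gp_build(0.7, 100, D)
  expect_equal(g2$X, diag(0.49 + 1e-9, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a random distance matrix keeps the factorization exact
  set.seed(3)
  loc <- data.frame(lon = runif(6, 0, 2), lat = runif(6, 0, 2))
  D6 <- build_distance_matrix(loc)
  g3 <- gp_build(0.5, 0.01, D6)
  expect_equal(g3$LX %*% t(g3$LX), g3$X, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(gp_build(1, 1, matrix(c(0, 1, 2, 0), 2)), "isSymmetric")
})

test_that("Beta and Gamma parameterizations have the stated means", {
  # Beta(phi*kappa, (1-phi)*kappa) has mean phi: quadrature at (0.3, 10)
  m_beta <- integrate(function(x) x * dbeta(x, 0.3 * 10, 0.7 * 10),
                      0, 1)$value
  expect_equal(m_beta, 0.3, tolerance = 1e-6)
  # Gamma(mu*theta, theta) has mean mu: quadrature at (0.4, 5)
  m_gamma <- integrate(function(x) x * dgamma(x, 0.4 * 5, rate = 5),
                       0, Inf)$value
  expect_equal(m_gamma, 0.4, tolerance = 1e-6)
  # theta -> infinity at fixed mu kills the variance (var = mu / theta)
  v <- integrate(function(x) (x - 0.4)^2 * dgamma(x, 0.4 * 1e6, rate = 1e6),
                 0, Inf)$value
  expect_lt(v, 1e-5)
})

test_that("monitoring noise scales as sigma * (365 - mdays)", {
  md <- tiny_mdata()
  st <- random_state(md, 1)
  # a household monitored for all 365 days has Sigma = 0: phi equals
  # plogis(phibar) no matter what tau is
  md2 <- md
  md2$freq$mdays[1] <- 365
  md2$freq$sig_base[1] <- 0
  st_a <- st; st_a$tau[1] <- -3
  st_b <- st; st_b$tau[1] <- 3
  # tau only enters through Sigma * tau, so the Beta part is unchanged;
  # the difference must equal the standard-normal prior difference alone
  expect_equal(loglik_frequency(st_a, md2) - loglik_frequency(st_b, md2),
               dnorm(-3, log = TRUE) - dnorm(3, log = TRUE),
               tolerance = 1e-10)
  # one monitored day gives the maximum sd, 364 * sigma
  expect_equal(st$sigma * (365 - 1), 364 * st$sigma)
  md3 <- md
  md3$freq$mdays[1] <- 400
  expect_error(loglik_frequency(st, md3), "mdays")
})

test_that("the joint posterior is the sum of its independently computed terms", {
  md <- tiny_mdata()
  pri <- default_priors(md)
  for (seed in c(2, 5)) {
    st <- random_state(md, seed)
    ref <- manual_loglik(st, md)
    manual_total <- ref$consumption + ref$frequency + ref$quantity +
      sum(dnorm(st$eta_c, log = TRUE)) +
      sum(dnorm(st$ame_mis, st$nu, st$psi, log = TRUE) -
            pnorm(0, st$nu, st$psi, lower.tail = FALSE, log.p = TRUE)) +
      sum(dnorm(md$ame_obs, st$nu, st$psi, log = TRUE) -
            pnorm(0, st$nu, st$psi, lower.tail = FALSE, log.p = TRUE)) -
      sum(log(st$ame_mis[md$quant$imput_id[md$quant$imput_id > 0]])) +
      sum(dnorm(c(st$alpha, st$beta, st$gamma, st$gamma_ame), 0,
                pri$coef_sd, log = TRUE)) +
      log(2) + dnorm(st$zeta_c, 0, pri$zeta_sd, log = TRUE) +
      log(2) + dnorm(st$rho_c, 0, pri$rho_sd, log = TRUE) +
      log(2) + dnorm(st$sigma, 0, pri$sigma_sd, log = TRUE) +
      log(2) + dnorm(1 / sqrt(st$kappa), 0, pri$kappa_sd, log = TRUE) +
      log(0.5) - 1.5 * log(st$kappa) +
      dgamma(st$theta, pri$theta[1], pri$theta[2], log = TRUE) +
      dnorm(st$nu, pri$nu_centre, pri$nu_sd, log = TRUE) -
      pnorm(0, pri$nu_centre, pri$nu_sd, lower.tail = FALSE, log.p = TRUE) +
      log(2) + dnorm(st$psi, 0, pri$psi_sd, log = TRUE)
    expect_equal(log_posterior(st, md, pri), manual_total,
                 tolerance = 1e-10)
  }
})

test_that("the log posterior is finite at the prior centres", {
  md <- tiny_mdata()
  pri <- default_priors(md)
  st <- wildmeatr:::.init_state(md, pri)
  expect_true(is.finite(log_posterior(st, md, pri)))
})

test_that("non-finite terms are reported by name", {
  md <- tiny_mdata()
  st <- random_state(md, 3)
  st$theta <- -1                                 # invalid Gamma rate
  expect_error(suppressWarnings(log_posterior(st, md)), "quantity")
})

test_that("centred and non-centred forms define the same joint density", {
  md <- tiny_mdata()
  for (seed in c(4, 9, 13)) {
    st <- random_state(md, seed)
    LX <- gp_build(st$zeta_c, st$rho_c, md$D)$LX
    st_c <- st
    st_c$eps_c <- as.vector(LX %*% st$eta_c)
    phibar <- as.vector(md$freq$X %*% st$beta)
    Sig <- st$sigma * md$freq$sig_base
    st_c$logit_phi <- phibar + Sig * st$tau
    lp_nc <- log_posterior(st, md)
    lp_c <- log_posterior(st_c, md, parameterization = "centred")
    # change of variables: eps = LX eta and logit_phi = phibar + Sigma tau
    log_jac <- sum(log(diag(LX))) + sum(log(Sig))
    expect_equal(lp_nc, lp_c + log_jac, tolerance = 1e-8)
  }
})

test_that("imputed AMEs collapse to nu as psi vanishes", {
  md <- tiny_mdata()
  st <- random_state(md, 6)
  st$psi <- 1e-7
  st$ame_mis <- rep(st$nu, md$n_miss_ame)
  at_nu <- log_posterior(st, md, on_nonfinite = "value")
  st2 <- st
  st2$ame_mis <- rep(st$nu + 1e-3, md$n_miss_ame)
  away <- log_posterior(st2, md, on_nonfinite = "value")
  expect_true(at_nu > away)                       # degenerate prior pins A
})

test_that("removing a data block removes exactly that likelihood term", {
  w <- tiny_world()
  sv <- w$survey
  sv$households$frequency <- NA                  # no frequency data at all
  md0 <- prepare_model_data(sv,
                            consumption = tiny_formulas$consumption,
                            frequency = ~1,
                            quantity = tiny_formulas$quantity,
                            spatial = "consumption")
  st <- random_state(md0, 10)
  expect_equal(nrow(md0$freq$X), 0)
  expect_equal(loglik_frequency(st, md0), 0)     # empty product
  # the remaining blocks still contribute
  expect_true(is.finite(loglik_consumption(st, md0)))
  expect_true(loglik_quantity(st, md0) != 0)
})
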