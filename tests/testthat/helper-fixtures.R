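# shared fixtures, built in code once per test run

# a small synthetic survey + model data (20 locations, ~200 households)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixtures("tiny", seed = 3)
    cache
  }
})

tiny_formulas <- list(
  consumption = ~ 0 + region + region:V1 + v3,
  frequency = ~ 0 + region + region:V2 + v3,
  quantity = ~ 0 + region + region:V2
)

tiny_mdata <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- prepare_model_data(
        tiny_world()$survey,
        consumption = tiny_formulas$consumption,
        frequency = tiny_formulas$frequency,
        quantity = tiny_formulas$quantity,
        spatial = "consumption")
    cache
  }
})

# a short posterior fit on the tiny world, reused across test files
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        sample_posterior(tiny_mdata(), chains = 1, iterations = 400,
                         warmup = 250, seed = 42))
    cache
  }
})

# a random-but-valid parameter state for likelihood oracle tests
random_state <- function(mdata, seed) {
  set.seed(seed)
  st <- list(
    alpha = rnorm(ncol(mdata$cons$X), 0, 0.5),
    beta = rnorm(ncol(mdata$freq$X), 0, 0.5),
    gamma = rnorm(ncol(mdata$quant$X), 0, 0.5),
    gamma_ame = rnorm(1, 0, 0.05),
    sigma = runif(1, 5e-4, 3e-3),
    kappa = runif(1, 5, 50),
    theta = runif(1, 2, 10),
    tau = rnorm(nrow(mdata$freq$X)),
    nu = runif(1, 4, 6), psi = runif(1, 1, 3),
    ame_mis = runif(mdata$n_miss_ame, 2, 8)
  )
  names(st$alpha) <- colnames(mdata$cons$X)
  names(st$beta) <- colnames(mdata$freq$X)
  names(st$gamma) <- colnames(mdata$quant$X)
  if ("consumption" %in% mdata$spatial) {
    st$zeta_c <- runif(1, 0.2, 1)
    st$rho_c <- runif(1, 0.005, 0.03)
    st$eta_c <- rnorm(mdata$n_loc)
  }
  if ("frequency" %in% mdata$spatial) {
    st$zeta_f <- runif(1, 0.2, 1)
    st$rho_f <- runif(1, 0.005, 0.03)
    st$eta_f <- rnorm(mdata$n_loc)
  }
  st
}

# cell table + designs for predictions over the tiny world's full landscape
tiny_cells <- function(mdata = tiny_mdata()) {
  cells <- tiny_world()$truth$cells
  cells$region <- factor(cells$region)
  cells$ame <- cells$ame_total
  w <- list(v3 = c(a = 0.3, b = 0.7))
  list(cells = cells, design = list(
    consumption = build_cell_design(tiny_formulas$consumption, cells, w,
                                    mdata$cons$xlevels),
    frequency = build_cell_design(tiny_formulas$frequency, cells, w,
                                  mdata$freq$xlevels),
    quantity = build_cell_design(tiny_formulas$quantity, cells,
                                 xlevels = mdata$quant$xlevels)))
}
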