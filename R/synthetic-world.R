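#' Specification of the synthetic landscape
#'
#' Describes the simulated study area used for parameter-recovery testing: a
#' 900-cell landscape split into three contiguous regions with contrasting
#' covariates. Region 1 (360 cells) has high `V1` and low `V2` and few
#' households (mean 40); region 2 (180 cells) has high `V2`, low `V1` and
#' many households (mean 100); region 3 (360 cells) is intermediate (mean
#' 65). Each cell holds one location (a cluster of villages); households have
#' on average 5 adult male equivalents and carry a two-level categorical
#' covariate `V3` with level probabilities 0.30/0.70.
#'
#' The generative regression parameters (per-region intercepts and slopes of
#' the three processes) are stand-in defaults calibrated so that roughly 16%
#' of simulated recall events are consumption events; they are fully
#' overridable.
#'
#' @param n_cells number of cells (default 900; must be compatible with
#'   `region_sizes`).
#' @param region_sizes cells per region, summing to `n_cells`.
#' @param household_count_means mean households per cell, by region.
#' @param ame_mean mean adult male equivalents per household.
#' @param v3_level_probs probabilities of the two `V3` levels.
#' @param v1_region_means,v2_region_means per-region means of the continuous
#'   covariates; cell values are drawn around them with sd `covariate_sd`.
#' @param covariate_sd within-region sd of `V1`, `V2`.
#' @param region_params list with per-region intercepts/slopes:
#'   `a0`, `a1` (consumption, logit), `b0`, `b1` (frequency, logit),
#'   `g0`, `g2` (quantity, log) each length 3; scalars `a2`, `b2` (effect of
#'   the second `V3` level), `g1` (per-AME slope) and `theta` (Gamma rate).
#' @param gp_params list with `zeta` (marginal sd) and `rho` (inverse length
#'   scale, 1/km) of the spatial process on consumption.
#' @param sigma per-unmonitored-day sd of the frequency monitoring noise.
#' @param origin,spacing_deg grid origin (lon, lat) and spacing in degrees.
#' @return list of class `wm_landscape_spec`.
#' @export
landscape_spec <- function(n_cells = 900,
                           region_sizes = c(360, 180, 360),
                           household_count_means = c(40, 100, 65),
                           ame_mean = 5,
                           v3_level_probs = c(0.30, 0.70),
                           v1_region_means = c(1, -1, 0),
                           v2_region_means = c(-1, 1, 0),
                           covariate_sd = 0.5,
                           region_params = list(
                             a0 = c(-2.5, -1.9, -2.2),
                             a1 = c(0.8, 0.5, 0.6), a2 = 0.5,
                             b0 = c(-1.9, -1.3, -1.6),
                             b1 = c(0.4, 0.6, 0.5), b2 = 0.4,
                             g0 = c(-1.9, -1.5, -1.7),
                             g1 = -0.03,
                             g2 = c(0.15, 0.10, 0.12),
                             theta = 6),
                           gp_params = list(zeta = 0.6, rho = 0.015),
                           sigma = 0.002,
                           origin = c(15, -7.5), spacing_deg = 0.5) {
  stopifnot(sum(region_sizes) == n_cells,
            abs(sum(v3_level_probs) - 1) < 1e-9,
            all(household_count_means > 0), ame_mean > 0)
  structure(as.list(environment()), class = "wm_landscape_spec")
}

#' Specification of the observation process
#'
#' Which part of the simulated world a survey sees: the fraction of cells
#' surveyed (the coverage scenarios are 5%, 10% and 15%), the fraction of
#' surveyed locations reporting frequency (80%) and quantity (50%), the
#' fraction of households with unknown AME (20%), and the fraction of
#' households interviewed within each surveyed cell. Monitored days are drawn
#' log-uniformly on 1..365.
#'
#' @param coverage fraction of cells surveyed (in (0, 1]).
#' @param frac_frequency_studies fraction of surveyed locations providing
#'   frequency data.
#' @param frac_quantity_studies fraction providing quantity data.
#' @param frac_missing_ame fraction of surveyed households with missing AME.
#' @param household_sampling_fraction fraction of a cell's households that
#'   are interviewed.
#' @return list of class `wm_observation_spec`.
#' @export
observation_spec <- function(coverage = 0.10,
                             frac_frequency_studies = 0.80,
                             frac_quantity_studies = 0.50,
                             frac_missing_ame = 0.20,
                             household_sampling_fraction = 0.20) {
  fr <- c(coverage, frac_frequency_studies, frac_quantity_studies,
          household_sampling_fraction)
  stopifnot(all(fr > 0), all(fr <= 1),
            frac_missing_ame >= 0, frac_missing_ame < 1)
  structure(as.list(environment())[c("coverage", "frac_frequency_studies",
                                     "frac_quantity_studies",
                                     "frac_missing_ame",
                                     "household_sampling_fraction")],
            class = "wm_observation_spec")
}

#' Generate the synthetic landscape
#'
#' Lays the cells out on a near-square lon/lat grid (one location per cell),
#' assigns contiguous row-blocks of cells to the three regions, draws the
#' cell covariates `V1`, `V2` around their region means, the household count
#' per cell (Poisson around the region mean, at least 1) and, per household,
#' the AME count (Poisson around `ame_mean`, at least 1) and the `V3` level.
#'
#' @param spec a `wm_landscape_spec`.
#' @param seed integer seed.
#' @return list of class `wm_landscape` with `cells` (one row per cell) and
#'   `households` (one row per household), plus the spec.
#' @export
generate_landscape <- function(spec = landscape_spec(), seed = 1) {
  stopifnot(inherits(spec, "wm_landscape_spec"))
  set.seed(seed)
  n <- spec$n_cells
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  ix <- seq_len(n) - 1
  cells <- data.frame(
    cell_id = seq_len(n),
    lon = spec$origin[1] + (ix %% ncol_grid) * spec$spacing_deg,
    lat = spec$origin[2] + (ix %/% ncol_grid) * spec$spacing_deg,
    region = rep(seq_along(spec$region_sizes), spec$region_sizes)
  )
  cells$V1 <- stats::rnorm(n, spec$v1_region_means[cells$region],
                           spec$covariate_sd)
  cells$V2 <- stats::rnorm(n, spec$v2_region_means[cells$region],
                           spec$covariate_sd)
  cells$n_households <- pmax(
    1L, stats::rpois(n, spec$household_count_means[cells$region]))
  hh_cell <- rep(cells$cell_id, cells$n_households)
  nh <- length(hh_cell)
  households <- data.frame(
    household_id = sprintf("hh%06d", seq_len(nh)),
    cell_id = hh_cell,
    region = cells$region[hh_cell],
    ame = pmax(1L, stats::rpois(nh, spec$ame_mean)),
    v3 = factor(sample(c("a", "b"), nh, replace = TRUE,
                       prob = spec$v3_level_probs), levels = c("a", "b"))
  )
  structure(list(cells = cells, households = households, spec = spec),
            class = "wm_landscape")
}

#' Simulate the generative truth on a landscape
#'
#' Draws the latent spatial process over the cell distance matrix and
#' computes, for every household, the true consumption probability `pi`
#' (logit-linear in `V1`, `V3` and the spatial effect), frequency of
#' consumption `phi` (logit-linear in `V2`, `V3`) and mean quantity per AME
#' `mu` (log-linear in `V2` and the household AME count), all with
#' region-varying intercepts and slopes. Ground-truth summaries include the
#' true regional mean probability, frequency and quantity and the true total
#' tonnes consumed per year
#' (`sum over households of pi * phi * mu * AME * 365 / 1000`).
#'
#' @param landscape a `wm_landscape`.
#' @param seed integer seed (spatial draw).
#' @param region_params,gp_params optional overrides of the spec values.
#' @return list of class `wm_truth`.
#' @export
simulate_truth <- function(landscape, seed = 1,
                           region_params = landscape$spec$region_params,
                           gp_params = landscape$spec$gp_params) {
  stopifnot(inherits(landscape, "wm_landscape"))
  set.seed(seed + 1L)
  cells <- landscape$cells
  hh <- landscape$households
  rp <- region_params
  D <- build_distance_matrix(data.frame(location_id = cells$cell_id,
                                        lon = cells$lon, lat = cells$lat))
  eps <- if (gp_params$zeta == 0) rep(0, nrow(cells)) else
    gp_eps(gp_params$zeta, gp_params$rho, D, stats::rnorm(nrow(cells)))
  cells$eps <- eps

  r <- hh$region
  v3b <- as.integer(hh$v3 == "b")
  hh$pi <- stats::plogis(rp$a0[r] + rp$a1[r] * cells$V1[hh$cell_id] +
                           rp$a2 * v3b + eps[hh$cell_id])
  hh$phi <- stats::plogis(rp$b0[r] + rp$b1[r] * cells$V2[hh$cell_id] +
                            rp$b2 * v3b)
  hh$mu <- exp(rp$g0[r] + rp$g1 * hh$ame + rp$g2[r] * cells$V2[hh$cell_id])
  hh$rate <- hh$pi * hh$phi * hh$mu            # kg / AME / day

  cell_ame <- rowsum(hh$ame, hh$cell_id)[, 1]
  cell_rate <- rowsum(hh$rate * hh$ame, hh$cell_id)[, 1] / cell_ame
  cells$ame_total <- cell_ame[as.character(cells$cell_id)]
  cells$rate <- cell_rate[as.character(cells$cell_id)]

  structure(list(
    cells = cells, households = hh, D = D,
    params = c(rp, gp_params, list(sigma = landscape$spec$sigma)),
    summary = list(
      mean_pi = mean(hh$pi), mean_phi = mean(hh$phi), mean_mu = mean(hh$mu),
      total_ame = sum(hh$ame),
      total_tonnes = sum(hh$rate * hh$ame) * 365 / 1000
    ),
    spec = landscape$spec
  ), class = "wm_truth")
}

#' Observe a simulated world through a survey design
#'
#' Randomly selects `coverage * n_cells` locations (rounded); all of them
#' provide consumption/non-consumption recalls, a random 80% provide
#' frequency data and a random 50% quantity data. Within each surveyed cell a
#' fraction of households is interviewed; 20% of interviewed households have
#' missing AME. Each household is monitored for `mdays` 24-h recalls (drawn
#' log-uniformly on 1..365): consumption flags are Bernoulli draws from the
#' household's true `pi`; observed quantities per AME on consumption days are
#' Gamma draws around `mu`; the observed frequency applies
#' logit-normal monitoring noise with sd `sigma * (365 - mdays)` to the true
#' frequency, so a household monitored for all 365 days reports its true
#' frequency exactly.
#'
#' The result is a `wm_survey` (already through [ingest_survey()], which it
#' passes with zero exclusions) plus the ground truth.
#'
#' @param truth a `wm_truth`.
#' @param obs a `wm_observation_spec`.
#' @param seed integer seed.
#' @return list with `survey` (a `wm_survey`), `truth` and per-table raw
#'   data.
#' @export
observe <- function(truth, obs = observation_spec(), seed = 1) {
  stopifnot(inherits(truth, "wm_truth"), inherits(obs, "wm_observation_spec"))
  set.seed(seed + 2L)
  cells <- truth$cells
  n_surv <- round(obs$coverage * nrow(cells))
  if (n_surv < 1) stop("coverage yields zero surveyed locations")
  surv <- sort(sample(cells$cell_id, n_surv))
  freq_cells <- sort(sample(surv, round(obs$frac_frequency_studies * n_surv)))
  quant_cells <- sort(sample(surv, round(obs$frac_quantity_studies * n_surv)))

  hh <- truth$households[truth$households$cell_id %in% surv, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hh)), hh$cell_id), function(i)
    i[sample.int(length(i),
                 max(1, round(obs$household_sampling_fraction * length(i))))]))
  hh <- hh[sort(keep), , drop = FALSE]
  nh <- nrow(hh)

  mdays <- pmin(365, pmax(1, round(exp(stats::runif(nh, 0, log(365))))))
  miss_ame <- stats::runif(nh) < obs$frac_missing_ame

  in_freq <- hh$cell_id %in% freq_cells & mdays >= 2
  sig <- truth$params$sigma * (365 - mdays)
  freq_obs <- stats::plogis(stats::qlogis(hh$phi) +
                              sig * stats::rnorm(nh))
  freq_obs[!in_freq] <- NA

  households <- data.frame(
    household_id = hh$household_id,
    location_id = hh$cell_id,
    study_id = "sim1",
    mdays = mdays,
    frequency = freq_obs,
    education = "unknown",
    ame = ifelse(miss_ame, NA_real_, hh$ame),
    v3 = hh$v3
  )

  ## recalls: mdays one-day recalls per household
  rid <- rep(seq_len(nh), mdays)
  R <- length(rid)
  consumed <- stats::rbinom(R, 1, hh$pi[rid])
  quantity <- rep(NA_real_, R)
  qsel <- consumed == 1 & hh$cell_id[rid] %in% quant_cells
  if (any(qsel)) {
    th <- truth$params$theta
    quantity[qsel] <- stats::rgamma(sum(qsel),
                                    shape = hh$mu[rid[qsel]] * th,
                                    rate = th) * hh$ame[rid[qsel]]
  }
  quantity[consumed == 0 & hh$cell_id[rid] %in% quant_cells] <- 0
  recalls <- data.frame(
    recall_id = sprintf("rc%07d", seq_len(R)),
    household_id = hh$household_id[rid],
    days = 1,
    consumed = consumed,
    quantity_kg = quantity,
    ame = ifelse(miss_ame[rid], NA_real_, hh$ame[rid])
  )

  locations <- data.frame(
    location_id = cells$cell_id[cells$cell_id %in% surv],
    lon = cells$lon[cells$cell_id %in% surv],
    lat = cells$lat[cells$cell_id %in% surv],
    location_type = "village",
    hpd = 0, rem = 0, hdi = 0.5, fci = 0,
    region = factor(cells$region[cells$cell_id %in% surv]),
    V1 = cells$V1[cells$cell_id %in% surv],
    V2 = cells$V2[cells$cell_id %in% surv]
  )
  studies <- data.frame(study_id = "sim1", study_type = 1, period = 1)

  survey <- ingest_survey(studies, locations, households, recalls)
  list(survey = survey, truth = truth,
       surveyed_cells = surv, frequency_cells = freq_cells,
       quantity_cells = quant_cells)
}

#' One-call synthetic survey
#'
#' Convenience wrapper chaining [generate_landscape()], [simulate_truth()]
#' and [observe()] under a single seed.
#'
#' @param spec a `wm_landscape_spec`.
#' @param obs a `wm_observation_spec`.
#' @param seed integer seed.
#' @return as [observe()].
#' @export
synthetic_survey <- function(spec = landscape_spec(),
                             obs = observation_spec(), seed = 1) {
  land <- generate_landscape(spec, seed)
  truth <- simulate_truth(land, seed)
  observe(truth, obs, seed)
}
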