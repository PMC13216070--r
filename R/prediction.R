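#' Classify settlements by population size
#'
#' Villages are settlements of up to 10,000 people, towns between 10,000 and
#' 100,000, cities above 100,000. A population of exactly 10,000 (100,000) is
#' assigned to the larger class, town (city), since the village rule is "up
#' to 10,000" while towns start at ">10,000"; the boundary is resolved toward
#' the larger class and noted here.
#'
#' @param pop numeric vector of people counts (>= 0).
#' @return factor with levels `village`, `town`, `city`.
#' @export
classify_settlements <- function(pop) {
  if (any(pop < 0)) stop("population counts must be >= 0")
  cut(pop, breaks = c(-Inf, 10000, 100000, Inf),
      labels = c("village", "town", "city"), right = FALSE)
}

#' Adult male equivalents of a grid cell
#'
#' Converts a cell population into AMEs assuming an adult sex ratio of 0.5:
#' adult males weight 1, adult females 0.86 and children (age structure
#' unknown at grid scale) 0.78.
#'
#' @param pop people in the cell (>= 0).
#' @param prop_child proportion of children in the population, in \[0, 1\];
#'   the adult proportion is `1 - prop_child`.
#' @return AME count.
#' @export
grid_ame <- function(pop, prop_child) {
  stopifnot(all(pop >= 0), all(prop_child >= 0 & prop_child <= 1))
  prop_adult <- 1 - prop_child
  pop * prop_adult * 0.5 * 1 + pop * prop_adult * 0.5 * 0.86 +
    pop * prop_child * 0.78
}

#' Weight a categorical parameter by population proportions
#'
#' The prediction grid does not contain individual settlements or households,
#' so a parameter estimated per category (settlement type, education level)
#' is collapsed to a cell-level value by weighting the level parameters with
#' the proportions of people in each level — a dot product. For a two-level
#' education parameter the proportions are `(1 - ED, ED)` where `ED` is the
#' proportion with secondary-or-higher education.
#'
#' @param levels parameter values per category: a numeric vector, or a matrix
#'   of posterior draws (draws x categories).
#' @param props proportions per category, summing to 1.
#' @return weighted parameter (scalar, or vector of draws).
#' @export
weight_categorical <- function(levels, props) {
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  if (is.matrix(levels)) {
    stopifnot(ncol(levels) == length(props))
    drop(levels %*% props)
  } else {
    stopifnot(length(levels) == length(props))
    sum(levels * props)
  }
}

#' Grid geometry of the prediction landscape
#'
#' Each prediction cell has the area of the 40-km-radius circle used to
#' compute location covariates (pi * 40^2 ~ 5,027 km2). The conventional cell
#' side used downstream is 70.09 km, and the forest buffer radius used to
#' delimit the forest region is twice the cell side (140.18 km). The printed
#' side is slightly inconsistent with the printed area (sqrt(5027) = 70.90);
#' the conventional side is kept because the buffer is defined from it.
#'
#' @param buffer_radius_km radius of the covariate circle (default 40).
#' @param cell_side_km conventional cell side (default 70.09).
#' @return list with `cell_area_km2`, `cell_side_km`, `forest_buffer_km`.
#' @export
grid_geometry <- function(buffer_radius_km = 40, cell_side_km = 70.09) {
  list(cell_area_km2 = pi * buffer_radius_km^2,
       cell_side_km = cell_side_km,
       forest_buffer_km = 2 * cell_side_km)
}

#' Build a cell-level design matrix, weighting categorical covariates
#'
#' Evaluates a submodel formula on the prediction cells. Categorical
#' covariates without a cell-level value (settlement type, education, the
#' simulation's `V3`) are supplied as per-cell proportion weights: the design
#' is computed at every level combination and averaged with the product
#' weights, which is exactly the parameter-weighting of the prediction
#' equations (linearity of the design in the dummy columns).
#'
#' @param formula the submodel fixed-effects formula.
#' @param cells data.frame of prediction cells (must contain every variable
#'   of the formula; weighted factors may hold any placeholder level).
#' @param weights named list: for factor `v`, either a named numeric vector
#'   of level proportions (same for all cells) or a matrix
#'   (cells x levels, columns named by level).
#' @param xlevels factor levels of the fitted design
#'   (`mdata$cons$xlevels` etc.), ensuring identical contrasts.
#' @return design matrix (cells x coefficients).
#' @export
build_cell_design <- function(formula, cells, weights = list(),
                              xlevels = NULL) {
  for (v in names(xlevels))
    if (v %in% names(cells) && !v %in% names(weights))
      cells[[v]] <- factor(cells[[v]], levels = xlevels[[v]])
  if (!length(weights))
    return(stats::model.matrix(formula, cells))
  lev <- lapply(names(weights), function(v) {
    w <- weights[[v]]
    if (is.matrix(w)) colnames(w) else names(w)
  })
  names(lev) <- names(weights)
  combos <- expand.grid(lev, stringsAsFactors = FALSE)
  X <- NULL
  for (k in seq_len(nrow(combos))) {
    ck <- cells
    wk <- rep(1, nrow(cells))
    for (v in names(weights)) {
      ck[[v]] <- factor(combos[k, v], levels = lev[[v]])
      w <- weights[[v]]
      wk <- wk * if (is.matrix(w)) w[, combos[k, v]] else w[[combos[k, v]]]
    }
    Xk <- stats::model.matrix(formula, ck)
    X <- if (is.null(X)) Xk * wk else X + Xk * wk
  }
  X
}

.draws_for <- function(fit, block, colnames_X) {
  want <- paste0(block, "[", colnames_X, "]")
  if (length(colnames_X) == 1 && colnames_X == block) want <- block
  miss <- setdiff(want, colnames(fit$draws))
  if (length(miss))
    stop("posterior draws missing for: ", paste(miss, collapse = ", "))
  fit$draws[, want, drop = FALSE]
}

#' Posterior prediction of consumption on a grid of cells
#'
#' For every posterior draw and cell, computes the predicted consumption
#' probability (logit link), mean frequency (logit link) and mean quantity
#' per AME (log link, evaluated at the data-mean AME count), with random
#' effects at their estimated means (zero by construction) and the spatial
#' effect at its prior mean; then draws the predicted consumption flag
#' (Bernoulli), frequency (Beta with the draw's `kappa`) and quantity (Gamma
#' with the draw's `theta`) and forms the consumption rate as their product
#' (kg undressed meat per AME per day). Annual consumed biomass per cell is
#' `rate * AME * 365` kg.
#'
#' @param fit a `wm_fit`.
#' @param cells data.frame of prediction cells; must contain an `ame` column
#'   (AME count per cell) plus the covariates referenced by the design.
#' @param design named list of design matrices for `consumption`, `frequency`
#'   and `quantity`, from [build_cell_design()] (rows matching `cells`).
#' @param ame_bar mean AME per recall used in the quantity prediction;
#'   defaults to the observed data mean stored in the fit.
#' @param days recall duration at which consumption probability is evaluated
#'   (daily rates, so 1); only used if the consumption design lacks a days
#'   column. Kept as an explicit argument for transparency.
#' @param seed seed for the predictive draws.
#' @return object of class `wm_prediction`: per-cell draw matrices (`pi`,
#'   `phi`, `mu`, `rate`, `kg_year`), a per-cell `summary` data.frame
#'   (median/mean/sd/95% interval of the rate in g/AME/day and of annual kg)
#'   and `total_tonnes` (posterior draws of the regional total).
#' @export
predict_cells <- function(fit, cells, design, ame_bar = fit$mdata$ame_bar,
                          days = 1, seed = 1) {
  stopifnot(inherits(fit, "wm_fit"),
            all(c("consumption", "frequency", "quantity") %in% names(design)),
            "ame" %in% names(cells))
  set.seed(seed)
  a <- .draws_for(fit, "alpha", colnames(design$consumption))
  b <- .draws_for(fit, "beta", colnames(design$frequency))
  g <- .draws_for(fit, "gamma", colnames(design$quantity))
  g_ame <- fit$draws[, "gamma_ame"]
  kappa <- fit$draws[, "kappa"]; theta <- fit$draws[, "theta"]

  pi_m <- stats::plogis(design$consumption %*% t(a))       # cells x draws
  phi_m <- stats::plogis(design$frequency %*% t(b))
  mu_m <- exp(sweep(design$quantity %*% t(g), 2, g_ame * ame_bar, `+`))

  nc <- nrow(pi_m); nd <- ncol(pi_m)
  cons <- matrix(stats::rbinom(nc * nd, 1, pi_m), nc, nd)
  freq <- matrix(stats::rbeta(nc * nd, sweep(phi_m, 2, kappa, `*`),
                              sweep(1 - phi_m, 2, kappa, `*`)), nc, nd)
  qty <- matrix(stats::rgamma(nc * nd,
                              shape = sweep(mu_m, 2, theta, `*`),
                              rate = rep(theta, each = nc)), nc, nd)
  rate <- cons * freq * qty                                 # kg/AME/day
  kg_year <- rate * cells$ame * 365

  qs <- function(m) data.frame(
    median = apply(m, 1, stats::median), mean = rowMeans(m),
    sd = apply(m, 1, stats::sd),
    lower = apply(m, 1, stats::quantile, 0.025),
    upper = apply(m, 1, stats::quantile, 0.975))
  s_rate <- qs(rate * 1000)   # g/AME/day
  names(s_rate) <- paste0("rate_g_", names(s_rate))
  s_kg <- qs(kg_year)
  names(s_kg) <- paste0("kg_year_", names(s_kg))
  structure(list(
    pi = pi_m, phi = phi_m, mu = mu_m,
    consumption = cons, frequency = freq, quantity = qty,
    rate = rate, kg_year = kg_year,
    summary = cbind(cells[, intersect(c("cell_id", "lon", "lat", "ame"),
                                      names(cells)), drop = FALSE],
                    s_rate, s_kg),
    total_tonnes = colSums(kg_year) / 1000,
    ame_bar = ame_bar, days = days
  ), class = "wm_prediction")
}

#' @export
print.wm_prediction <- function(x, ...) {
  cat("<wm_prediction>", nrow(x$rate), "cells x", ncol(x$rate), "draws\n")
  cat("regional total:", round(stats::median(x$total_tonnes), 1),
      "t/year (median),",
      paste(round(stats::quantile(x$total_tonnes, c(0.025, 0.975)), 1),
            collapse = " - "), "(95% interval)\n")
  invisible(x)
}

#' Annual consumed biomass from a consumption rate
#'
#' `kg/year = rate * AME * 365`; tonnes are kg / 1000. Totals over cells are
#' plain sums, so biomass is additive over any partition of the grid.
#'
#' @param rate consumption rate in kg/AME/day (vector or cells-x-draws
#'   matrix).
#' @param ame AME count (scalar or per-cell vector).
#' @return list with `kg_year` and `tonnes_year` of the same shape as
#'   `rate`, plus `total_tonnes` (summed over cells).
#' @export
biomass <- function(rate, ame) {
  stopifnot(all(ame >= 0))
  kg <- rate * ame * 365
  total <- if (is.matrix(kg)) colSums(kg) / 1000 else sum(kg) / 1000
  list(kg_year = kg, tonnes_year = kg / 1000, total_tonnes = total)
}

#' Protein contribution of a wild meat consumption rate
#'
#' Only 70% of undressed meat is edible (dressed fraction) and wild meat
#' provides 29.4 g of protein per 100 g of dressed meat; the WHO recommends
#' 56 g protein per day for an adult male. A rate of 50 g/AME/day therefore
#' supplies 10 g protein, 18% of the recommendation.
#'
#' @param rate_g_per_ame_day undressed consumption rate in g/AME/day.
#' @param dressed_fraction edible fraction of undressed meat (default 0.70).
#' @param protein_per_g g protein per g of dressed meat (default 0.294).
#' @param recommended_g_day recommended daily protein intake (default 56).
#' @return data.frame with `protein_g_day` and `percent_recommended`.
#' @export
protein_contribution <- function(rate_g_per_ame_day,
                                 dressed_fraction = 0.70,
                                 protein_per_g = 0.294,
                                 recommended_g_day = 56) {
  stopifnot(all(rate_g_per_ame_day >= 0))
  protein <- rate_g_per_ame_day * dressed_fraction * protein_per_g
  data.frame(protein_g_day = protein,
             percent_recommended = protein / recommended_g_day * 100)
}

#' Covariate dissimilarity between prediction cells and the survey data
#'
#' Extrapolation-risk map: for each continuous covariate, the absolute
#' difference between the cell value and the recall-weighted data mean,
#' normalized by the maximum absolute difference across cells (to \[0, 1\]);
#' the dissimilarity index is the sum over the four covariates, from 0 (cell
#' at the data means) to 4 (maximum difference on every covariate).
#'
#' @param cells data.frame of prediction cells containing `vars`.
#' @param recall_covariates data.frame with one row per recall event and the
#'   same `vars` (the covariates assigned to each recall), so the means are
#'   recall-weighted.
#' @param vars covariate names (default the four continuous drivers).
#' @return list with `M_bar` (data means), `delta_prime` (cells x vars,
#'   normalized differences) and `Delta` (per-cell index in \[0, length(vars)\]).
#' @export
dissimilarity_index <- function(cells, recall_covariates,
                                vars = c("hpd", "rem", "hdi", "fci")) {
  stopifnot(all(vars %in% names(cells)), all(vars %in% names(recall_covariates)))
  M_bar <- vapply(recall_covariates[vars], mean, 0)
  dp <- vapply(vars, function(v) {
    d <- abs(cells[[v]] - M_bar[[v]])
    mx <- max(d)
    if (mx == 0)
      stop("covariate '", v, "' is constant at the data mean across cells; ",
           "normalization undefined")
    d / mx
  }, numeric(nrow(cells)))
  list(M_bar = M_bar, delta_prime = dp, Delta = rowSums(dp))
}
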