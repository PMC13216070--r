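#' Assemble model-ready data for the joint consumption model
#'
#' Turns a validated `wm_survey` into the internal structure used by the
#' likelihood functions and the posterior sampler. Each submodel gets a fixed
#' effects design matrix built from an R formula evaluated on the appropriate
#' level of the data:
#'
#' * `consumption`: recall level (recalls joined to households, locations and
#'   studies). Bernoulli likelihood for the consumption flag. Recalls sharing
#'   a design row are grouped into binomial counts (an exact reduction).
#' * `frequency`: household level, restricted to households with an observed
#'   frequency. Beta likelihood with monitoring-duration-dependent noise.
#' * `quantity`: recall level, restricted to consumption recalls with an
#'   observed positive quantity. Gamma likelihood for quantity per AME; the
#'   AME term is handled separately from the formula because missing AMEs are
#'   model parameters (Bayesian imputation).
#'
#' Observed frequencies exactly 0 or 1 are clamped to
#' `[clamp, 1 - clamp]` before the Beta likelihood; the number of clamped
#' records is reported in the returned object.
#'
#' @param survey a `wm_survey` from [ingest_survey()].
#' @param consumption,frequency,quantity right-hand-side formulas for the
#'   fixed effects of each submodel (e.g. `~ hpd:location_type + hdi + rem +
#'   fci + education + days`).
#' @param spatial character subset of `c("consumption", "frequency")`: which
#'   submodels carry a latent Gaussian-process spatial effect (each submodel
#'   gets its own GP; they share the distance matrix).
#' @param random character subset of `c("study", "household")`: random
#'   intercepts entering the consumption and quantity submodels.
#' @param clamp boundary clamp for observed frequencies (default `1e-4`).
#' @param distance_method passed to [build_distance_matrix()].
#' @return object of class `wm_model_data`.
#' @export
prepare_model_data <- function(survey,
                               consumption = ~1, frequency = ~1,
                               quantity = ~1,
                               spatial = c("consumption", "frequency"),
                               random = character(),
                               clamp = 1e-4,
                               distance_method = "haversine") {
  stopifnot(inherits(survey, "wm_survey"))
  spatial <- intersect(spatial, c("consumption", "frequency"))
  random <- intersect(random, c("study", "household"))

  loc <- survey$locations
  hh <- survey$households
  rc <- survey$recalls
  loc$.loc_idx <- seq_len(nrow(loc))
  hh$.hh_idx <- seq_len(nrow(hh))

  hh_full <- merge(hh, loc, by = "location_id", sort = FALSE)
  if ("study_id" %in% names(hh) && nrow(survey$studies) > 0)
    hh_full <- merge(hh_full, survey$studies, by = "study_id", sort = FALSE)
  hh_full <- hh_full[order(hh_full$.hh_idx), , drop = FALSE]

  rc_full <- merge(rc, hh_full, by = "household_id", sort = FALSE,
                   suffixes = c("", ".hh"))

  mm <- function(f, data) {
    mf <- stats::model.frame(f, data, na.action = stats::na.fail)
    list(X = stats::model.matrix(f, mf), terms = stats::terms(mf),
         xlevels = stats::.getXlevels(stats::terms(mf), mf))
  }

  ## --- consumption (recall level, grouped to binomial counts) ----------
  dc <- mm(consumption, rc_full)
  key <- apply(cbind(dc$X, rc_full$.hh_idx), 1, paste, collapse = "\r")
  grp <- match(key, unique(key))
  first <- !duplicated(grp)
  grp_f <- factor(grp, levels = unique(grp))   # keep first-appearance order
  cons <- list(
    X = dc$X[first, , drop = FALSE],
    events = as.numeric(tapply(rc_full$consumed, grp_f, sum)),
    trials = as.numeric(table(grp_f)),
    loc = rc_full$.loc_idx[first],
    study = if ("study_id" %in% names(rc_full))
      match(rc_full$study_id, unique(rc_full$study_id))[first] else NULL,
    house = rc_full$.hh_idx[first],
    terms = dc$terms, xlevels = dc$xlevels
  )

  ## --- frequency (household level) --------------------------------------
  fh <- hh_full[!is.na(hh_full$frequency), , drop = FALSE]
  n_clamped <- sum(fh$frequency <= clamp | fh$frequency >= 1 - clamp)
  y <- pmin(pmax(fh$frequency, clamp), 1 - clamp)
  df <- mm(frequency, fh)
  freq <- list(X = df$X, y = y, mdays = fh$mdays,
               sig_base = 365 - fh$mdays, loc = fh$.loc_idx,
               terms = df$terms, xlevels = df$xlevels)

  ## --- quantity (recall level, observed positive quantities) ------------
  qr <- rc_full[!is.na(rc_full$quantity_kg) & rc_full$quantity_kg > 0 &
                  rc_full$consumed == 1, , drop = FALSE]
  dq <- mm(quantity, qr)
  ame_obs <- qr$ame                       # NA where to be imputed
  miss_hh <- unique(qr$.hh_idx[is.na(ame_obs)])
  quant <- list(
    X = dq$X, q = qr$quantity_kg / qr$days, ame = ame_obs,
    imput_id = ifelse(is.na(ame_obs), match(qr$.hh_idx, miss_hh), 0L),
    loc = qr$.loc_idx,
    study = if ("study_id" %in% names(qr))
      match(qr$study_id, unique(rc_full$study_id)) else NULL,
    house = qr$.hh_idx,
    terms = dq$terms, xlevels = dq$xlevels
  )

  D <- build_distance_matrix(loc, method = distance_method)

  ame_obs <- hh$ame[!is.na(hh$ame)]
  nu_centre <- if (length(ame_obs)) mean(ame_obs) else 5.09

  structure(list(
    cons = cons, freq = freq, quant = quant,
    D = D, n_loc = nrow(loc), n_house = nrow(hh),
    n_study = if ("study_id" %in% names(rc_full))
      length(unique(rc_full$study_id)) else 0L,
    n_miss_ame = length(miss_hh),
    ame_obs = ame_obs,
    spatial = spatial, random = random,
    clamp = clamp, n_clamped = n_clamped,
    nu_centre = nu_centre,
    ame_bar = nu_centre,
    formulas = list(consumption = consumption, frequency = frequency,
                    quantity = quantity)
  ), class = "wm_model_data")
}

#' @export
print.wm_model_data <- function(x, ...) {
  cat("<wm_model_data>\n")
  cat("  consumption:", nrow(x$cons$X), "binomial rows (",
      sum(x$cons$trials), "recalls ),", ncol(x$cons$X), "coefficients\n")
  cat("  frequency:  ", nrow(x$freq$X), "households,", ncol(x$freq$X),
      "coefficients,", x$n_clamped, "clamped\n")
  cat("  quantity:   ", nrow(x$quant$X), "recalls,", ncol(x$quant$X),
      "coefficients + AME slope,", x$n_miss_ame, "AMEs imputed\n")
  cat("  locations:  ", x$n_loc, "| spatial:",
      paste(x$spatial, collapse = "+"), "| random:",
      if (length(x$random)) paste(x$random, collapse = "+") else "none", "\n")
  invisible(x)
}
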