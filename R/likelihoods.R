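## Likelihood terms of the joint model.
##
## A parameter state is a plain list; the fields used here are
##   alpha, beta, gamma    coefficient vectors matched to the design columns
##   gamma_ame             slope of quantity-per-AME on the AME count
##   sigma                 per-unmonitored-day sd of the frequency noise
##   kappa, theta          Beta sample size, Gamma rate
##   tau                   standard-normal non-centring variates (frequency)
##   zeta_c/rho_c/eta_c    GP for the consumption submodel
##   zeta_f/rho_f/eta_f    GP for the frequency submodel
##   nu, psi, ame_mis      AME imputation
##   re_*, sd_*            optional study/household random intercepts

.spatial_eps <- function(state, mdata, which) {
  if (!(which %in% mdata$spatial)) return(rep(0, mdata$n_loc))
  if (which == "consumption")
    gp_eps(state$zeta_c, state$rho_c, mdata$D, state$eta_c)
  else
    gp_eps(state$zeta_f, state$rho_f, mdata$D, state$eta_f)
}

.re_term <- function(state, mdata, block, idx_study, idx_house) {
  out <- 0
  if ("study" %in% mdata$random && !is.null(idx_study))
    out <- out + state[[paste0("re_study_", block)]][idx_study]
  if ("household" %in% mdata$random)
    out <- out + state[[paste0("re_house_", block)]][idx_house]
  out
}

#' Bernoulli log-likelihood of the consumption submodel
#'
#' Sum over recall events of the Bernoulli log-mass at
#' `plogis(X alpha + spatial effect + random intercepts)`. Recalls sharing a
#' design row are evaluated as binomial counts, which is numerically
#' identical to the per-recall sum.
#'
#' @param state parameter state list (see source file header).
#' @param mdata a `wm_model_data`.
#' @param eps optional spatial effect vector per location; computed from the
#'   state's GP parameters when omitted.
#' @return scalar log-likelihood.
#' @export
loglik_consumption <- function(state, mdata, eps = NULL) {
  cc <- mdata$cons
  if (is.null(eps)) eps <- .spatial_eps(state, mdata, "consumption")
  lp <- drop(cc$X %*% state$alpha) + eps[cc$loc] +
    .re_term(state, mdata, "c", cc$study, cc$house)
  sum(cc$events * stats::plogis(lp, log.p = TRUE) +
        (cc$trials - cc$events) * stats::plogis(-lp, log.p = TRUE))
}

# Beta data likelihood only (no tau prior); used by the sampler
.ll_freq_data <- function(state, mdata, eps = NULL) {
  ff <- mdata$freq
  if (is.null(eps)) eps <- .spatial_eps(state, mdata, "frequency")
  phibar <- drop(ff$X %*% state$beta) + eps[ff$loc]
  phi <- stats::plogis(phibar + state$sigma * ff$sig_base * state$tau)
  sum(stats::dbeta(ff$y, phi * state$kappa, (1 - phi) * state$kappa,
                   log = TRUE))
}

#' Beta log-likelihood of the frequency submodel (non-centred)
#'
#' The household mean frequency is
#' `phi_h = plogis(phibar_h + Sigma_h * tau_h)` with
#' `Sigma_h = sigma * (365 - mdays_h)`, so a household monitored on all 365
#' days has no observation noise. The observed frequency follows
#' `Beta(phi_h * kappa, (1 - phi_h) * kappa)`. The standard-normal
#' log-density of the non-centring variates `tau` is included, making this
#' the complete frequency block of the joint density.
#'
#' @inheritParams loglik_consumption
#' @return scalar log-likelihood.
#' @export
loglik_frequency <- function(state, mdata, eps = NULL) {
  if (any(mdata$freq$mdays > 365)) stop("mdays must not exceed 365")
  .ll_freq_data(state, mdata, eps) +
    sum(stats::dnorm(state$tau, log = TRUE))
}

# quantity-per-AME vector with imputed values merged in
.ame_merged <- function(state, mdata) {
  qq <- mdata$quant
  ame <- qq$ame
  if (mdata$n_miss_ame > 0) {
    m <- qq$imput_id > 0
    ame[m] <- state$ame_mis[qq$imput_id[m]]
  }
  ame
}

#' Gamma log-likelihood of the quantity submodel
#'
#' Quantity per AME follows `Gamma(mu_r * theta, theta)` (shape-rate), so the
#' mean is `mu_r = exp(X gamma + gamma_ame * AME_r + random intercepts)` and
#' the variance `mu_r / theta`. Missing AMEs are taken from the state's
#' imputed values (`ame_mis`); the truncated-normal imputation prior is a
#' separate term of [log_posterior()].
#'
#' @inheritParams loglik_consumption
#' @return scalar log-likelihood.
#' @export
loglik_quantity <- function(state, mdata) {
  qq <- mdata$quant
  if (any(qq$q <= 0)) stop("quantity reaching the Gamma likelihood must be > 0")
  ame <- .ame_merged(state, mdata)
  mu <- exp(drop(qq$X %*% state$gamma) + state$gamma_ame * ame +
              .re_term(state, mdata, "q", qq$study, qq$house))
  sum(stats::dgamma(qq$q / ame, shape = mu * state$theta,
                    rate = state$theta, log = TRUE))
}

#' Gaussian-process covariance and its Cholesky factor
#'
#' Exponentiated-quadratic kernel over the location distance matrix:
#' `X[l,j] = zeta^2 * exp(-rho^2 * D[l,j]^2)`, with a fixed jitter
#' `delta = 1e-9` added to the diagonal so the matrix stays positive
#' definite. Returns the covariance and its lower-triangular Cholesky factor.
#'
#' @param zeta marginal sd (maximum covariance between sites).
#' @param rho inverse length scale: rate of decay of covariance with distance
#'   (1/km when `D` is in km).
#' @param D symmetric hollow distance matrix.
#' @param delta diagonal jitter (default `1e-9`).
#' @return list with `X` (covariance) and `LX` (lower Cholesky factor).
#' @export
gp_build <- function(zeta, rho, D, delta = 1e-9) {
  stopifnot(isSymmetric(unname(D)), all(diag(D) == 0))
  X <- zeta^2 * exp(-rho^2 * D^2)
  diag(X) <- diag(X) + delta
  LX <- tryCatch(t(chol(X)), error = function(e)
    stop("Cholesky factorization failed; the kernel matrix is not positive ",
         "definite at delta = ", delta, " - consider a larger jitter"))
  list(X = X, LX = LX)
}

#' Latent spatial effects from the non-centred parameterization
#'
#' Maps standard-normal variates through the Cholesky factor of the kernel
#' matrix: `eps = LX %*% eta`, so `eps` has the Gaussian-process prior
#' distribution with covariance from [gp_build()].
#'
#' @inheritParams gp_build
#' @param eta standard-normal vector, one entry per location.
#' @return numeric vector of spatial effects.
#' @export
gp_eps <- function(zeta, rho, D, eta, delta = 1e-9) {
  drop(gp_build(zeta, rho, D, delta)$LX %*% eta)
}

#' Weakly informative default priors
#'
#' Normal(0, 2.5) on all logit/log-scale coefficients; half-Normal(0, 2) on
#' the GP marginal sd `zeta`, the frequency noise rate `sigma` and the
#' imputation sd `psi`; half-Normal(0, 0.05) on the GP inverse length scale
#' `rho` (distances in km, so this admits length scales from ~20 km up);
#' half-Normal(0, 1) on the Beta noise scale `1/sqrt(kappa)` (a prior on
#' the sd scale stays flat as the noise vanishes, so the posterior can push
#' the Beta sample size `kappa` arbitrarily high when the data carry no
#' observation noise beyond the monitoring channel — any prior with an
#' exponential tail in `kappa` itself caps the precision and biases the
#' frequency intercepts); Gamma(2, 0.1) on the Gamma rate `theta`;
#' Normal(centre, 2) truncated at 0 on the imputation mean `nu`, centred at
#' the mean of the observed AMEs; half-Normal(0, 1) on random-intercept sds.
#' All values can be overridden via the `...` arguments.
#'
#' @param mdata optional `wm_model_data`; supplies the `nu` centre.
#' @param ... named overrides of individual entries.
#' @return named list of prior settings.
#' @export
default_priors <- function(mdata = NULL, ...) {
  p <- list(coef_sd = 2.5, zeta_sd = 2, sigma_sd = 2, rho_sd = 0.05,
            kappa_sd = 1, theta = c(2, 0.1),
            nu_centre = if (!is.null(mdata)) mdata$nu_centre else 5.09,
            nu_sd = 2, psi_sd = 2, re_sd = 1)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

.lhalfnorm <- function(x, sd) {
  ifelse(x < 0, -Inf, log(2) + stats::dnorm(x, 0, sd, log = TRUE))
}

.ltruncnorm0 <- function(x, mean, sd) {
  ifelse(x <= 0, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

# prior density of the Beta sample size kappa, parameterized through the
# Beta noise scale 1/sqrt(kappa) ~ half-Normal(0, sd): flat near zero noise,
# so the posterior can express "no extra observation noise" (kappa large)
# without fighting an exponential prior tail
.lkappa_prior <- function(kappa, sd) {
  ifelse(kappa <= 0, -Inf,
         .lhalfnorm(1 / sqrt(kappa), sd) + log(0.5) - 1.5 * log(kappa))
}

# log-prior of everything except tau (inside loglik_frequency) and eta
.log_prior <- function(state, mdata, priors) {
  lp <- sum(stats::dnorm(c(state$alpha, state$beta, state$gamma,
                           state$gamma_ame), 0, priors$coef_sd, log = TRUE))
  if ("consumption" %in% mdata$spatial)
    lp <- lp + .lhalfnorm(state$zeta_c, priors$zeta_sd) +
      .lhalfnorm(state$rho_c, priors$rho_sd)
  if ("frequency" %in% mdata$spatial)
    lp <- lp + .lhalfnorm(state$zeta_f, priors$zeta_sd) +
      .lhalfnorm(state$rho_f, priors$rho_sd)
  lp <- lp + .lhalfnorm(state$sigma, priors$sigma_sd) +
    .lkappa_prior(state$kappa, priors$kappa_sd) +
    stats::dgamma(state$theta, priors$theta[1], priors$theta[2], log = TRUE) +
    .ltruncnorm0(state$nu, priors$nu_centre, priors$nu_sd) +
    .lhalfnorm(state$psi, priors$psi_sd)
  for (blk in c("c", "q")) {
    for (lev in c("study", "house")) {
      re <- state[[paste0("re_", lev, "_", blk)]]
      if (!is.null(re)) {
        sd_re <- state[[paste0("sd_", lev, "_", blk)]]
        lp <- lp + sum(stats::dnorm(re, 0, sd_re, log = TRUE)) +
          .lhalfnorm(sd_re, priors$re_sd)
      }
    }
  }
  lp
}

#' Joint log-posterior density of the full model
#'
#' Sum of the three submodel log-likelihoods, the standard-normal log-density
#' of the GP non-centring variates, the truncated-normal imputation terms for
#' missing AMEs, and the priors. With
#' `parameterization = "centred"` the state instead carries the natural
#' latent quantities (`eps_c`/`eps_f` with multivariate-normal GP priors and
#' `logit_phi` with its Normal(phibar, Sigma) prior); both parameterizations
#' define the same joint distribution, related by the linear change of
#' variables `eps = LX eta`, `logit_phi = phibar + Sigma tau`.
#'
#' @inheritParams loglik_consumption
#' @param priors prior settings from [default_priors()].
#' @param parameterization `"noncentred"` (sampling scale, default) or
#'   `"centred"`.
#' @param on_nonfinite `"error"` (name the offending term) or `"value"`
#'   (return the non-finite value, used internally by the sampler).
#' @return scalar log-density (unnormalized).
#' @export
log_posterior <- function(state, mdata, priors = default_priors(mdata),
                          parameterization = c("noncentred", "centred"),
                          on_nonfinite = c("error", "value")) {
  parameterization <- match.arg(parameterization)
  on_nonfinite <- match.arg(on_nonfinite)
  terms <- list()
  if (parameterization == "noncentred") {
    terms$consumption <- loglik_consumption(state, mdata)
    terms$frequency <- loglik_frequency(state, mdata)
    terms$quantity <- loglik_quantity(state, mdata)
    if ("consumption" %in% mdata$spatial)
      terms$gp_consumption <- sum(stats::dnorm(state$eta_c, log = TRUE))
    if ("frequency" %in% mdata$spatial)
      terms$gp_frequency <- sum(stats::dnorm(state$eta_f, log = TRUE))
  } else {
    eps_c <- if ("consumption" %in% mdata$spatial) state$eps_c else
      rep(0, mdata$n_loc)
    eps_f <- if ("frequency" %in% mdata$spatial) state$eps_f else
      rep(0, mdata$n_loc)
    terms$consumption <- loglik_consumption(state, mdata, eps = eps_c)
    ff <- mdata$freq
    phi <- stats::plogis(state$logit_phi)
    terms$frequency <- sum(stats::dbeta(ff$y, phi * state$kappa,
                                        (1 - phi) * state$kappa, log = TRUE))
    phibar <- drop(ff$X %*% state$beta) + eps_f[ff$loc]
    Sig <- state$sigma * ff$sig_base
    terms$frequency_latent <-
      sum(stats::dnorm(state$logit_phi, phibar, Sig, log = TRUE))
    terms$quantity <- loglik_quantity(state, mdata)
    mvn_lp <- function(eps, zeta, rho) {
      LX <- gp_build(zeta, rho, mdata$D)$LX
      z <- forwardsolve(LX, eps)
      -sum(log(diag(LX))) - 0.5 * sum(z^2) -
        0.5 * length(eps) * log(2 * pi)
    }
    if ("consumption" %in% mdata$spatial)
      terms$gp_consumption <- mvn_lp(eps_c, state$zeta_c, state$rho_c)
    if ("frequency" %in% mdata$spatial)
      terms$gp_frequency <- mvn_lp(eps_f, state$zeta_f, state$rho_f)
  }
  # truncated-normal population model for household AME: observed values
  # inform (nu, psi); missing ones are imputed from the same distribution
  if (mdata$n_miss_ame > 0 || length(mdata$ame_obs))
    terms$imputation <- sum(.ltruncnorm0(c(mdata$ame_obs, state$ame_mis),
                                         state$nu, state$psi))
  # change of variables: the observed datum is the quantity, so rows whose
  # AME is a parameter carry the -log(AME) Jacobian of q -> q/AME (without
  # it the density has an improper ridge in the imputed AME when the Gamma
  # shape is below 1)
  if (mdata$n_miss_ame > 0) {
    id <- mdata$quant$imput_id
    terms$quantity_jacobian <- -sum(log(state$ame_mis[id[id > 0]]))
  }
  terms$prior <- .log_prior(state, mdata, priors)
  vals <- unlist(terms)
  if (on_nonfinite == "error" && any(!is.finite(vals)))
    stop("non-finite log-posterior term: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  sum(vals)
}
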