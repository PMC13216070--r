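## Posterior sampling for the joint model.
##
## The sampler combines, per iteration:
##  * adaptive-Metropolis blocks (Haario-style, proposal covariance learned
##    during warmup) for the coefficient vectors of each submodel and for the
##    (log) GP hyperparameters;
##  * elliptical slice sampling for the GP non-centring variates eta and the
##    frequency non-centring variates tau (their priors are standard normal,
##    which is exactly the setting elliptical slice sampling is exact for);
##  * element-wise vectorized Metropolis for imputed AMEs and random
##    intercepts (conditionally independent given the rest);
##  * scalar adaptive random walks on log scales for sigma, kappa, theta, psi
##    and the random-intercept sds.
## Adaptation runs during warmup only and is frozen afterwards.

# Robbins-Monro step for a log proposal scale
.adapt <- function(log_s, acc, t, target) {
  log_s + min(0.25, t^-0.6) * (acc - target)
}

.ess_step <- function(f, ll_fun, ll_cur) {
  # elliptical slice sampling step for f ~ N(0, I) a priori
  nu <- stats::rnorm(length(f))
  logy <- ll_cur + log(stats::runif(1))
  th <- stats::runif(1, 0, 2 * pi)
  lo <- th - 2 * pi; hi <- th
  repeat {
    fp <- f * cos(th) + nu * sin(th)
    llp <- ll_fun(fp)
    if (is.finite(llp) && llp > logy) return(list(f = fp, ll = llp))
    if (th < 0) lo <- th else hi <- th
    th <- stats::runif(1, lo, hi)
    if (hi - lo < 1e-10) return(list(f = f, ll = ll_cur))
  }
}

## Generalized-linear-model fits of each submodel (ignoring the latent
## structure) provide starting values and, through their estimated
## coefficient covariances, preconditioning for the Metropolis proposals.
# ridge-regularized coefficient covariance from a (possibly rank-deficient)
# weighted design; NA coefficients are dropped to zero
.ridge_cov <- function(X, w, scale = 1) {
  A <- crossprod(X * sqrt(w))
  lam <- 1e-6 * mean(diag(A)) + 1e-10
  solve(A + diag(lam, ncol(A))) * scale
}

.glm_inits <- function(mdata) {
  fix <- function(coef) ifelse(is.finite(coef), coef, 0)
  out <- list()
  cc <- mdata$cons
  out$alpha <- tryCatch({
    f <- suppressWarnings(stats::glm.fit(cc$X, cc$events / cc$trials,
                                         weights = cc$trials,
                                         family = stats::binomial()))
    list(coef = fix(unname(f$coefficients)),
         cov = .ridge_cov(cc$X, f$weights))
  }, error = function(e) NULL)
  ff <- mdata$freq
  out$beta <- tryCatch({
    f <- stats::lm.fit(ff$X, stats::qlogis(ff$y))
    s2 <- sum(f$residuals^2) / max(1, nrow(ff$X) - ncol(ff$X))
    list(coef = fix(unname(f$coefficients)),
         cov = .ridge_cov(ff$X, rep(1, nrow(ff$X)), s2))
  }, error = function(e) NULL)
  qq <- mdata$quant
  ok <- qq$imput_id == 0
  out$gamma <- tryCatch({
    X <- cbind(qq$X[ok, , drop = FALSE], ame = qq$ame[ok])
    y <- qq$q[ok] / qq$ame[ok]
    f <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::Gamma("log")))
    disp <- sum((y - f$fitted.values)^2 / f$fitted.values^2) /
      max(1, sum(ok) - ncol(X))
    list(coef = fix(unname(f$coefficients)),
         cov = .ridge_cov(X, f$weights, disp))
  }, error = function(e) NULL)
  out
}

.init_state <- function(mdata, priors, jitter = 0, inits = NULL) {
  st <- list(
    alpha = stats::rnorm(ncol(mdata$cons$X), 0, jitter),
    beta = stats::rnorm(ncol(mdata$freq$X), 0, jitter),
    gamma = stats::rnorm(ncol(mdata$quant$X), 0, jitter),
    gamma_ame = stats::rnorm(1, 0, jitter),
    sigma = 0.002 * exp(stats::rnorm(1, 0, jitter)),
    kappa = 10 * exp(stats::rnorm(1, 0, jitter)),
    theta = 5 * exp(stats::rnorm(1, 0, jitter)),
    tau = rep(0, nrow(mdata$freq$X)),
    nu = priors$nu_centre,
    psi = if (length(mdata$ame_obs) > 1) stats::sd(mdata$ame_obs) else 1,
    ame_mis = rep(priors$nu_centre, mdata$n_miss_ame)
  )
  if (!is.null(inits)) {
    if (!is.null(inits$alpha) && all(is.finite(inits$alpha$coef)))
      st$alpha <- st$alpha + inits$alpha$coef
    if (!is.null(inits$beta) && all(is.finite(inits$beta$coef)))
      st$beta <- st$beta + inits$beta$coef
    if (!is.null(inits$gamma) && all(is.finite(inits$gamma$coef))) {
      p <- ncol(mdata$quant$X)
      st$gamma <- st$gamma + inits$gamma$coef[seq_len(p)]
      st$gamma_ame <- st$gamma_ame + unname(inits$gamma$coef[p + 1])
    }
  }
  names(st$alpha) <- colnames(mdata$cons$X)
  names(st$beta) <- colnames(mdata$freq$X)
  names(st$gamma) <- colnames(mdata$quant$X)
  if ("consumption" %in% mdata$spatial) {
    st$zeta_c <- 0.5; st$rho_c <- 0.01
    st$eta_c <- rep(0, mdata$n_loc)
  }
  if ("frequency" %in% mdata$spatial) {
    st$zeta_f <- 0.5; st$rho_f <- 0.01
    st$eta_f <- rep(0, mdata$n_loc)
  }
  if ("study" %in% mdata$random) {
    st$re_study_c <- rep(0, mdata$n_study); st$sd_study_c <- 0.5
    st$re_study_q <- rep(0, mdata$n_study); st$sd_study_q <- 0.5
  }
  if ("household" %in% mdata$random) {
    st$re_house_c <- rep(0, mdata$n_house); st$sd_house_c <- 0.5
    st$re_house_q <- rep(0, mdata$n_house); st$sd_house_q <- 0.5
  }
  st
}

.flatten_state <- function(st, monitor_latent = FALSE) {
  keep <- c("alpha", "beta", "gamma", "gamma_ame", "sigma", "kappa", "theta",
            "zeta_c", "rho_c", "zeta_f", "rho_f", "nu", "psi",
            "sd_study_c", "sd_study_q", "sd_house_c", "sd_house_q")
  if (monitor_latent)
    keep <- c(keep, "eta_c", "eta_f", "tau", "ame_mis",
              "re_study_c", "re_study_q")
  out <- numeric(0)
  for (nm in keep) {
    v <- st[[nm]]
    if (is.null(v)) next
    if (length(v) == 1 && is.null(names(v))) names(v) <- nm
    else names(v) <- paste0(nm, "[", if (!is.null(names(st[[nm]])))
      names(st[[nm]]) else seq_along(v), "]")
    out <- c(out, v)
  }
  out
}

#' Split potential-scale-reduction factor (Rhat)
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting half-chains, so convergence failures
#' within a single chain are also detected.
#'
#' @param x numeric vector of draws (chains stacked).
#' @param chain integer vector of the same length giving the chain of each
#'   draw.
#' @return scalar Rhat (NA for fewer than 4 draws or zero-variance chains).
#' @export
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    n2 <- floor(length(xs) / 2)
    if (n2 < 2) next
    halves <- c(halves, list(xs[1:n2], xs[(n2 + 1):(2 * n2)]))
  }
  if (length(halves) < 2) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[1:n])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sample the joint posterior
#'
#' Runs the block sampler described in the package vignette: adaptive
#' Metropolis for coefficient blocks and GP hyperparameters, elliptical slice
#' sampling for the non-centring latents, element-wise Metropolis for imputed
#' AMEs and random intercepts. Adaptation happens during warmup only. The
#' run is fully reproducible: the same seed, data and configuration give
#' identical draws.
#'
#' @param mdata a `wm_model_data` from [prepare_model_data()].
#' @param chains number of chains (run sequentially), default 2.
#' @param iterations total iterations per chain, default 1500.
#' @param warmup warmup (adaptation) iterations discarded from the output,
#'   default 1000.
#' @param seed integer seed governing all randomness.
#' @param priors prior settings, see [default_priors()].
#' @param monitor_latent also store the latent vectors (eta, tau, imputed
#'   AMEs); default `FALSE`.
#' @param progress print a line per chain, default `FALSE`.
#' @param sweeps block-schedule passes per iteration (default 2). Several
#'   passes per recorded draw shorten autocorrelation times at modest cost;
#'   the coefficient/spatial-field ridge moves run once per pass.
#' @return object of class `wm_fit` with elements `draws` (matrix, kept
#'   draws x parameters), `chain` (chain index per row), `rhat` (named
#'   vector, split-Rhat per monitored scalar), `acceptance` (per block),
#'   `mdata`, `priors` and the sampler configuration. Parameters whose Rhat
#'   exceeds 1.01 are listed in a warning, never hidden.
#' @export
sample_posterior <- function(mdata, chains = 2, iterations = 1500,
                             warmup = 1000, seed = 1,
                             priors = default_priors(mdata),
                             monitor_latent = FALSE, progress = FALSE,
                             sweeps = 3) {
  stopifnot(inherits(mdata, "wm_model_data"), warmup < iterations)
  inits <- .glm_inits(mdata)
  all_draws <- NULL; chain_id <- integer(0); acc_all <- list()
  for (ch in seq_len(chains)) {
    set.seed((seed * 97 + ch * 1009) %% .Machine$integer.max)
    res <- .run_chain(mdata, iterations, warmup, priors,
                      jitter = if (ch == 1) 0 else 0.1,
                      monitor_latent = monitor_latent, inits = inits,
                      sweeps = sweeps)
    all_draws <- rbind(all_draws, res$draws)
    chain_id <- c(chain_id, rep(ch, nrow(res$draws)))
    acc_all[[ch]] <- res$acc
    if (progress)
      cat(sprintf("chain %d: %d draws kept, lp = %.1f\n",
                  ch, nrow(res$draws), res$lp))
  }
  rhat <- apply(all_draws, 2, split_rhat, chain = chain_id)
  acc <- Reduce(`+`, acc_all) / chains
  fit <- structure(list(draws = all_draws, chain = chain_id, rhat = rhat,
                        acceptance = acc, mdata = mdata, priors = priors,
                        config = list(chains = chains,
                                      iterations = iterations,
                                      warmup = warmup, seed = seed),
                        n_clamped = mdata$n_clamped),
                   class = "wm_fit")
  bad <- names(rhat)[!is.na(rhat) & rhat > 1.01]
  if (length(bad))
    warning("Rhat > 1.01 for: ", paste(bad, collapse = ", "),
            " - treat these marginals with caution", call. = FALSE)
  low <- names(acc)[acc < 0.02]
  if (length(low))
    warning("very low acceptance rate in block(s): ",
            paste(low, collapse = ", "), call. = FALSE)
  fit
}

.run_chain <- function(mdata, iterations, warmup, priors, jitter,
                       monitor_latent, inits = NULL, sweeps = 3) {
  st <- .init_state(mdata, priors, jitter, inits)
  sp_c <- "consumption" %in% mdata$spatial
  sp_f <- "frequency" %in% mdata$spatial

  cache <- new.env(parent = emptyenv())
  refresh_gp <- function(which) {
    if (which == "c" && sp_c) {
      cache$LX_c <- gp_build(st$zeta_c, st$rho_c, mdata$D)$LX
      cache$eps_c <- drop(cache$LX_c %*% st$eta_c)
    }
    if (which == "f" && sp_f) {
      cache$LX_f <- gp_build(st$zeta_f, st$rho_f, mdata$D)$LX
      cache$eps_f <- drop(cache$LX_f %*% st$eta_f)
    }
  }
  if (sp_c) refresh_gp("c") else cache$eps_c <- rep(0, mdata$n_loc)
  if (sp_f) refresh_gp("f") else cache$eps_f <- rep(0, mdata$n_loc)

  ll_cons <- function(s) loglik_consumption(s, mdata, eps = cache$eps_c)
  ll_freq <- function(s) .ll_freq_data(s, mdata, eps = cache$eps_f)
  ll_quant <- function(s) loglik_quantity(s, mdata)

  ## location-level columns of a design: their effect on the linear
  ## predictor can be absorbed exactly by the spatial field, so coefficient
  ## shifts along that ridge are proposed jointly with a compensating eps
  ## move (likelihood-invariant; accepted on the prior ratio)
  loc_design <- function(X, loc) {
    if (!nrow(X)) return(NULL)
    const <- vapply(seq_len(ncol(X)), function(j)
      all(tapply(X[, j], loc, function(v) max(v) - min(v)) == 0), TRUE)
    if (!any(const)) return(NULL)
    M <- matrix(0, mdata$n_loc, sum(const))
    M[loc, ] <- X[, const, drop = FALSE]
    list(cols = which(const), M = M)
  }
  ld_c <- if (sp_c) loc_design(mdata$cons$X, mdata$cons$loc) else NULL
  ld_f <- if (sp_f) loc_design(mdata$freq$X, mdata$freq$loc) else NULL

  ## ---- adaptive-Metropolis machinery -----------------------------------
  am_new <- function(d, scale = 0.1 / sqrt(d), cov0 = NULL) {
    e <- new.env(parent = emptyenv())
    e$d <- d; e$log_s <- log(scale); e$n <- 0
    e$mean <- rep(0, d); e$M2 <- diag(d) * 0; e$chol <- NULL
    if (!is.null(cov0)) {
      e$chol <- tryCatch(chol(cov0), error = function(err) NULL)
      if (!is.null(e$chol)) e$log_s <- log(2.38 / sqrt(d))
    }
    e$acc <- 0; e$tries <- 0
    e
  }
  am_update_stats <- function(e, x) {
    e$n <- e$n + 1
    dlt <- x - e$mean
    e$mean <- e$mean + dlt / e$n
    e$M2 <- e$M2 + tcrossprod(dlt, x - e$mean)
    if (e$n > max(100, 2 * e$d) && e$n %% 25 == 0) {
      cv <- e$M2 / (e$n - 1) + diag(e$d) * 1e-8
      ch <- tryCatch(chol(cv), error = function(err) NULL)
      if (!is.null(ch)) e$chol <- ch
    }
  }
  am_propose <- function(e, x) {
    z <- stats::rnorm(e$d)
    step <- if (!is.null(e$chol)) drop(z %*% e$chol) else z
    x + exp(e$log_s) * step
  }

  blocks <- list(
    alpha = am_new(length(st$alpha),
                   cov0 = if (!is.null(inits$alpha)) inits$alpha$cov),
    beta = am_new(length(st$beta),
                  cov0 = if (!is.null(inits$beta)) inits$beta$cov),
    gamma = am_new(length(st$gamma) + 1,
                   cov0 = if (!is.null(inits$gamma)) inits$gamma$cov),
    hyp_f = am_new(2, 0.3),        # log sigma, log kappa
    theta = am_new(1, 0.3),
    nu_psi = am_new(2, 0.3)
  )
  if (sp_c) blocks$gp_c <- am_new(2, 0.3)
  if (sp_f) blocks$gp_f <- am_new(2, 0.3)
  if (!is.null(ld_c))
    blocks$ridge_c <- am_new(length(ld_c$cols), 0.3 / sqrt(length(ld_c$cols)))
  if (!is.null(ld_f))
    blocks$ridge_f <- am_new(length(ld_f$cols), 0.3 / sqrt(length(ld_f$cols)))
  blocks$alpha_cw <- am_new(1, 0.1)
  blocks$freq_ridge <- am_new(length(st$beta), 0.2 / sqrt(length(st$beta)))
  if (mdata$n_miss_ame > 0) blocks$ame_mis <- am_new(1, 0.5)
  for (lev in intersect(c("study", "house"),
                        sub("household", "house", mdata$random)))
    for (blk in c("c", "q"))
      blocks[[paste0("re_", lev, "_", blk)]] <- am_new(1, 0.5)

  mh <- function(e, cur_lp, prop_lp, adapting) {
    e$tries <- e$tries + 1
    ok <- is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp
    if (ok) e$acc <- e$acc + 1
    if (adapting)
      e$log_s <- .adapt(e$log_s, as.numeric(ok), e$tries,
                        if (e$d > 1) 0.234 else 0.44)
    ok
  }

  ## per-row quantity log-likelihood, for element-wise AME updates;
  ## includes the -log(AME) Jacobian on imputed rows (the observed datum is
  ## the quantity, not the ratio)
  quant_rows <- function(s) {
    qq <- mdata$quant
    ame <- .ame_merged(s, mdata)
    stats::dgamma(qq$q / ame,
                  shape = exp(drop(qq$X %*% s$gamma) + s$gamma_ame * ame +
                                .re_term(s, mdata, "q", qq$study,
                                         qq$house)) * s$theta,
                  rate = s$theta, log = TRUE) -
      log(ame) * (qq$imput_id > 0)
  }
  cons_rows <- function(s) {
    cc <- mdata$cons
    lp <- drop(cc$X %*% s$alpha) + cache$eps_c[cc$loc] +
      .re_term(s, mdata, "c", cc$study, cc$house)
    cc$events * stats::plogis(lp, log.p = TRUE) +
      (cc$trials - cc$events) * stats::plogis(-lp, log.p = TRUE)
  }

  kept <- iterations - warmup
  draws <- NULL
  acc_names <- names(blocks)

  for (it in seq_len(iterations)) {
    adapting <- it <= warmup
    for (sw in seq_len(sweeps)) {

    ## alpha ------------------------------------------------------------
    e <- blocks$alpha
    prop <- st; prop$alpha[] <- am_propose(e, st$alpha)
    lp_c <- ll_cons(st) + sum(stats::dnorm(st$alpha, 0, priors$coef_sd,
                                           log = TRUE))
    lp_p <- ll_cons(prop) + sum(stats::dnorm(prop$alpha, 0, priors$coef_sd,
                                             log = TRUE))
    if (mh(e, lp_c, lp_p, adapting)) st <- prop
    if (adapting) am_update_stats(e, st$alpha)

    ## component-wise refresh of alpha (directions whose conditional scale
    ## differs strongly from the joint proposal, e.g. household-level terms)
    e <- blocks$alpha_cw
    lp_cur <- ll_cons(st)
    for (j in seq_along(st$alpha)) {
      prop <- st
      prop$alpha[j] <- st$alpha[j] + stats::rnorm(1, 0, exp(e$log_s))
      lp_p <- ll_cons(prop) +
        stats::dnorm(prop$alpha[j], 0, priors$coef_sd, log = TRUE)
      if (mh(e, lp_cur + stats::dnorm(st$alpha[j], 0, priors$coef_sd,
                                      log = TRUE), lp_p, adapting)) {
        st <- prop
        lp_cur <- lp_p - stats::dnorm(st$alpha[j], 0, priors$coef_sd,
                                      log = TRUE)
      }
    }

    ## GP (consumption): eta via ESS, then (zeta, rho) ------------------
    if (sp_c) {
      ll_eta <- function(eta) {
        s2 <- st
        cache$eps_c <- drop(cache$LX_c %*% eta)
        loglik_consumption(s2, mdata, eps = cache$eps_c)
      }
      r <- .ess_step(st$eta_c, ll_eta, ll_eta(st$eta_c))
      st$eta_c <- r$f
      cache$eps_c <- drop(cache$LX_c %*% st$eta_c)

      e <- blocks$gp_c
      cur <- log(c(st$zeta_c, st$rho_c))
      prp <- am_propose(e, cur)
      prop <- st; prop$zeta_c <- exp(prp[1]); prop$rho_c <- exp(prp[2])
      LX_p <- tryCatch(gp_build(prop$zeta_c, prop$rho_c, mdata$D)$LX,
                       error = function(err) NULL)
      lp_c <- ll_cons(st) + .lhalfnorm(st$zeta_c, priors$zeta_sd) +
        .lhalfnorm(st$rho_c, priors$rho_sd) + sum(cur)
      if (!is.null(LX_p)) {
        eps_old <- cache$eps_c
        cache$eps_c <- drop(LX_p %*% st$eta_c)
        lp_p <- ll_cons(prop) + .lhalfnorm(prop$zeta_c, priors$zeta_sd) +
          .lhalfnorm(prop$rho_c, priors$rho_sd) + sum(prp)
        if (mh(e, lp_c, lp_p, adapting)) {
          st <- prop; cache$LX_c <- LX_p
        } else cache$eps_c <- eps_old
      } else mh(e, lp_c, -Inf, adapting)
      if (adapting) am_update_stats(e, log(c(st$zeta_c, st$rho_c)))

      if (!is.null(ld_c)) {        # ridge move: alpha[loc] vs eps
        e <- blocks$ridge_c
        dlt <- am_propose(e, rep(0, e$d))
        prop_alpha <- st$alpha
        prop_alpha[ld_c$cols] <- prop_alpha[ld_c$cols] + dlt
        eps_p <- cache$eps_c - drop(ld_c$M %*% dlt)
        eta_p <- forwardsolve(cache$LX_c, eps_p)
        lp_c <- sum(stats::dnorm(st$alpha, 0, priors$coef_sd, log = TRUE)) +
          sum(stats::dnorm(st$eta_c, log = TRUE))
        lp_p <- sum(stats::dnorm(prop_alpha, 0, priors$coef_sd,
                                 log = TRUE)) +
          sum(stats::dnorm(eta_p, log = TRUE))
        if (mh(e, lp_c, lp_p, adapting)) {
          st$alpha <- prop_alpha; st$eta_c <- eta_p; cache$eps_c <- eps_p
        }
      }
    }

    ## beta --------------------------------------------------------------
    e <- blocks$beta
    prop <- st; prop$beta[] <- am_propose(e, st$beta)
    lp_c <- ll_freq(st) + sum(stats::dnorm(st$beta, 0, priors$coef_sd,
                                           log = TRUE))
    lp_p <- ll_freq(prop) + sum(stats::dnorm(prop$beta, 0, priors$coef_sd,
                                             log = TRUE))
    if (mh(e, lp_c, lp_p, adapting)) st <- prop
    if (adapting) am_update_stats(e, st$beta)

    ## GP (frequency) ----------------------------------------------------
    if (sp_f) {
      ll_eta <- function(eta) {
        cache$eps_f <- drop(cache$LX_f %*% eta)
        .ll_freq_data(st, mdata, eps = cache$eps_f)
      }
      r <- .ess_step(st$eta_f, ll_eta, ll_eta(st$eta_f))
      st$eta_f <- r$f
      cache$eps_f <- drop(cache$LX_f %*% st$eta_f)

      e <- blocks$gp_f
      cur <- log(c(st$zeta_f, st$rho_f))
      prp <- am_propose(e, cur)
      prop <- st; prop$zeta_f <- exp(prp[1]); prop$rho_f <- exp(prp[2])
      LX_p <- tryCatch(gp_build(prop$zeta_f, prop$rho_f, mdata$D)$LX,
                       error = function(err) NULL)
      lp_c <- ll_freq(st) + .lhalfnorm(st$zeta_f, priors$zeta_sd) +
        .lhalfnorm(st$rho_f, priors$rho_sd) + sum(cur)
      if (!is.null(LX_p)) {
        eps_old <- cache$eps_f
        cache$eps_f <- drop(LX_p %*% st$eta_f)
        lp_p <- ll_freq(prop) + .lhalfnorm(prop$zeta_f, priors$zeta_sd) +
          .lhalfnorm(prop$rho_f, priors$rho_sd) + sum(prp)
        if (mh(e, lp_c, lp_p, adapting)) {
          st <- prop; cache$LX_f <- LX_p
        } else cache$eps_f <- eps_old
      } else mh(e, lp_c, -Inf, adapting)
      if (adapting) am_update_stats(e, log(c(st$zeta_f, st$rho_f)))

      if (!is.null(ld_f)) {        # ridge move: beta[loc] vs eps
        e <- blocks$ridge_f
        dlt <- am_propose(e, rep(0, e$d))
        prop_beta <- st$beta
        prop_beta[ld_f$cols] <- prop_beta[ld_f$cols] + dlt
        eps_p <- cache$eps_f - drop(ld_f$M %*% dlt)
        eta_p <- forwardsolve(cache$LX_f, eps_p)
        lp_c <- sum(stats::dnorm(st$beta, 0, priors$coef_sd, log = TRUE)) +
          sum(stats::dnorm(st$eta_f, log = TRUE))
        lp_p <- sum(stats::dnorm(prop_beta, 0, priors$coef_sd,
                                 log = TRUE)) +
          sum(stats::dnorm(eta_p, log = TRUE))
        if (mh(e, lp_c, lp_p, adapting)) {
          st$beta <- prop_beta; st$eta_f <- eta_p; cache$eps_f <- eps_p
        }
      }
    }

    ## tau via ESS --------------------------------------------------------
    if (length(st$tau)) {
      ll_tau <- function(tau) {
        s2 <- st; s2$tau <- tau
        .ll_freq_data(s2, mdata, eps = cache$eps_f)
      }
      ll_t <- ll_tau(st$tau)
      r <- .ess_step(st$tau, ll_tau, ll_t)
      st$tau <- r$f

      ## element-wise refresh of the logit-frequency field: the u_h are
      ## conditionally independent given everything else, so each is
      ## re-proposed from the Gaussian approximation of its conditional
      ## (Beta likelihood x normal prior) and accepted with the exact
      ## densities - this re-randomizes the whole field every sweep, which
      ## vector-wise elliptical slices cannot do when kappa is large
      ff <- mdata$freq
      if (nrow(ff$X)) {
        sig_h <- pmax(st$sigma * ff$sig_base, 1e-8)
        phibar <- drop(ff$X %*% st$beta) + cache$eps_f[ff$loc]
        u_c <- phibar + sig_h * st$tau
        v_h <- 1 / (st$kappa * ff$y * (1 - ff$y))
        prec <- 1 / v_h + 1 / sig_h^2
        m_u <- (stats::qlogis(ff$y) / v_h + phibar / sig_h^2) / prec
        s_u <- 1 / sqrt(prec)
        u_p <- stats::rnorm(length(u_c), m_u, s_u)
        lbeta_u <- function(u) {
          phi <- stats::plogis(u)
          stats::dbeta(ff$y, phi * st$kappa, (1 - phi) * st$kappa,
                       log = TRUE)
        }
        dlt <- lbeta_u(u_p) - lbeta_u(u_c) +
          stats::dnorm(u_p, phibar, sig_h, log = TRUE) -
          stats::dnorm(u_c, phibar, sig_h, log = TRUE) +
          stats::dnorm(u_c, m_u, s_u, log = TRUE) -
          stats::dnorm(u_p, m_u, s_u, log = TRUE)
        acc_u <- is.finite(dlt) & log(stats::runif(length(dlt))) < dlt
        u_c[acc_u] <- u_p[acc_u]
        st$tau <- (u_c - phibar) / sig_h
      }

      ## sigma-tau interweave: sigma e^d, tau e^-d leaves every Sigma_h
      ## tau_h product - hence the whole frequency likelihood - unchanged;
      ## accepted on the priors and the log|J| = -n d Jacobian
      dlt <- stats::rnorm(1, 0, 0.3)
      sig_p <- st$sigma * exp(dlt)
      tau_p <- st$tau * exp(-dlt)
      lp_c <- sum(stats::dnorm(st$tau, log = TRUE)) +
        .lhalfnorm(st$sigma, priors$sigma_sd) + log(st$sigma)
      lp_p <- sum(stats::dnorm(tau_p, log = TRUE)) +
        .lhalfnorm(sig_p, priors$sigma_sd) + log(sig_p) -
        length(st$tau) * dlt
      if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_c) {
        st$sigma <- sig_p; st$tau <- tau_p
      }

      ## kappa-tau interweave: changing the Beta sample size moves the
      ## conditional distribution of every non-centring variate, so kappa
      ## jumps are proposed jointly with an affine remap of tau matched to
      ## the Gaussian approximation of its conditional (mean pulled toward
      ## the precision-weighted residual, scale sqrt(v/(v + Sigma^2)) with
      ## v the Beta logit-scale variance ~ 1/(kappa y(1-y)))
      ff <- mdata$freq
      phibar <- drop(ff$X %*% st$beta) + cache$eps_f[ff$loc]
      sig_h <- pmax(st$sigma * ff$sig_base, 1e-8)
      resid <- stats::qlogis(ff$y) - phibar
      yv <- ff$y * (1 - ff$y)
      cond <- function(kap) {
        v <- 1 / (kap * yv)
        list(m = sig_h * resid / (sig_h^2 + v),
             s = sqrt(v / (v + sig_h^2)))
      }
      for (k_it in 1:6) {
        dlt <- stats::rnorm(1, 0, 1.0)
        kap_p <- st$kappa * exp(dlt)
        cc_c <- cond(st$kappa); cc_p <- cond(kap_p)
        tau_p <- cc_p$m + (st$tau - cc_c$m) * (cc_p$s / cc_c$s)
        prop <- st; prop$kappa <- kap_p; prop$tau <- tau_p
        lp_c <- .ll_freq_data(st, mdata, eps = cache$eps_f) +
          sum(stats::dnorm(st$tau, log = TRUE)) +
          .lkappa_prior(st$kappa, priors$kappa_sd) + log(st$kappa)
        lp_p <- .ll_freq_data(prop, mdata, eps = cache$eps_f) +
          sum(stats::dnorm(tau_p, log = TRUE)) +
          .lkappa_prior(kap_p, priors$kappa_sd) + log(kap_p) +
          sum(log(cc_p$s / cc_c$s))
        if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_c) {
          st$kappa <- kap_p; st$tau <- tau_p
        }
      }

      ## exact Gibbs draw of beta in the centred parameterization: holding
      ## the household logit-frequencies u = Xb + eps + Sigma*tau fixed,
      ## the full conditional of beta is Gaussian (the Beta observation
      ## density depends on u only), so beta is redrawn exactly and tau is
      ## mapped back; this removes the beta-tau funnel entirely
      e <- blocks$freq_ridge
      sig_h <- pmax(st$sigma * ff$sig_base, 1e-8)
      p_b <- ncol(ff$X)
      eps_h <- cache$eps_f[ff$loc]
      u_c <- drop(ff$X %*% st$beta) + eps_h + sig_h * st$tau
      A2 <- crossprod(ff$X / sig_h) + diag(1 / priors$coef_sd^2, p_b)
      cA <- tryCatch(chol(A2), error = function(err) NULL)
      if (!is.null(cA)) {
        rhs <- crossprod(ff$X, (u_c - eps_h) / sig_h^2)
        bhat <- backsolve(cA, forwardsolve(t(cA), rhs))
        beta_new <- drop(bhat + backsolve(cA, stats::rnorm(p_b)))
        st$beta[] <- beta_new
        st$tau <- (u_c - drop(ff$X %*% beta_new) - eps_h) / sig_h
        e$tries <- e$tries + 1; e$acc <- e$acc + 1
      }
    }

    ## (log sigma, log kappa) --------------------------------------------
    e <- blocks$hyp_f
    cur <- log(c(st$sigma, st$kappa))
    prp <- am_propose(e, cur)
    prop <- st; prop$sigma <- exp(prp[1]); prop$kappa <- exp(prp[2])
    pr <- function(s, lg) .lhalfnorm(s$sigma, priors$sigma_sd) +
      .lkappa_prior(s$kappa, priors$kappa_sd) + sum(lg)
    if (mh(e, ll_freq(st) + pr(st, cur), ll_freq(prop) + pr(prop, prp),
           adapting)) st <- prop
    if (adapting) am_update_stats(e, log(c(st$sigma, st$kappa)))

    ## gamma block (incl. gamma_ame) --------------------------------------
    e <- blocks$gamma
    cur <- c(st$gamma, st$gamma_ame)
    prp <- am_propose(e, cur)
    prop <- st
    prop$gamma[] <- prp[seq_along(st$gamma)]
    prop$gamma_ame <- unname(prp[length(prp)])
    pr <- function(v) sum(stats::dnorm(v, 0, priors$coef_sd, log = TRUE))
    if (mh(e, ll_quant(st) + pr(cur), ll_quant(prop) + pr(prp), adapting))
      st <- prop
    if (adapting) am_update_stats(e, c(st$gamma, st$gamma_ame))

    e <- blocks$theta
    cur <- log(st$theta)
    prp <- am_propose(e, cur)
    prop <- st; prop$theta <- exp(prp)
    prt <- function(s, lg) stats::dgamma(s$theta, priors$theta[1],
                                         priors$theta[2], log = TRUE) + lg
    if (mh(e, ll_quant(st) + prt(st, cur), ll_quant(prop) + prt(prop, prp),
           adapting)) st <- prop
    if (adapting) am_update_stats(e, log(st$theta))

    ## imputed AMEs: element-wise vectorized Metropolis -------------------
    if (mdata$n_miss_ame > 0) {
      e <- blocks$ame_mis
      z <- stats::rnorm(mdata$n_miss_ame, 0, exp(e$log_s))
      prop <- st; prop$ame_mis <- st$ame_mis + z
      rows_c <- quant_rows(st); rows_p <- quant_rows(prop)
      id <- mdata$quant$imput_id
      keep_r <- id > 0
      d_ll <- rowsum(rows_p[keep_r] - rows_c[keep_r], id[keep_r])
      d_ll <- d_ll[order(as.integer(rownames(d_ll))), 1]
      dlt <- d_ll + .ltruncnorm0(prop$ame_mis, st$nu, st$psi) -
        .ltruncnorm0(st$ame_mis, st$nu, st$psi)
      ok <- is.finite(dlt) & log(stats::runif(mdata$n_miss_ame)) < dlt
      st$ame_mis[ok] <- prop$ame_mis[ok]
      e$tries <- e$tries + 1
      e$acc <- e$acc + mean(ok)
      if (adapting) e$log_s <- .adapt(e$log_s, mean(ok), e$tries, 0.44)
    }

    ## nu, psi -------------------------------------------------------------
    if (mdata$n_miss_ame > 0 || length(mdata$ame_obs)) {
      e <- blocks$nu_psi
      cur <- c(st$nu, log(st$psi))
      prp <- am_propose(e, cur)
      prop <- st; prop$nu <- prp[1]; prop$psi <- exp(prp[2])
      tgt <- function(s, lpsi)
        sum(.ltruncnorm0(c(mdata$ame_obs, s$ame_mis), s$nu, s$psi)) +
        .ltruncnorm0(s$nu, priors$nu_centre, priors$nu_sd) +
        .lhalfnorm(s$psi, priors$psi_sd) + lpsi
      if (mh(e, tgt(st, cur[2]), tgt(prop, prp[2]), adapting)) st <- prop
      if (adapting) am_update_stats(e, c(st$nu, log(st$psi)))
    }

    ## random intercepts ---------------------------------------------------
    for (lev in intersect(c("study", "house"),
                          sub("household", "house", mdata$random))) {
      for (blk in c("c", "q")) {
        nm <- paste0("re_", lev, "_", blk)
        e <- blocks[[nm]]
        v <- st[[nm]]
        idx <- if (blk == "c") mdata$cons[[if (lev == "study") "study"
                                           else "house"]] else
          mdata$quant[[if (lev == "study") "study" else "house"]]
        if (is.null(idx)) next
        z <- stats::rnorm(length(v), 0, exp(e$log_s))
        prop <- st; prop[[nm]] <- v + z
        rows_c <- if (blk == "c") cons_rows(st) else quant_rows(st)
        rows_p <- if (blk == "c") cons_rows(prop) else quant_rows(prop)
        d_ll <- rep(0, length(v))
        agg <- rowsum(rows_p - rows_c, idx)
        d_ll[as.integer(rownames(agg))] <- agg[, 1]
        sd_re <- st[[paste0("sd_", lev, "_", blk)]]
        dlt <- d_ll + stats::dnorm(prop[[nm]], 0, sd_re, log = TRUE) -
          stats::dnorm(v, 0, sd_re, log = TRUE)
        ok <- is.finite(dlt) & log(stats::runif(length(v))) < dlt
        st[[nm]][ok] <- prop[[nm]][ok]
        e$tries <- e$tries + 1; e$acc <- e$acc + mean(ok)
        if (adapting) e$log_s <- .adapt(e$log_s, mean(ok), e$tries, 0.44)
        # conjugate-free scalar update of the sd on the log scale
        sdn <- paste0("sd_", lev, "_", blk)
        s_prop <- st[[sdn]] * exp(stats::rnorm(1, 0, 0.2))
        lp_c <- sum(stats::dnorm(st[[nm]], 0, st[[sdn]], log = TRUE)) +
          .lhalfnorm(st[[sdn]], priors$re_sd) + log(st[[sdn]])
        lp_p <- sum(stats::dnorm(st[[nm]], 0, s_prop, log = TRUE)) +
          .lhalfnorm(s_prop, priors$re_sd) + log(s_prop)
        if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_c)
          st[[sdn]] <- s_prop
      }
    }

    }                              # end of sweep loop

    if (it > warmup) {
      row <- .flatten_state(st, monitor_latent)
      if (is.null(draws))
        draws <- matrix(NA_real_, kept, length(row),
                        dimnames = list(NULL, names(row)))
      draws[it - warmup, ] <- row
    }
  }

  acc <- vapply(blocks, function(e) if (e$tries) e$acc / e$tries else NA_real_,
                0)
  lp <- log_posterior(st, mdata, priors, on_nonfinite = "value")
  list(draws = draws, acc = acc, lp = lp)
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("<wm_fit>", nrow(x$draws), "draws x", ncol(x$draws), "parameters (",
      x$config$chains, "chain(s) x", x$config$iterations, "iterations,",
      x$config$warmup, "warmup )\n")
  cat("max Rhat:", round(max(x$rhat, na.rm = TRUE), 3),
      "| clamped frequencies:", x$n_clamped, "\n")
  invisible(x)
}

#' Posterior summary table for a fitted model
#'
#' @param object a `wm_fit`.
#' @param probs interval probabilities, default the 95% interval.
#' @param ... unused.
#' @return data.frame with mean, sd, median, interval bounds and Rhat per
#'   monitored parameter.
#' @export
summary.wm_fit <- function(object, probs = c(0.025, 0.975), ...) {
  d <- object$draws
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    median = apply(d, 2, stats::median),
    lower = apply(d, 2, stats::quantile, probs[1]),
    upper = apply(d, 2, stats::quantile, probs[2]),
    rhat = object$rhat[colnames(d)],
    row.names = NULL
  )
}
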