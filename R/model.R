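#' Prior configuration for the reparameterized life-course regression
#'
#' Defaults follow common weakly informative practice for this model:
#' a uniform (symmetric Dirichlet, `alpha = 1`) prior over the weight
#' simplex, a Cauchy(0, 2.5) prior for the lifetime effect `delta` and
#' for any covariate coefficients, a lognormal(1, 1) prior (log-scale
#' location 1, log-scale SD 1) for the residual SD `sigma`, and a wide
#' Cauchy(0, 10) prior for the intercept when one is included.
#'
#' @param dirichlet_alpha Dirichlet concentration for `w`; `alpha > 1`
#'   biases toward accumulation, `alpha < 1` toward a critical period.
#' @param delta_cauchy_scale scale of the Cauchy prior on `delta`.
#' @param sigma_lognormal length-2 numeric `(location, scale)` of the
#'   lognormal prior on `sigma`, both on the log scale.
#' @param gamma_cauchy_scale scale of the Cauchy prior on covariate
#'   coefficients.
#' @param intercept_cauchy_scale scale of the Cauchy prior on the
#'   intercept.
#' @return An object of class `lc_priors`.
#' @export
prior_config <- function(dirichlet_alpha = 1, delta_cauchy_scale = 2.5,
                         sigma_lognormal = c(1, 1), gamma_cauchy_scale = 2.5,
                         intercept_cauchy_scale = 10) {
  stopifnot(dirichlet_alpha > 0, delta_cauchy_scale > 0,
            length(sigma_lognormal) == 2L, sigma_lognormal[2] > 0,
            gamma_cauchy_scale > 0, intercept_cauchy_scale > 0)
  structure(list(dirichlet_alpha = dirichlet_alpha,
                 delta_cauchy_scale = delta_cauchy_scale,
                 sigma_lognormal = as.numeric(sigma_lognormal),
                 gamma_cauchy_scale = gamma_cauchy_scale,
                 intercept_cauchy_scale = intercept_cauchy_scale),
            class = "lc_priors")
}

#' MCMC configuration
#'
#' Desk-scale defaults (4 chains of 1000 post-warmup draws) give stable
#' ROPE and ranking probabilities for routine use; study-scale settings
#' (e.g. 5 chains of 10000) are available by argument.
#'
#' @param chains number of independent chains (>= 2, for diagnostics).
#' @param draws_per_chain post-warmup draws per chain.
#' @param warmup burn-in iterations discarded per chain.
#' @param adapt sampler adaptation iterations.
#' @param seed integer RNG seed; chain seeds are derived from it.
#' @param rhat_threshold maximum tolerated split-Rhat; the fit errors
#'   rather than silently returning a non-converged posterior.
#' @return An object of class `lc_mcmc`.
#' @export
mcmc_config <- function(chains = 4L, draws_per_chain = 1000L, warmup = 500L,
                        adapt = 500L, seed = 1L, rhat_threshold = 1.01) {
  stopifnot(chains >= 2L, draws_per_chain >= 1L,
            chains * draws_per_chain >= 1000L,
            warmup >= 0L, adapt >= 0L, rhat_threshold > 1)
  structure(list(chains = as.integer(chains),
                 draws_per_chain = as.integer(draws_per_chain),
                 warmup = as.integer(warmup), adapt = as.integer(adapt),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "lc_mcmc")
}

#' Assemble a life-course dataset
#'
#' @param outcome numeric outcome vector of length `n`.
#' @param exposures numeric `n x T` matrix, one column per measurement
#'   occasion.
#' @param covariates optional numeric `n x K` matrix of controls; when
#'   present an intercept is always included in the model.
#' @param occasion_names optional character names for the occasions.
#' @return An object of class `lc_data`.
#' @export
lifecourse_data <- function(outcome, exposures, covariates = NULL,
                            occasion_names = NULL) {
  exposures <- as.matrix(exposures)
  outcome <- as.numeric(outcome)
  n <- length(outcome)
  periods <- ncol(exposures)
  if (periods < 2L) stop("need at least two measurement occasions", call. = FALSE)
  if (nrow(exposures) != n) stop("outcome and exposures disagree on n", call. = FALSE)
  if (n <= periods) stop("need more observations than occasions (n > T)", call. = FALSE)
  if (anyNA(outcome) || anyNA(exposures)) {
    stop("missing values are not supported; handle them upstream", call. = FALSE)
  }
  if (any(apply(exposures, 2L, stats::sd) == 0)) {
    stop("constant exposure column: its weight is unidentifiable", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n || anyNA(covariates)) {
      stop("covariates must be complete and match n", call. = FALSE)
    }
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1L) {
      stop("covariate matrix is rank deficient", call. = FALSE)
    }
  }
  if (is.null(occasion_names)) occasion_names <- paste0("x", seq_len(periods))
  structure(list(outcome = outcome, exposures = exposures,
                 covariates = covariates, occasion_names = occasion_names,
                 n = n, periods = periods), class = "lc_data")
}

## JAGS model code.  The Gaussian likelihood enters only through the
## sufficient statistics (y'y, X'y, X'X, ...), encoded with the Poisson
## zeros trick, so the per-iteration cost does not grow with n.  The
## Dirichlet prior on w is realized as normalized Gamma(alpha, 1)
## variates, giving JAGS scalar nodes it can slice-sample; the simplex
## constraint holds by construction, not by clipping.
jags_model_code <- function(has_z) {
  paste0("model {\n",
    "  for (j in 1:P) { g[j] ~ dgamma(alpha_w, 1) }\n",
    "  w <- g / sum(g)\n",
    "  delta ~ dt(0, prec_delta, 1)\n",
    "  sigma ~ dlnorm(mu_sigma, prec_sigma)\n",
    "  q1 <- yty - 2*delta*inprod(w, xty) + delta^2 * inprod(w, XtX %*% w)\n",
    if (has_z) paste0(
    "  for (k in 1:K) { b[k] ~ dt(0, prec_b[k], 1) }\n",
    "  q2 <- -2*inprod(b, zty) + 2*delta*inprod(b, ZtX %*% w) + inprod(b, ZtZ %*% b)\n",
    "  q <- q1 + q2\n")
    else
    "  q <- q1\n",
    "  lam <- C0 + n*log(sigma) + q / (2*sigma^2)\n",
    "  zero ~ dpois(lam)\n",
    "}\n")
}

split_rhat <- function(x) {
  # x: iterations x chains; split each chain in half (Gelman et al. style)
  n <- nrow(x)
  half <- n %/% 2L
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2L, stats::var)
  W <- mean(s2)
  B <- m * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Fit the Bayesian life-course regression
#'
#' Samples the posterior of the reparameterized model
#' `y_i = (alpha +) delta * sum_j x_ij w_j (+ c_i' gamma) + e_i`,
#' `e_i ~ N(0, sigma)`, with `w` on the `T`-part simplex under a
#' symmetric Dirichlet prior.  The simplex constraint is enforced by
#' parameterization (normalized Gamma variates), never by clipping.
#' Gibbs/slice sampling is run with `rjags`; the likelihood is collapsed
#' to its sufficient statistics so runtime is essentially independent of
#' `n`.  The fit fails with a diagnostics error if any parameter's
#' split-Rhat exceeds `mcmc$rhat_threshold`.
#'
#' @param data an [lifecourse_data()] object.
#' @param priors an [prior_config()].
#' @param mcmc an [mcmc_config()].
#' @param intercept include an intercept?  Forced `TRUE` when
#'   covariates are present; default `FALSE` (the simulation-style model
#'   with centred exposures).
#' @return An object of class `lc_posterior` with `weight_draws`
#'   (`S x T`, rows on the simplex), `delta_draws`, `sigma_draws`,
#'   optional `intercept_draws` / `gamma_draws`, and a `diagnostics`
#'   data frame of split-Rhat and effective sample sizes.
#' @export
fit_lifecourse <- function(data, priors = prior_config(), mcmc = mcmc_config(),
                           intercept = !is.null(data$covariates)) {
  stopifnot(inherits(data, "lc_data"))
  if (!is.null(data$covariates)) intercept <- TRUE
  y <- data$outcome
  X <- data$exposures
  P <- data$periods
  has_z <- intercept
  Z <- if (has_z) cbind(`(Intercept)` = 1, data$covariates) else NULL

  jd <- list(P = P, n = data$n, yty = sum(y * y),
             xty = as.vector(crossprod(X, y)), XtX = crossprod(X),
             alpha_w = priors$dirichlet_alpha,
             prec_delta = priors$delta_cauchy_scale^-2,
             mu_sigma = priors$sigma_lognormal[1],
             prec_sigma = priors$sigma_lognormal[2]^-2,
             zero = 0)
  # C0 keeps the Poisson rate positive; n*log(sigma) can reach about -4n
  # under the lognormal(1,1) prior's lower tail
  jd$C0 <- 10 * data$n + 1e4
  if (has_z) {
    K <- ncol(Z)
    jd$K <- K
    jd$zty <- as.vector(crossprod(Z, y))
    jd$ZtX <- crossprod(Z, X)
    jd$ZtZ <- crossprod(Z)
    jd$prec_b <- c(priors$intercept_cauchy_scale,
                   rep(priors$gamma_cauchy_scale, K - 1L))^-2
  }

  set.seed(mcmc$seed)
  inits <- lapply(seq_len(mcmc$chains), function(i) {
    # keep derived chain seeds positive 32-bit integers
    chain_seed <- as.integer((as.numeric(mcmc$seed) * 1009 + i) %%
                               (.Machine$integer.max - 1)) + 1L
    ini <- list(g = stats::rgamma(P, 1, 1), delta = stats::rnorm(1),
                sigma = exp(stats::rnorm(1, 0, 0.5)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = chain_seed)
    if (has_z) ini$b <- stats::rnorm(jd$K, 0, 0.5)
    ini
  })

  monitors <- c("w", "delta", "sigma", if (has_z) "b")
  jm <- rjags::jags.model(textConnection(jags_model_code(has_z)), data = jd,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = TRUE)
  if (mcmc$warmup > 0L) stats::update(jm, mcmc$warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = mcmc$draws_per_chain,
                            progress.bar = "none")

  pars <- colnames(sm[[1L]])
  per_chain <- lapply(sm, as.matrix)
  rhat <- vapply(pars, function(p) {
    split_rhat(sapply(per_chain, function(ch) ch[, p]))
  }, numeric(1))
  ess <- as.numeric(coda::effectiveSize(sm)[pars])
  diagnostics <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                            row.names = NULL)
  bad <- diagnostics$parameter[diagnostics$rhat > mcmc$rhat_threshold]
  if (length(bad) > 0L) {
    stop(structure(class = c("lc_convergence_error", "error", "condition"),
                   list(message = paste0("MCMC did not converge (split-Rhat > ",
                                         mcmc$rhat_threshold, ") for: ",
                                         paste(bad, collapse = ", ")),
                        call = sys.call(-1), diagnostics = diagnostics)))
  }

  m <- do.call(rbind, per_chain)
  W <- m[, paste0("w[", seq_len(P), "]"), drop = FALSE]
  colnames(W) <- data$occasion_names
  out <- list(weight_draws = W, delta_draws = as.numeric(m[, "delta"]),
              sigma_draws = as.numeric(m[, "sigma"]),
              intercept_draws = if (has_z) as.numeric(m[, "b[1]"]),
              gamma_draws = if (has_z && jd$K > 1L)
                m[, paste0("b[", 2:jd$K, "]"), drop = FALSE],
              diagnostics = diagnostics, priors = priors, mcmc = mcmc,
              n = data$n, periods = P)
  class(out) <- "lc_posterior"
  out
}

#' @export
print.lc_posterior <- function(x, ...) {
  cat(sprintf("Life-course posterior: %d draws, %d occasions, n = %d\n",
              length(x$delta_draws), x$periods, x$n))
  cat(sprintf("  posterior mean w: (%s)\n",
              paste(sprintf("%.3f", colMeans(x$weight_draws)), collapse = ", ")))
  di <- delta_interval(x)
  cat(sprintf("  lifetime effect delta: %s\n", format(di)))
  cat(sprintf("  max split-Rhat %.4f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Central credible interval for the lifetime effect
#'
#' Equal-tailed interval from the posterior draw quantiles of `delta`,
#' together with whether it excludes zero -- the gate applied before any
#' model comparison (a lifetime effect must be credible before asking
#' which life-course pattern carries it).
#'
#' @param draws an `lc_posterior`, or a numeric vector of delta draws.
#' @param level interval mass in `(0, 1)`; default 0.95.
#' @return An object of class `lc_interval`: `mean`, `lower`, `upper`,
#'   `level`, `excludes_zero`.
#' @export
delta_interval <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  d <- if (inherits(draws, "lc_posterior")) draws$delta_draws else as.numeric(draws)
  qs <- unname(stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(list(mean = mean(d), lower = qs[1], upper = qs[2], level = level,
                 excludes_zero = qs[1] > 0 || qs[2] < 0),
            class = "lc_interval")
}

#' @export
format.lc_interval <- function(x, digits = 2, ...) {
  sprintf("%.*f (%.*f, %.*f)", digits, x$mean, digits, x$lower, digits, x$upper)
}

#' @export
print.lc_interval <- function(x, ...) {
  cat(sprintf("%.0f%% credible interval: %s; %s zero\n", 100 * x$level,
              format(x), if (x$excludes_zero) "excludes" else "contains"))
  invisible(x)
}

#' Map sign-coherent coefficient draws back to the simplex
#'
#' Retains the draws of an unrestricted coefficient vector that lie in a
#' sign-coherent orthant (all components strictly positive or all
#' strictly negative) and renormalizes each by its component sum,
#' `theta_i -> theta_i / sum(theta)`.  A negative-orthant row divided by
#' its (negative) sum also lands on the simplex.  The result can be fed
#' to [rope_test()] and [finest_credible_rank()], extending the
#' life-course machinery to encompassing regression fits.
#'
#' @param coef_draws numeric `S x T` matrix of coefficient draws.
#' @param orthant `"any"` (default), `"positive"` or `"negative"`.
#' @return Matrix of simplex rows, one per retained draw.
#' @export
sign_then_simplex <- function(coef_draws, orthant = c("any", "positive", "negative")) {
  orthant <- match.arg(orthant)
  draws <- as_draw_matrix(coef_draws)
  pos <- rowSums(draws > 0) == ncol(draws)
  neg <- rowSums(draws < 0) == ncol(draws)
  keep <- switch(orthant, any = pos | neg, positive = pos, negative = neg)
  if (!any(keep)) {
    stop("no draws lie in the requested sign-coherent orthant", call. = FALSE)
  }
  kept <- draws[keep, , drop = FALSE]
  kept / rowSums(kept)
}
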