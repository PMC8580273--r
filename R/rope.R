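#' ROPE configuration for the three life-course models
#'
#' The range statistic `phi = max(w) - min(w)` of a simplex weight
#' vector is 0 under the accumulation model (all weights equal), 1 under
#' a critical-period model (one weight carries everything) and strictly
#' between under any sensitive pattern.  Two thresholds `0 < a < b < 1`
#' cut `[0, 1]` into three regions of practical equivalence:
#' accumulation `[0, a]`, sensitive `(a, b)` and critical `[b, 1]`.
#'
#' @param a lower threshold; default 0.15.
#' @param b upper threshold; default `1 - a`.
#' @param decision_threshold posterior probability above which a model is
#'   deemed credible in absolute terms; default 0.9.
#' @param bf_threshold Bayes-factor cut for relative credibility;
#'   default 3.2.
#' @return An object of class `lc_rope_config`.
#' @export
rope_config <- function(a = 0.15, b = 1 - a, decision_threshold = 0.9,
                        bf_threshold = 3.2) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            a > 0, b < 1, a < b,
            decision_threshold > 0, decision_threshold < 1, bf_threshold > 0)
  structure(list(a = a, b = b, decision_threshold = decision_threshold,
                 bf_threshold = bf_threshold), class = "lc_rope_config")
}

#' Range statistic of a weight vector
#'
#' `phi = max(w) - min(w)`.  On the simplex this lies in `[0, 1]`,
#' equals 0 exactly at the accumulation point `(1/T, ..., 1/T)` and 1
#' exactly at a vertex (critical period).
#'
#' @param w numeric vector of length `>= 2` with finite components.
#' @return Numeric scalar.
#' @export
range_statistic <- function(w) {
  if (!is.numeric(w) || length(w) < 2L || !all(is.finite(w))) {
    stop("'w' must be a numeric vector of length >= 2 with finite components",
         call. = FALSE)
  }
  max(w) - min(w)
}

## row-wise phi for a draw matrix
phi_of_draws <- function(draws) {
  idx <- seq_len(ncol(draws))
  block_max(draws, idx) - block_min(draws, idx)
}

#' Classify a range value into a life-course model
#'
#' Boundary values fall into the closed outer intervals: `phi <= a` is
#' accumulation, `phi >= b` is critical, anything between is sensitive.
#'
#' @param phi numeric vector of range values in `[0, 1]`.
#' @param cfg an [rope_config()].
#' @return Character vector over `"accumulation"`, `"sensitive"`,
#'   `"critical"`.
#' @export
classify_phi <- function(phi, cfg = rope_config()) {
  if (!is.numeric(phi) || any(!is.finite(phi)) || any(phi < 0 | phi > 1)) {
    stop("'phi' values must lie in [0, 1]; only simplex draws can be classified",
         call. = FALSE)
  }
  ifelse(phi <= cfg$a, "accumulation", ifelse(phi >= cfg$b, "critical", "sensitive"))
}

check_simplex <- function(draws, tol = 1e-8) {
  draws[draws < 0 & draws > -1e-12] <- 0
  if (any(draws < 0) || any(abs(rowSums(draws) - 1) > tol)) {
    stop("draw rows must lie on the unit simplex (non-negative, summing to 1)",
         call. = FALSE)
  }
  draws
}

#' Omnibus ROPE test of the accumulation, sensitive and critical models
#'
#' Computes the posterior probability of each composite life-course
#' model as the fraction of posterior weight draws whose range `phi`
#' falls in the model's ROPE interval.  The three probabilities are
#' exhaustive and sum to 1.  A model is the conclusive decision when its
#' probability exceeds `cfg$decision_threshold`; otherwise the test is
#' inconclusive.  When prior ROPE probabilities are supplied (e.g. from
#' [prior_rope_probabilities()]), per-model Bayes factors against the
#' complement are reported as well.
#'
#' @param weight_draws numeric `S x T` matrix of posterior weight draws;
#'   every row must lie on the simplex within numerical tolerance.
#' @param cfg an [rope_config()].
#' @param prior_probs optional named numeric vector of the three prior
#'   ROPE probabilities (`accumulation`, `sensitive`, `critical`).
#' @return An object of class `lc_rope`: posterior probabilities,
#'   decision, `phi` summary and optional Bayes factors.
#' @export
rope_test <- function(weight_draws, cfg = rope_config(), prior_probs = NULL) {
  draws <- as_draw_matrix(weight_draws)
  draws <- check_simplex(draws)
  phi <- phi_of_draws(draws)
  lab <- classify_phi(phi, cfg)
  models <- c("accumulation", "sensitive", "critical")
  p <- vapply(models, function(m) mean(lab == m), numeric(1))
  decision <- if (any(p > cfg$decision_threshold)) models[which.max(p)] else "inconclusive"
  bf <- NULL
  if (!is.null(prior_probs)) {
    bf <- lapply(models, function(m) bayes_factor(p[[m]], prior_probs[[m]],
                                                  cfg$bf_threshold))
    names(bf) <- models
  }
  structure(list(
    p_accumulation = p[["accumulation"]],
    p_sensitive = p[["sensitive"]],
    p_critical = p[["critical"]],
    decision = decision,
    bayes_factors = bf,
    phi_summary = c(mean = mean(phi),
                    stats::quantile(phi, c(0.025, 0.25, 0.5, 0.75, 0.975))),
    config = cfg), class = "lc_rope")
}

#' @export
print.lc_rope <- function(x, ...) {
  cat(sprintf("ROPE test of life-course models (a = %.2f, b = %.2f)\n",
              x$config$a, x$config$b))
  cat(sprintf("  p(accumulation | y) = %.4f\n", x$p_accumulation))
  cat(sprintf("  p(sensitive    | y) = %.4f\n", x$p_sensitive))
  cat(sprintf("  p(critical     | y) = %.4f\n", x$p_critical))
  cat(sprintf("  decision (threshold %.2f): %s\n", x$config$decision_threshold,
              x$decision))
  if (!is.null(x$bayes_factors)) {
    for (m in names(x$bayes_factors)) {
      b <- x$bayes_factors[[m]]
      cat(sprintf("  BF(%s) = %.3g (log BF = %.3g)%s\n", m, b$bf, b$log_bf,
                  if (isTRUE(b$decisive)) " [decisive]" else ""))
    }
  }
  invisible(x)
}

#' Prior probability of each ROPE under a symmetric Dirichlet
#'
#' Monte-Carlo estimate of the prior mass that `Dirichlet(alpha * 1_T)`
#' places on the accumulation, sensitive and critical ROPEs.  Used to
#' turn posterior ROPE probabilities into Bayes factors.  For `T = 2`
#' and `alpha = 1` the range `phi = |2 w1 - 1|` is uniform on `[0, 1]`,
#' so the probabilities are `(a, b - a, 1 - b)` exactly.
#'
#' @param periods number of occasions `T >= 2`.
#' @param cfg an [rope_config()].
#' @param alpha Dirichlet concentration (`alpha > 1` biases toward
#'   accumulation, `alpha < 1` toward critical).
#' @param prior_draw_count Monte-Carlo sample size; at least 1000.
#' @param seed optional RNG seed for reproducibility.
#' @return Named numeric vector of three probabilities summing to 1.
#' @export
prior_rope_probabilities <- function(periods, cfg = rope_config(), alpha = 1,
                                     prior_draw_count = 100000L, seed = NULL) {
  stopifnot(periods >= 2L, alpha > 0, prior_draw_count >= 1000L)
  if (!is.null(seed)) set.seed(seed)
  w <- rdirichlet(prior_draw_count, rep(alpha, periods))
  lab <- classify_phi(phi_of_draws(w), cfg)
  c(accumulation = mean(lab == "accumulation"),
    sensitive = mean(lab == "sensitive"),
    critical = mean(lab == "critical"))
}

## symmetric-capable Dirichlet sampler via normalized gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Bayes factor of a region against its complement
#'
#' `BF = [p(R | y) / p(R)] / [p(not R | y) / p(not R)]`, the change in
#' odds of the region relative to its prior odds.  Values above
#' `bf_threshold` are flagged decisive; whether practice thresholds the
#' Bayes factor or its logarithm varies, so both are reported.
#'
#' @param posterior_p posterior probability of the region.
#' @param prior_p prior probability, strictly inside `(0, 1)`.
#' @param bf_threshold decisiveness cut; default 3.2.
#' @return List with `bf`, `log_bf` and `decisive`.
#' @export
bayes_factor <- function(posterior_p, prior_p, bf_threshold = 3.2) {
  stopifnot(is.numeric(posterior_p), is.numeric(prior_p),
            posterior_p >= 0, posterior_p <= 1)
  if (prior_p <= 0 || prior_p >= 1) {
    stop("Bayes factor undefined for prior probability 0 or 1", call. = FALSE)
  }
  if (posterior_p == 1) {
    warning("posterior probability 1: Bayes factor is +Inf")
    bf <- Inf
  } else if (posterior_p == 0) {
    warning("posterior probability 0: Bayes factor is 0 (log BF -Inf)")
    bf <- 0
  } else {
    bf <- (posterior_p / prior_p) / ((1 - posterior_p) / (1 - prior_p))
  }
  list(bf = bf, log_bf = log(bf), decisive = is.finite(bf) && bf > bf_threshold ||
         is.infinite(bf))
}

#' Posterior probability of sign-coherent coefficient vectors
#'
#' For draws of an unrestricted regression coefficient vector, the
#' fraction of draws whose components are all strictly positive or all
#' strictly negative, i.e. the posterior mass of the union of the two
#' sign-coherent orthants.  A component exactly at zero places the draw
#' in neither orthant.  Sign coherence is the implicit assumption behind
#' the simplex reparameterization `theta = delta * w`; assessing it
#' under an encompassing model, and then renormalizing the coherent
#' draws with [sign_then_simplex()], extends the ROPE/FCR machinery to
#' ordinary regression fits.
#'
#' @param coef_draws numeric `S x T` matrix of coefficient draws.
#' @return List with `p_coherent`, `p_positive`, `p_negative`.
#' @export
sign_coherence_probability <- function(coef_draws) {
  draws <- as_draw_matrix(coef_draws)
  pos <- rowSums(draws > 0) == ncol(draws)
  neg <- rowSums(draws < 0) == ncol(draws)
  list(p_coherent = mean(pos | neg),
       p_positive = mean(pos),
       p_negative = mean(neg))
}
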