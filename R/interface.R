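#' Full life-course analysis of one dataset
#'
#' Runs the complete workflow: fit the reparameterized regression, apply
#' the delta gate (95% credible interval for the lifetime effect vs
#' zero), and -- if a lifetime effect is credible -- the omnibus ROPE
#' test of the accumulation, sensitive and critical models.  When the
#' sensitive model wins, the finest credible rank decomposes it into the
#' most informative credible partial ranking of occasions; when the
#' critical model wins, the per-occasion probabilities `p(w_j >= b | y)`
#' identify which period is critical.  With `sensitivity = TRUE` the
#' ROPE test is re-run at `(a, b) = (0.1, 0.9)` and `(0.2, 0.8)` to show
#' how the decision depends on the thresholds.
#'
#' @param data an [lifecourse_data()] object.
#' @param priors,mcmc,rope_cfg configuration objects.
#' @param beta FCR credibility level; default 0.9.
#' @param prior_probs optional prior ROPE probabilities for Bayes
#'   factors (see [prior_rope_probabilities()]).
#' @param sensitivity re-run the ROPE test at alternative thresholds?
#' @return An object of class `lc_analysis`.
#' @export
analyze_lifecourse <- function(data, priors = prior_config(),
                               mcmc = mcmc_config(), rope_cfg = rope_config(),
                               beta = 0.9, prior_probs = NULL,
                               sensitivity = FALSE) {
  fit <- fit_lifecourse(data, priors, mcmc)
  di <- delta_interval(fit, 0.95)
  out <- list(fit = fit, delta = di, rope = NULL, fcr = NULL,
              critical_occasion = NULL, sensitivity = NULL, beta = beta)
  if (di$excludes_zero) {
    out$rope <- rope_test(fit$weight_draws, rope_cfg, prior_probs)
    if (out$rope$decision == "sensitive") {
      out$fcr <- finest_credible_rank(fit$weight_draws, beta)
    } else if (out$rope$decision == "critical") {
      p_crit <- colMeans(fit$weight_draws >= rope_cfg$b)
      out$critical_occasion <- list(probabilities = p_crit,
                                    occasion = which.max(p_crit))
    }
    if (sensitivity) {
      out$sensitivity <- lapply(list(c(0.1, 0.9), c(0.2, 0.8)), function(ab) {
        alt <- rope_config(a = ab[1], b = ab[2],
                           decision_threshold = rope_cfg$decision_threshold,
                           bf_threshold = rope_cfg$bf_threshold)
        rope_test(fit$weight_draws, alt, prior_probs)
      })
    }
  }
  class(out) <- "lc_analysis"
  out
}

#' @export
print.lc_analysis <- function(x, ...) {
  cat("Life-course model comparison\n")
  cat("============================\n\n")
  cat(sprintf("Posterior mean weights: (%s)\n",
              paste(sprintf("%.3f", colMeans(x$fit$weight_draws)), collapse = ", ")))
  cat(sprintf("Lifetime effect delta: %s [%d%% CI]\n", format(x$delta),
              round(100 * x$delta$level)))
  if (!x$delta$excludes_zero) {
    cat("\nThe credible interval for delta contains zero: no credible\n")
    cat("lifetime effect, so no life-course model comparison is attempted.\n")
    return(invisible(x))
  }
  cat("\n")
  print(x$rope)
  if (!is.null(x$fcr)) {
    cat("\n")
    print(x$fcr)
  }
  if (!is.null(x$critical_occasion)) {
    cat(sprintf("\nMost probable critical occasion: %d (p = %.3f)\n",
                x$critical_occasion$occasion,
                max(x$critical_occasion$probabilities)))
  }
  if (!is.null(x$sensitivity)) {
    cat("\nSensitivity to ROPE thresholds:\n")
    for (alt in x$sensitivity) {
      cat(sprintf("  (a, b) = (%.2f, %.2f): decision %s\n",
                  alt$config$a, alt$config$b, alt$decision))
    }
  }
  invisible(x)
}

#' Read a life-course dataset from delimited text
#'
#' @param path CSV file with named columns.
#' @param outcome name of the outcome column.
#' @param exposures character vector of exposure column names, in
#'   occasion order.
#' @param covariates optional character vector of covariate columns.
#' @return An [lifecourse_data()] object.
#' @export
read_lifecourse_csv <- function(path, outcome = "y",
                                exposures = NULL, covariates = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(exposures)) {
    exposures <- grep("^x[0-9]+$", names(df), value = TRUE)
  }
  missing_cols <- setdiff(c(outcome, exposures, covariates), names(df))
  if (length(missing_cols) > 0L) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lifecourse_data(df[[outcome]], as.matrix(df[exposures]),
                  if (length(covariates)) as.matrix(df[covariates]),
                  occasion_names = exposures)
}

#' Read a posterior draw matrix from delimited text
#'
#' Expects a header `w1..wT` (or any column names, taken in order).
#'
#' @param path CSV file of draws, one row per posterior draw.
#' @return Numeric matrix.
#' @export
read_draws_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Serialize an FCR, ROPE result or analysis to JSON
#'
#' The FCR serializes as
#' `{chain: [{ranking, probability}], beta, fcr, conclusive}`; ROPE
#' results and whole analyses as flat named structures.  Files written
#' here re-read with [jsonlite::fromJSON()] to equal values.
#'
#' @param x an `lc_fcr`, `lc_rope`, `lc_interval` or `lc_analysis`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
lc_to_json <- function(x, path = NULL) {
  obj <- lc_serialize(x)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

lc_serialize <- function(x) {
  if (inherits(x, "lc_fcr")) {
    list(chain = lapply(seq_along(x$chain), function(i) {
           list(ranking = format(x$chain[[i]]), probability = x$probabilities[i])
         }),
         beta = x$beta, fcr = format(x$fcr), conclusive = x$conclusive)
  } else if (inherits(x, "lc_rope")) {
    list(p_accumulation = x$p_accumulation, p_sensitive = x$p_sensitive,
         p_critical = x$p_critical, decision = x$decision,
         a = x$config$a, b = x$config$b,
         decision_threshold = x$config$decision_threshold,
         phi_mean = unname(x$phi_summary[["mean"]]),
         bayes_factors = if (!is.null(x$bayes_factors))
           lapply(x$bayes_factors, function(b)
             list(bf = b$bf, log_bf = b$log_bf, decisive = b$decisive)))
  } else if (inherits(x, "lc_interval")) {
    list(mean = x$mean, lower = x$lower, upper = x$upper, level = x$level,
         excludes_zero = x$excludes_zero)
  } else if (inherits(x, "lc_analysis")) {
    list(delta = lc_serialize(x$delta),
         rope = if (!is.null(x$rope)) lc_serialize(x$rope),
         fcr = if (!is.null(x$fcr)) lc_serialize(x$fcr),
         critical_occasion = x$critical_occasion,
         sensitivity = if (!is.null(x$sensitivity))
           lapply(x$sensitivity, lc_serialize))
  } else {
    stop("don't know how to serialize objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

#' Parse an FCR result back from its JSON form
#'
#' @param path_or_string JSON file path or string produced by
#'   [lc_to_json()].
#' @return An `lc_fcr` object equal to the one serialized.
#' @export
fcr_from_json <- function(path_or_string) {
  obj <- jsonlite::fromJSON(path_or_string, simplifyVector = FALSE)
  chain <- lapply(obj$chain, function(el) as_ranking(el$ranking))
  structure(list(chain = chain,
                 probabilities = vapply(obj$chain, function(el)
                   as.numeric(el$probability), numeric(1)),
                 beta = obj$beta, fcr = as_ranking(obj$fcr),
                 conclusive = isTRUE(obj$conclusive)),
            class = "lc_fcr")
}

#' Write a simulated cohort and its ground truth to disk
#'
#' Emits `<stem>.csv` with columns `y, x1..xT` and a `<stem>.json`
#' sidecar recording the generating regime (family, `w*`, `delta*`,
#' true ranking, seed).
#'
#' @param sim result of [simulate_lifecourse()].
#' @param stem output path without extension.
#' @param seed the seed used, recorded in the sidecar.
#' @return Invisibly, the two paths written.
#' @export
write_simulated_cohort <- function(sim, stem, seed = NULL) {
  df <- data.frame(y = sim$data$outcome, sim$data$exposures)
  names(df) <- c("y", paste0("x", seq_len(sim$data$periods)))
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(list(family = tr$family, periods = tr$periods,
                            w_star = tr$w_star, delta_star = tr$delta_star,
                            true_ranking = format(tr$true_ranking),
                            r_star = tr$r_star, seed = seed),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Write study-result summary files
#'
#' Emits `confusion.csv` (the 4 x 4 confusion matrix) and `q_table.csv`
#' (mean ranking information by sample size), plus `cells.csv` with the
#' full per-cell records.
#'
#' @param study an `lc_study` from [run_study()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_study_result <- function(study, dir) {
  stopifnot(inherits(study, "lc_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("confusion.csv", "q_table.csv", "cells.csv"))
  utils::write.csv(as.data.frame(study$confusion), paths[1])
  utils::write.csv(study$q_by_n, paths[2], row.names = FALSE)
  utils::write.csv(study$cells, paths[3], row.names = FALSE)
  invisible(paths)
}
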