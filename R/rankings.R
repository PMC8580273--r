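#' Partial rankings of measurement occasions
#'
#' A partial ranking orders the `T` measurement occasions of a life-course
#' study into blocks of increasing importance.  Occasions in an earlier
#' block have strictly smaller weights than occasions in any later block;
#' occasions within a block are incomparable.  The string notation joins
#' blocks with `"|"` and occasions within a block with `","`, least
#' important first, so `"3|1|2"` says occasion 3 matters least and
#' occasion 2 most, while `"1,3|2"` only says occasion 2 matters most.
#'
#' The canonical string form sorts indices within each block ascending
#' (`"3,1|2"` and `"1,3|2"` denote the same ranking and both parse).
#' A ranking with `k` blocks makes `r = k - 1` distinctions; a full
#' ranking has `r = T - 1` and the vacuous ranking (one block) has
#' `r = 0` and asserts nothing.
#'
#' @param x a ranking string such as `"1,3|2"`, or a list of integer
#'   vectors (one per block, least important block first).
#' @param periods total number of occasions `T`.  Inferred from the
#'   indices present when omitted.
#' @return An object of class `lc_ranking` with fields `blocks` (list of
#'   sorted integer vectors) and `periods`.
#' @examples
#' as_ranking("3,1|2")          # canonicalizes to 1,3|2
#' as_ranking(list(3, 1, 2))    # the full ranking 3|1|2
#' @export
as_ranking <- function(x, periods = NULL) {
  if (inherits(x, "lc_ranking")) {
    return(x)
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    blocks <- lapply(strsplit(strsplit(x, "|", fixed = TRUE)[[1L]], ",", fixed = TRUE),
                     function(b) as.integer(trimws(b)))
  } else if (is.list(x)) {
    blocks <- lapply(x, function(b) as.integer(b))
  } else {
    stop("cannot interpret 'x' as a partial ranking", call. = FALSE)
  }
  new_ranking(blocks, periods)
}

new_ranking <- function(blocks, periods = NULL) {
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  idx <- unlist(blocks)
  if (length(idx) == 0L || anyNA(idx)) {
    stop("blocks must contain occasion indices", call. = FALSE)
  }
  if (is.null(periods)) periods <- max(idx)
  periods <- as.integer(periods)
  if (any(vapply(blocks, length, 1L) == 0L)) {
    stop("blocks must be non-empty", call. = FALSE)
  }
  if (length(idx) != periods || !setequal(idx, seq_len(periods)) ||
      anyDuplicated(idx) > 0L) {
    stop("blocks must partition 1..", periods, call. = FALSE)
  }
  structure(list(blocks = blocks, periods = periods), class = "lc_ranking")
}

#' @export
format.lc_ranking <- function(x, ...) {
  paste(vapply(x$blocks, paste, "", collapse = ","), collapse = "|")
}

#' @export
print.lc_ranking <- function(x, ...) {
  r <- n_distinctions(x)
  cat(format(x), if (r == 0L) " (vacuous ranking)" else sprintf(" (%d distinction%s)",
      r, if (r == 1L) "" else "s"), "\n", sep = "")
  invisible(x)
}

#' @export
`==.lc_ranking` <- function(e1, e2) {
  format(as_ranking(e1)) == format(as_ranking(e2))
}

#' Number of distinctions made by a partial ranking
#'
#' The number of inequalities (bars `"|"`) a ranking asserts: one less
#' than its number of blocks.
#'
#' @param p an `lc_ranking` or ranking string.
#' @return Integer `r >= 0`.
#' @export
n_distinctions <- function(p) {
  length(as_ranking(p)$blocks) - 1L
}

#' The vacuous ranking on T occasions
#'
#' @param periods number of occasions.
#' @return The single-block `lc_ranking` that makes no distinctions.
#' @export
vacuous_ranking <- function(periods) {
  new_ranking(list(seq_len(periods)), periods)
}

#' Label a weight vector with its (tie-merged) full ranking
#'
#' Orders the occasions by ascending component value, least important
#' first, so `c(0.2, 0.7, 0.1)` is labelled `"3|1|2"`.  Occasions with
#' exactly equal components are merged into one block, so the label of a
#' vector with ties is a partial ranking; this makes the label well
#' defined for ground-truth vectors padded with zeros, e.g.
#' `c(0, 0, 1)` is labelled `"1,2|3"`.
#'
#' @param w numeric vector of length `T >= 2` with finite components.
#' @return An `lc_ranking`.
#' @export
full_rank_label <- function(w) {
  if (!is.numeric(w) || length(w) < 2L || !all(is.finite(w))) {
    stop("'w' must be a numeric vector of length >= 2 with finite components",
         call. = FALSE)
  }
  vals <- sort(unique(w))
  new_ranking(lapply(vals, function(v) which(w == v)), length(w))
}

#' Does a weight vector satisfy a partial ranking?
#'
#' `TRUE` iff for every pair of adjacent blocks the largest component in
#' the earlier block is strictly below the smallest component in the
#' later block.  Exact cross-block ties do not satisfy the ranking.
#'
#' @param w numeric vector of length `p$periods`.
#' @param p an `lc_ranking` or ranking string.
#' @return Logical scalar.
#' @export
satisfies <- function(w, p) {
  p <- as_ranking(p)
  if (length(w) != p$periods) {
    stop("length(w) must equal the ranking's number of occasions", call. = FALSE)
  }
  nb <- length(p$blocks)
  if (nb == 1L) return(TRUE)
  for (k in seq_len(nb - 1L)) {
    if (max(w[p$blocks[[k]]]) >= min(w[p$blocks[[k + 1L]]])) return(FALSE)
  }
  TRUE
}

## column-wise max/min over a block of a draw matrix, vectorized over rows
block_max <- function(draws, idx) {
  if (length(idx) == 1L) draws[, idx] else do.call(pmax, lapply(idx, function(j) draws[, j]))
}
block_min <- function(draws, idx) {
  if (length(idx) == 1L) draws[, idx] else do.call(pmin, lapply(idx, function(j) draws[, j]))
}

## logical vector: which rows of `draws` satisfy ranking p
satisfying_rows <- function(draws, p) {
  nb <- length(p$blocks)
  ok <- rep(TRUE, nrow(draws))
  if (nb == 1L) return(ok)
  for (k in seq_len(nb - 1L)) {
    ok <- ok & (block_max(draws, p$blocks[[k]]) < block_min(draws, p$blocks[[k + 1L]]))
  }
  ok
}

as_draw_matrix <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L || ncol(draws) < 2L) {
    stop("'draws' must be a non-empty matrix with at least two columns",
         call. = FALSE)
  }
  draws
}

#' Posterior probability of a partial ranking
#'
#' Estimates `p(ranking | y)` by the fraction of posterior draws whose
#' components satisfy all of the ranking's inequalities.  The rows may be
#' simplex weight draws or draws of an unrestricted coefficient vector;
#' only the component order matters.  The vacuous ranking has
#' probability exactly 1.
#'
#' @param draws numeric `S x T` matrix, one row per posterior draw.
#' @param p an `lc_ranking` or ranking string on `T` occasions.
#' @return A probability in `[0, 1]`.
#' @export
ranking_probability <- function(draws, p) {
  draws <- as_draw_matrix(draws)
  p <- as_ranking(p)
  if (ncol(draws) != p$periods) {
    stop("draw columns must match the ranking's number of occasions", call. = FALSE)
  }
  if (length(p$blocks) == 1L) return(1)
  mean(satisfying_rows(draws, p))
}

#' One-step coarsenings of a partial ranking
#'
#' All rankings obtained from `p` by merging exactly one pair of adjacent
#' blocks (exchanging one `"|"` for a `","`).  A ranking with `k` blocks
#' has `k - 1` coarsenings; the vacuous ranking has none.
#'
#' @param p an `lc_ranking` or ranking string.
#' @return List of `lc_ranking` objects, ordered by merge position.
#' @export
coarsenings <- function(p) {
  p <- as_ranking(p)
  nb <- length(p$blocks)
  if (nb < 2L) return(list())
  lapply(seq_len(nb - 1L), function(k) {
    merged <- c(p$blocks[seq_len(k - 1L)],
                list(c(p$blocks[[k]], p$blocks[[k + 1L]])),
                if (k + 1L < nb) p$blocks[seq(k + 2L, nb)] else NULL)
    new_ranking(merged, p$periods)
  })
}

## most frequent full (tie-merged) label among the draws; frequency ties are
## broken by canonical-string order for reproducibility
map_full_label <- function(draws) {
  labs <- apply(draws, 1L, function(r) {
    if (anyDuplicated(r)) format(full_rank_label(r)) else paste(order(r), collapse = "|")
  })
  tab <- table(labs)
  best <- sort(names(tab)[tab == max(tab)], method = "radix")[1L]
  as_ranking(best, ncol(draws))
}

#' Finest credible rank of a posterior sample
#'
#' Greedy decomposition of the sensitive model into its most informative
#' credible partial ranking.  The algorithm starts at the maximum a
#' posteriori full ranking among the draws, then repeatedly coarsens to
#' the most probable ranking at the next (lower) level of resolution,
#' producing a nested chain that ends in the vacuous ranking with
#' probability 1.  The finest credible rank (FCR) is the first chain
#' element whose posterior probability reaches `beta`.  The result is
#' conclusive unless the FCR is vacuous.
#'
#' Because coarsening enlarges the underlying region of parameter space,
#' the chain probabilities are non-decreasing.  When two coarsenings tie
#' in estimated probability, the merge whose combined block contains the
#' smallest occasion index is taken, making the chain deterministic.
#'
#' @param draws numeric `S x T` matrix of posterior draws of the weight
#'   (or unrestricted coefficient) vector.
#' @param beta credibility level in `(0, 1)`; default 0.90.
#' @return An object of class `lc_fcr`: list with `chain` (list of
#'   `lc_ranking` from finest to vacuous), `probabilities`, `beta`,
#'   `fcr` and `conclusive`.
#' @examples
#' draws <- matrix(rep(c(0.1, 0.2, 0.7), each = 100), ncol = 3)
#' finest_credible_rank(draws)$fcr  # 1|2|3 with probability 1
#' @export
finest_credible_rank <- function(draws, beta = 0.9) {
  draws <- as_draw_matrix(draws)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    stop("'beta' must be a probability strictly between 0 and 1", call. = FALSE)
  }
  cur <- map_full_label(draws)
  chain <- list(cur)
  probs <- ranking_probability(draws, cur)
  while (length(cur$blocks) > 1L) {
    cands <- coarsenings(cur)
    pc <- vapply(cands, function(cc) ranking_probability(draws, cc), numeric(1))
    best <- which(pc == max(pc))
    if (length(best) > 1L) {
      lead <- vapply(best, function(k) min(cur$blocks[[k]], cur$blocks[[k + 1L]]), numeric(1))
      best <- best[which.min(lead)]
    }
    cur <- cands[[best]]
    chain <- c(chain, list(cur))
    probs <- c(probs, pc[best])
  }
  sel <- which(probs >= beta)[1L]
  structure(list(chain = chain, probabilities = probs, beta = beta,
                 fcr = chain[[sel]],
                 conclusive = length(chain[[sel]]$blocks) > 1L),
            class = "lc_fcr")
}

#' @export
print.lc_fcr <- function(x, ...) {
  cat(sprintf("Finest credible rank at beta = %.2f\n\n", x$beta))
  cat(sprintf("%-24s %s\n", "Ranking", "Probability"))
  for (i in seq_along(x$chain)) {
    marker <- if (identical(format(x$chain[[i]]), format(x$fcr))) "  <- FCR" else ""
    cat(sprintf("%-24s %.3f%s\n", format(x$chain[[i]]), x$probabilities[i], marker))
  }
  cat(if (x$conclusive) "\nConclusive: the FCR makes at least one distinction.\n"
      else "\nInconclusive: only the vacuous ranking is credible.\n")
  invisible(x)
}

#' Fraction of true distinctions preserved by an inferred ranking
#'
#' The information metric `q = r / r*`, where `r` counts the
#' distinctions in the inferred ranking and `r*` those in the true
#' ranking.  `q = 1` means the inference is as informative as the truth;
#' `q = 0` means the vacuous ranking.  Undefined when the truth makes no
#' distinctions (`r* = 0`, the accumulation ground truth).
#'
#' @param fcr inferred `lc_ranking` (or string).
#' @param truth true `lc_ranking` (or string) with `r* >= 1`.
#' @return Ratio `r / r*`.
#' @export
q_metric <- function(fcr, truth) {
  r_star <- n_distinctions(truth)
  if (r_star == 0L) {
    stop("q is undefined when the true ranking makes no distinctions", call. = FALSE)
  }
  n_distinctions(fcr) / r_star
}

#' Is an inferred ranking consistent with a ground-truth weight vector?
#'
#' The ranking is inconsistent if it asserts `w[i] < w[j]` for any pair
#' where the truth has `w[j] < w[i]`, or where the truth holds them
#' exactly equal (claiming an order between truly tied occasions is
#' counted as a violation).  The vacuous ranking is always consistent.
#'
#' @param fcr an `lc_ranking` or ranking string.
#' @param truth_w numeric ground-truth weight vector.
#' @return Logical scalar.
#' @export
is_consistent <- function(fcr, truth_w) {
  p <- as_ranking(fcr)
  if (length(truth_w) != p$periods) {
    stop("length(truth_w) must equal the ranking's number of occasions",
         call. = FALSE)
  }
  nb <- length(p$blocks)
  if (nb == 1L) return(TRUE)
  for (k in seq_len(nb - 1L)) {
    earlier <- unlist(p$blocks[seq_len(k)])
    later <- p$blocks[[k + 1L]]
    if (max(truth_w[earlier]) >= min(truth_w[later])) return(FALSE)
  }
  TRUE
}
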