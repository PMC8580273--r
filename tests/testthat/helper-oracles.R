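# Independent oracles and generators used across the suite.

# all permutations of 1..k (k! rows); small k only
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

# Brute-force probability of a partial ranking: enumerate all full
# rankings (permutations listing occasions from least to most important),
# keep those that refine the partial ranking, and sum their empirical
# frequencies among the draws.  Independent of satisfies()/block logic:
# ranking membership is decided purely on positions within the
# permutation, and draw frequencies purely on order().
brute_force_ranking_probability <- function(draws, blocks) {
  k <- ncol(draws)
  perms <- all_permutations(k)
  pos_of <- function(perm) {
    p <- integer(k); p[perm] <- seq_len(k); p
  }
  consistent <- apply(perms, 1L, function(perm) {
    pos <- pos_of(perm)
    nb <- length(blocks)
    if (nb == 1L) return(TRUE)
    for (a in seq_len(nb - 1L)) {
      for (b in seq.int(a + 1L, nb)) {
        if (max(pos[blocks[[a]]]) > min(pos[blocks[[b]]])) return(FALSE)
      }
    }
    TRUE
  })
  draw_perm <- apply(draws, 1L, function(r) paste(order(r), collapse = " "))
  perm_key <- apply(perms, 1L, paste, collapse = " ")
  counts <- table(factor(draw_perm, levels = perm_key))
  sum(counts[consistent]) / nrow(draws)
}

# random blocks forming a partial ranking of 1..k
random_blocks <- function(k) {
  nb <- sample.int(k, 1L)
  cut_points <- sort(sample(seq_len(k - 1L), nb - 1L))
  perm <- sample.int(k)
  bounds <- c(0L, cut_points, k)
  lapply(seq_len(nb), function(i) perm[seq.int(bounds[i] + 1L, bounds[i + 1L])])
}

# simplex draws from a symmetric Dirichlet
random_simplex_draws <- function(s, k, alpha = 1) {
  g <- matrix(rgamma(s * k, alpha), s, k)
  g / rowSums(g)
}
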