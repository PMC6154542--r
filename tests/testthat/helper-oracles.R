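# Independent brute-force reference implementations; deliberately naive
# (loops, enumeration) and kept separate from the package's vectorized /
# closed-form code paths.

# PIC by an explicit pairwise double loop over the Botstein formula.
brute_pic <- function(p) {
  out <- 1 - sum(p^2)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) out <- out - 2 * p[i]^2 * p[j]^2
  }
  out
}

# Expected subsample richness by full enumeration of all size-n subsets.
brute_expected_richness <- function(scores, n) {
  combos <- utils::combn(nrow(scores), n)
  mean(apply(combos, 2, function(idx)
    sum(colSums(scores[idx, , drop = FALSE]) > 0)))
}

# UPGMA cophenetic distances by recursive agglomeration in which the
# distance between two clusters is recomputed from scratch as the mean of
# all original leaf-to-leaf distances (the defining property of average
# linkage), rather than by the package's running-update formula.
brute_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# One-level AMOVA components computed from the raw 0/1 data via centroid
# deviations (Gower's identity route), independent of the package's
# pairwise-distance route.
brute_amova_phi <- function(scores, grouping) {
  scores <- as.matrix(scores)
  N <- nrow(scores)
  groups <- split(seq_len(N), grouping)
  G <- length(groups)
  centroid <- colMeans(scores)
  ss_total <- sum(sweep(scores, 2, centroid)^2)
  ss_within <- sum(vapply(groups, function(idx) {
    cg <- colMeans(scores[idx, , drop = FALSE])
    sum(sweep(scores[idx, , drop = FALSE], 2, cg)^2)
  }, 0))
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (G - 1)
  ms_within <- ss_within / (N - G)
  n0 <- (N - sum(lengths(groups)^2) / N) / (G - 1)
  s2a <- (ms_among - ms_within) / n0
  max(s2a, 0) / (max(s2a, 0) + ms_within)
}

# Plain Rand index of two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Closed-form posterior mean log-likelihood of the K = 1 admixture model:
# theta_j | x ~ Beta(1 + c_j, 1 + n - c_j) and
# E[log theta] = digamma(a) - digamma(a + b).
closed_form_k1_loglik <- function(scores) {
  n <- nrow(scores)
  cj <- colSums(scores)
  a <- 1 + cj
  b <- 1 + n - cj
  sum(cj * (digamma(a) - digamma(a + b)) +
        (n - cj) * (digamma(b) - digamma(a + b)))
}
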