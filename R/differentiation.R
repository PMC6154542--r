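#' Pairwise squared-Euclidean band distances
#'
#' For 0/1 band profiles the squared Euclidean distance between two
#' individuals is simply the number of mismatched bands; this is the
#' standard AMOVA distance for dominant data.
#'
#' @param m A [band_matrix] with at least two individuals.
#' @return Symmetric integer matrix with zero diagonal; entry (i, j) is the
#'   Hamming mismatch count between the band profiles of i and j.
#' @export
pairwise_band_distance <- function(m) {
  if (n_individuals(m) < 2)
    stop("need at least two individuals", call. = FALSE)
  x <- m$scores
  r <- rowSums(x)
  d <- outer(r, r, `+`) - 2 * tcrossprod(x)
  diag(d) <- 0
  storage.mode(d) <- "integer"
  dimnames(d) <- list(m$individual_ids, m$individual_ids)
  d
}

# Excoffier-style one-level decomposition from a matrix of squared
# distances. SS identities: SS_total = sum_{i<j} d2_ij / N,
# SS_within = sum_g sum_{i<j in g} d2_ij / n_g (equal to the sums of
# squared deviations from group centroids, by Gower's identity).
amova_components <- function(d2, grouping) {
  N <- nrow(d2)
  groups <- split(seq_len(N), grouping)
  ng <- lengths(groups)
  G <- length(groups)
  ss_total <- sum(d2) / (2 * N)
  ss_within <- sum(vapply(groups, function(idx)
    sum(d2[idx, idx]) / (2 * length(idx)), 0))
  ss_among <- ss_total - ss_within
  df_among <- G - 1
  df_within <- N - G
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n0 <- (N - sum(ng^2) / N) / (G - 1)
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n0
  # negative among-group components are reported as-is but clamped to zero
  # inside the Phi ratio, the usual convention
  a <- max(sigma2_among, 0)
  phi <- if (a + sigma2_within > 0) a / (a + sigma2_within) else 0
  list(ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       sigma2_among = sigma2_among, sigma2_within = sigma2_within,
       phi_st = phi)
}

#' One-level AMOVA for dominant band data
#'
#' Partitions the total variance of pairwise squared-Euclidean band
#' distances into among-population and within-population components and
#' reports the fixation index `Phi_ST = sigma2_among / (sigma2_among +
#' sigma2_within)` (the quantity usually printed as FST for dominant
#' markers).  The decomposition is the standard mean-square system: the
#' within component is the within-group mean square and the among component
#' is `(MS_among - MS_within) / n0` with `n0` the usual unequal-sample-size
#' coefficient.
#'
#' @param m A [band_matrix].
#' @param grouping Optional factor/character grouping (defaults to the
#'   matrix's population labels); every group needs at least two
#'   individuals.
#' @return Object of class `amova_result` with sums of squares, degrees of
#'   freedom, variance components, `phi_st`, and (after
#'   [phi_st_permutation()]) a permutation p-value.
#' @export
amova <- function(m, grouping = NULL) {
  grouping <- grouping %||% m$population
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == n_individuals(m))
  ng <- table(grouping)
  if (length(ng) < 2)
    stop("AMOVA needs at least two populations", call. = FALSE)
  if (any(ng < 2))
    stop("population(s) of size 1 (zero within-group df): ",
         paste(names(ng)[ng < 2], collapse = ", "), call. = FALSE)
  d2 <- pairwise_band_distance(m)
  comp <- amova_components(d2, grouping)
  structure(c(comp, list(p_value = NA_real_, n_permutations = 0L,
                         grouping = grouping)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- data.frame(
    source = c("among populations", "within populations"),
    df = c(x$df_among, x$df_within),
    SS = c(x$ss_among, x$ss_within),
    sigma2 = c(x$sigma2_among, x$sigma2_within))
  tot <- max(x$sigma2_among, 0) + x$sigma2_within
  tab$pct_total <- 100 * c(max(x$sigma2_among, 0), x$sigma2_within) / tot
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Phi_ST = %.4f", x$phi_st))
  if (x$n_permutations > 0)
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value,
                x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Permutation test for Phi_ST
#'
#' Significance of the among-population component by permuting individuals
#' among populations (group sizes preserved) and recomputing Phi_ST; the
#' add-one estimator `p = (1 + #{perm >= observed}) / (1 + n_permutations)`
#' avoids a p-value of zero.
#'
#' @inheritParams amova
#' @param n_permutations At least 99 (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return An `amova_result` with `p_value` and `n_permutations` filled in.
#' @export
phi_st_permutation <- function(m, grouping = NULL, n_permutations = 999,
                               seed) {
  stopifnot(n_permutations >= 99)
  res <- amova(m, grouping)
  d2 <- pairwise_band_distance(m)
  grouping <- res$grouping
  N <- length(grouping)
  perm_phi <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    amova_components(d2, grouping[sample.int(N)])$phi_st
  }, 0))
  res$p_value <- (1 + sum(perm_phi >= res$phi_st)) / (1 + n_permutations)
  res$n_permutations <- as.integer(n_permutations)
  res
}

#' Fixation-index sweep over sampling sizes
#'
#' For each ladder size `n`, subsamples `n` individuals per population
#' (without replacement, `replicates` times) and computes Phi_ST on the
#' subsampled matrix.  Two contrasts are available: `"focal"` reports, per
#' population, the Phi_ST between that population's subsample and the
#' pooled subsamples of all other populations (one column per accession);
#' `"global"` reports a single among-all-populations Phi_ST per size.
#' Size-1 rows are reported as 0 by convention: with one individual per
#' group there are no within-group degrees of freedom.
#'
#' @param m A [band_matrix] whose every population has at least
#'   `max(ladder)` individuals.
#' @param ladder A [sampling_ladder()].
#' @param replicates Subsample draws per size (default 25).
#' @param seed Integer seed.
#' @param mode `"focal"` or `"global"` (see above).
#' @return `data.frame` with column `size` and one mean-Phi_ST column per
#'   population (`"focal"`) or a single `phi_st` column (`"global"`).
#' @export
fst_sweep <- function(m, ladder = sampling_ladder(), replicates = 25, seed,
                      mode = c("focal", "global")) {
  mode <- match.arg(mode)
  pops <- populations(m)
  by_pop <- split(m$individual_ids, m$population)[pops]
  if (any(lengths(by_pop) < max(ladder)))
    stop("every population needs at least max(ladder) individuals",
         call. = FALSE)
  with_seed(seed, {
    rows <- lapply(as.integer(ladder), function(size) {
      vals <- vapply(seq_len(replicates), function(r) {
        ids <- unlist(lapply(by_pop, function(x) sample(x, size)),
                      use.names = FALSE)
        if (size == 1) {
          if (mode == "global") return(0) else return(rep(0, length(pops)))
        }
        sub <- subset(m, individuals = ids)
        if (mode == "global") {
          amova(sub)$phi_st
        } else {
          vapply(pops, function(p)
            amova(sub, ifelse(sub$population == p, p, "rest"))$phi_st, 0)
        }
      }, if (mode == "global") numeric(1) else numeric(length(pops)))
      if (mode == "global")
        data.frame(size = size, phi_st = mean(vals))
      else {
        vals <- matrix(vals, nrow = length(pops))
        out <- data.frame(size = size)
        out[pops] <- rowMeans(vals)
        out
      }
    })
    do.call(rbind, rows)
  })
}
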