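#' Default sampling ladder
#'
#' The increasing subsample sizes at which retention and diversity are
#' tracked.  The default ladder (1, 2, 3, 5, 8, 10, 20, 30, 40, 50, 60)
#' densely covers the small-sample region where band retention changes
#' fastest and then widens once the curve is expected to plateau.
#'
#' @param sizes Strictly increasing positive integers.
#' @return Validated integer vector of class `sampling_ladder`.
#' @export
sampling_ladder <- function(sizes = c(1, 2, 3, 5, 8, 10, 20, 30, 40, 50, 60)) {
  sizes <- as.integer(sizes)
  if (any(sizes <= 0) || any(diff(sizes) <= 0))
    stop("ladder sizes must be strictly increasing positive integers",
         call. = FALSE)
  structure(sizes, class = "sampling_ladder")
}

#' Reserve percentage (RP)
#'
#' The proportion of the full sample's bands retained in a subsample,
#' `RP = 100 * sub_na / full_na`, rounded to the nearest whole percent with
#' ties away from zero.  RP is the criterion this package optimizes: a
#' sampling size is "enough" once RP exceeds a chosen threshold (90% in the
#' headline analysis).
#'
#' @param sub_na Band count of the subsample (`0 <= sub_na <= full_na`).
#' @param full_na Band count of the full population sample (`> 0`).
#' @return Integer percent in `[0, 100]`.
#' @export
#' @examples
#' reserve_percentage(67, 116)  # 58
#' reserve_percentage(95, 105)  # 90
reserve_percentage <- function(sub_na, full_na) {
  stopifnot(full_na > 0, sub_na >= 0, sub_na <= full_na)
  as.integer(round_half_up(100 * sub_na / full_na))
}

#' Exact expected band richness under subsampling
#'
#' The rarefaction oracle: for a subsample of `n` of the `N` individuals of
#' a population drawn uniformly without replacement, the expected number of
#' distinct bands is
#' `E[Na(n)] = sum_b (1 - choose(N - c_b, n) / choose(N, n))`
#' where `c_b` is the presence count of band `b`.  This is the
#' hypergeometric probability that at least one carrier of each band enters
#' the subsample, so no Monte-Carlo is needed for the expectation.
#'
#' @param m A [band_matrix].
#' @param population Population label to restrict to, or `NULL` for the
#'   whole matrix.
#' @param n Subsample size, `0 < n <= N`.
#' @return Expected band count; strictly increasing in `n` until all bands
#'   are recoverable, and equal to the full Na at `n = N`.
#' @export
expected_richness <- function(m, population = NULL, n) {
  if (!is.null(population)) {
    if (!population %in% m$population)
      stop("unknown population '", population, "'", call. = FALSE)
    m <- subset(m, individuals = m$individual_ids[m$population == population])
  }
  N <- n_individuals(m)
  stopifnot(n > 0, n <= N)
  counts <- band_presence_counts(m)
  counts <- counts[counts > 0]
  # exp(lchoose) keeps the ratio stable; lchoose(N-c, n) = -Inf when n > N-c
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Construct a rarefaction result
#'
#' Container for per-size subsampling summaries; normally produced by
#' [subsample_curve()], but it can also be built from an externally
#' tabulated retention curve (e.g. a published table) so that
#' [plateau_size()] works on either.
#'
#' @param per_size `data.frame` with at least columns `size` and `rp_mean`;
#'   [subsample_curve()] adds `na_mean`, `na_sd`, `rp_sd`, `he_mean`,
#'   `he_sd`, `pic_mean`, `pic_sd` and `expected_na`.
#' @param reference_na Band count of the full population sample.
#' @param replicates Subsamples drawn per size.
#' @param population Population label the curve belongs to.
#' @return Object of class `rarefaction_result`.
#' @export
rarefaction_result <- function(per_size, reference_na,
                               replicates = NA_integer_,
                               population = NA_character_) {
  stopifnot(is.data.frame(per_size),
            all(c("size", "rp_mean") %in% names(per_size)))
  structure(list(per_size = per_size,
                 reference_na = reference_na,
                 replicates = replicates,
                 population = population),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat("rarefaction_result for population", x$population, "(full Na =",
      x$reference_na, ",", x$replicates, "replicates/size)\n")
  print(x$per_size, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Random-subsampling retention curve
#'
#' The core sampling-size experiment: at each ladder size, draw
#' `replicates` subsamples uniformly without replacement from the
#' population's individuals and track the observed band number (Na), the
#' reserve percentage relative to the full population sample, He and PIC.
#' The exact expectation from [expected_richness()] is attached per size
#' for comparison with the Monte-Carlo means.  Sampling is without
#' replacement, which is what makes the curve reach the full-sample Na
#' exactly at `n = N`.  With `replicates = 1` the function mimics a
#' single-draw experiment.
#'
#' @param m A [band_matrix].
#' @param population Population label to rarefy.
#' @param ladder A [sampling_ladder()]; its maximum must not exceed the
#'   population size.
#' @param replicates Subsamples per size (default 200).
#' @param seed Integer seed; the result is bit-identical given the same
#'   seed and inputs.
#' @return A [rarefaction_result()].
#' @export
subsample_curve <- function(m, population, ladder = sampling_ladder(),
                            replicates = 200, seed) {
  if (!population %in% m$population)
    stop("unknown population '", population, "'", call. = FALSE)
  stopifnot(replicates >= 1)
  ids <- m$individual_ids[m$population == population]
  pop <- subset(m, individuals = ids)
  N <- n_individuals(pop)
  if (max(ladder) > N)
    stop("ladder size ", max(ladder), " exceeds population size ", N,
         call. = FALSE)
  full_counts <- band_presence_counts(pop)
  ref_na <- sum(full_counts > 0)
  scores <- pop$scores
  per_size <- with_seed(seed, {
    rows <- lapply(as.integer(ladder), function(size) {
      stats <- vapply(seq_len(replicates), function(r) {
        idx <- sample.int(N, size)
        counts <- if (size == 1) scores[idx, ] else colSums(scores[idx, , drop = FALSE])
        na <- sum(counts > 0)
        if (na == 0) return(c(0, 0, NA_real_, NA_real_))
        p <- counts[counts > 0] / sum(counts)
        s2 <- sum(p^2)
        c(na, reserve_percentage(na, ref_na), 1 - s2,
          1 - s2 - (s2^2 - sum(p^4)))
      }, numeric(4))
      data.frame(size = size,
                 na_mean = mean(stats[1, ]), na_sd = stats::sd(stats[1, ]),
                 rp_mean = mean(stats[2, ]), rp_sd = stats::sd(stats[2, ]),
                 he_mean = mean(stats[3, ]), he_sd = stats::sd(stats[3, ]),
                 pic_mean = mean(stats[4, ]), pic_sd = stats::sd(stats[4, ]),
                 expected_na = expected_richness(pop, n = size))
    })
    do.call(rbind, rows)
  })
  rarefaction_result(per_size, reference_na = ref_na,
                     replicates = as.integer(replicates),
                     population = population)
}

#' Smallest sampling size reaching a retention threshold
#'
#' @param r A [rarefaction_result()].
#' @param threshold Reserve-percentage threshold in `(0, 100]`.
#' @return The smallest ladder size whose mean RP is at least `threshold`.
#' @export
#' @examples
#' ## a published-style retention table: 90% retention first reached at 10
#' r <- rarefaction_result(
#'   data.frame(size = c(1, 5, 10, 60), rp_mean = c(56, 80, 90, 100)),
#'   reference_na = 105)
#' plateau_size(r, 90)
plateau_size <- function(r, threshold) {
  stopifnot(threshold > 0, threshold <= 100)
  ok <- which(r$per_size$rp_mean >= threshold)
  if (!length(ok))
    stop("no ladder size reaches mean RP >= ", threshold, call. = FALSE)
  r$per_size$size[ok[1]]
}
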