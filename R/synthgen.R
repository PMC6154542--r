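#' Default per-primer band counts for the synthetic generator
#'
#' Five single-primer markers contributing 25, 21, 29, 23 and 24 bands for
#' a universe of 122 bands, the typical yield of a five-primer dominant
#' marker screen on a legume panel.
#'
#' @return Named integer vector of band counts per primer.
#' @export
default_band_counts <- function() {
  c(Scot28 = 25L, Scot35 = 21L, Scot36 = 29L, Scot37 = 23L, Scot38 = 24L)
}

#' Specification of one synthetic population
#'
#' Describes how band presence probabilities are drawn for one population.
#' The band universe (shared across populations) is a mixture of "common"
#' bands, with ancestral presence probability drawn from `common_range`,
#' and "rare" bands drawn from `rare_range`; a fraction `rare_fraction` of
#' shared bands is rare.  Differentiation among populations has two
#' sources: `private_band_count` bands carried by this population only, and
#' `divergence`, a fixation-index-like parameter `F` under which each
#' population's frequency for a common shared band is drawn from a
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` distribution around the ancestral
#' frequency `p` (the standard Balding-Nichols construction).  Rare shared
#' bands keep their ancestral frequency in every population so that
#' per-population band counts stay comparable.
#'
#' @param name Population label.
#' @param n_individuals Individuals to simulate (default 60).
#' @param private_band_count Bands unique to this population (default 6).
#' @param common_range,rare_range Uniform ranges for ancestral common and
#'   rare band probabilities (defaults `(0.35, 0.65)` and `(0.02, 0.15)`).
#' @param rare_fraction Fraction of shared bands that are rare
#'   (default 0.15).
#' @param divergence Balding-Nichols `F` for common shared bands
#'   (default 0.45).
#' @param freq_bounds Closed interval to which per-population common-band
#'   frequencies are clipped after the divergence draw (default
#'   `c(0.18, 0.95)`), so a shared common band stays observable (and
#'   polymorphic) in every population.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(name, n_individuals = 60,
                            private_band_count = 6,
                            common_range = c(0.35, 0.65),
                            rare_range = c(0.02, 0.15),
                            rare_fraction = 0.15,
                            divergence = 0.45,
                            freq_bounds = c(0.18, 0.95)) {
  stopifnot(n_individuals >= 1, private_band_count >= 0,
            rare_fraction >= 0, rare_fraction <= 1,
            divergence >= 0, divergence < 1,
            all(common_range > 0), all(common_range < 1),
            all(rare_range > 0), all(rare_range < 1),
            length(freq_bounds) == 2, freq_bounds[1] < freq_bounds[2])
  structure(list(name = name, n_individuals = as.integer(n_individuals),
                 private_band_count = as.integer(private_band_count),
                 common_range = common_range, rare_range = rare_range,
                 rare_fraction = rare_fraction, divergence = divergence,
                 freq_bounds = freq_bounds),
            class = "population_spec")
}

#' Default four-population study design
#'
#' Two cultivated-variety-like and two wild-accession-like populations of
#' 60 individuals each, the design the whole pipeline is exercised on.
#'
#' @inheritParams population_spec
#' @return List of four [population_spec()] objects.
#' @export
default_population_specs <- function(rare_fraction = 0.15,
                                     divergence = 0.45,
                                     private_band_count = 6,
                                     freq_bounds = c(0.18, 0.95)) {
  lapply(c("LJ. 1", "LJ. 3", "IL. 17", "BE. 33"), population_spec,
         n_individuals = 60, private_band_count = private_band_count,
         rare_fraction = rare_fraction, divergence = divergence,
         freq_bounds = freq_bounds)
}

#' Generate a synthetic band matrix with recorded ground truth
#'
#' Draws a band universe (bands assigned to primers according to
#' `band_counts`), allocates each population's private bands, draws
#' ancestral and per-population presence probabilities as described in
#' [population_spec()], and then scores each individual's bands as
#' independent Bernoulli trials.  Bands are independent (no linkage): every
#' statistic in this package is single-band or frequency-based, so linkage
#' would add nothing testable.
#'
#' @param specs List of [population_spec()] objects; their mixture
#'   parameters (`common_range`, `rare_range`, `rare_fraction`) must agree
#'   because the shared ancestral pool is drawn once.
#' @param seed Integer seed.
#' @param band_counts Named integer vector of bands per primer
#'   (default [default_band_counts()]).
#' @return List with elements `matrix` (a [band_matrix]) and `truth`, a
#'   record holding `prob` (populations x bands matrix of true presence
#'   probabilities), `realized_na` (observed band count per population),
#'   `k_true` (number of populations), and `private_bands` (band ids
#'   private to each population).
#' @export
generate_band_matrix <- function(specs = default_population_specs(), seed,
                                 band_counts = default_band_counts()) {
  stopifnot(length(specs) >= 1)
  mix <- specs[[1]][c("common_range", "rare_range", "rare_fraction")]
  for (s in specs)
    if (!isTRUE(all.equal(mix, s[c("common_range", "rare_range",
                                   "rare_fraction")])))
      stop("all specs must share the same band-frequency mixture",
           call. = FALSE)
  npop <- length(specs)
  nb <- sum(band_counts)
  primer <- rep(names(band_counts), band_counts)
  band_ids <- unlist(lapply(names(band_counts), function(p)
    sprintf("%s_b%02d", p, seq_len(band_counts[[p]]))), use.names = FALSE)
  n_priv <- vapply(specs, function(s) s$private_band_count, 1L)
  if (sum(n_priv) >= nb)
    stop("private bands exhaust the band universe", call. = FALSE)

  with_seed(seed, {
    priv_idx <- split(sample.int(nb, sum(n_priv)),
                      rep(seq_len(npop), n_priv))
    shared <- setdiff(seq_len(nb), unlist(priv_idx))
    rare <- stats::runif(length(shared)) < mix$rare_fraction
    anc <- ifelse(rare,
                  stats::runif(length(shared), mix$rare_range[1],
                               mix$rare_range[2]),
                  stats::runif(length(shared), mix$common_range[1],
                               mix$common_range[2]))
    prob <- matrix(0, npop, nb,
                   dimnames = list(vapply(specs, `[[`, "", "name"),
                                   band_ids))
    for (p in seq_len(npop)) {
      f <- specs[[p]]$divergence
      pp <- anc
      if (f > 0 && any(!rare)) {
        a <- anc[!rare] * (1 - f) / f
        b <- (1 - anc[!rare]) * (1 - f) / f
        # bounded away from 0/1 so a common band stays observable (and
        # polymorphic) in every population, as in real multi-accession
        # band data where shared bands are lost only when truly rare
        fb <- specs[[p]]$freq_bounds
        pp[!rare] <- pmin(pmax(stats::rbeta(sum(!rare), a, b), fb[1]), fb[2])
      }
      prob[p, shared] <- pp
      mine <- priv_idx[[as.character(p)]] %||% integer(0)
      if (length(mine))
        prob[p, mine] <- stats::runif(length(mine),
                                      specs[[p]]$common_range[1],
                                      specs[[p]]$common_range[2])
    }
    n_ind <- vapply(specs, function(s) s$n_individuals, 1L)
    scores <- matrix(0L, sum(n_ind), nb)
    pop_labels <- rep(rownames(prob), n_ind)
    row <- 0L
    for (p in seq_len(npop)) {
      block <- matrix(stats::rbinom(n_ind[p] * nb, 1, rep(prob[p, ],
                                                          each = n_ind[p])),
                      n_ind[p], nb)
      scores[row + seq_len(n_ind[p]), ] <- block
      row <- row + n_ind[p]
    }
    ids <- sprintf("ind%03d", seq_len(sum(n_ind)))
    m <- band_matrix(scores, individual_ids = ids,
                     population_labels = pop_labels,
                     band_ids = band_ids, band_primer = primer)
    realized_na <- vapply(rownames(prob), function(lab)
      sum(colSums(m$scores[m$population == lab, , drop = FALSE]) > 0), 1L)
    list(matrix = m,
         truth = list(prob = prob, realized_na = realized_na,
                      k_true = npop,
                      private_bands = lapply(priv_idx, function(i)
                        band_ids[i])))
  })
}

#' Calibrate a population spec to a retention saturation target
#'
#' Checks that a single population generated from `spec` saturates its band
#' retention where intended: the exact expected reserve percentage at the
#' target sampling size (from [expected_richness()], no Monte-Carlo) must
#' fall inside `band`.  If retention is too low the rare-band fraction is
#' lowered in fixed steps (a deterministic search) until the target band is
#' met; if retention already exceeds the band the spec is returned
#' unchanged with a warning, since an all-common population saturates
#' trivially.
#'
#' @param spec A [population_spec()].
#' @param target List with `size` (sampling size, default 10) and `rp`
#'   (nominal retention percent, default 90).
#' @param band Acceptable window for the expected RP at `target$size`
#'   (default `c(88, 97)`).
#' @param seed Integer seed for the evaluation draws.
#' @param step Decrement applied to `rare_fraction` per search step.
#' @return The (possibly adjusted) spec, with attribute `rp_at_target`
#'   giving the achieved expected RP.
#' @export
calibrate_to_saturation <- function(spec, target = list(size = 10, rp = 90),
                                    band = c(88, 97), seed = 1,
                                    step = 0.05) {
  eval_rp <- function(s) {
    g <- generate_band_matrix(list(s), seed = seed)
    pop <- s$name
    full <- sum(band_presence_counts(g$matrix) > 0)
    100 * expected_richness(g$matrix, pop, n = target$size) / full
  }
  rp <- eval_rp(spec)
  if (rp > band[2]) {
    warning("expected RP at size ", target$size, " is ",
            round_half_up(rp, 1), "% (above ", band[2],
            "%): population saturates trivially; spec unchanged")
    attr(spec, "rp_at_target") <- rp
    return(spec)
  }
  while (rp < band[1] && spec$rare_fraction > 0) {
    spec$rare_fraction <- max(spec$rare_fraction - step, 0)
    rp <- eval_rp(spec)
  }
  if (rp < band[1])
    stop("cannot reach expected RP >= ", band[1], "% at size ",
         target$size, " even with no rare bands", call. = FALSE)
  attr(spec, "rp_at_target") <- rp
  spec
}
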