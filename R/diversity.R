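#' Pooled band-as-allele frequencies
#'
#' Dominant markers yield anonymous bands rather than genotyped loci, so
#' the package pools every observed band as one allele of a single phantom
#' multi-allelic locus.  The frequency of band *j* is its occurrence
#' proportion, `p_j = count_j / sum(counts)`; bands never observed in the
#' (subset of the) matrix are excluded.  Under this definition a single
#' individual showing `Na` bands has uniform frequencies `1/Na`, so its
#' expected heterozygosity is `1 - 1/Na`.
#'
#' @param m A [band_matrix].
#' @param bands Band ids to restrict to, or `"all"`.
#' @return An object of class `allele_freqs` with elements `band_ids`
#'   (bands with positive count) and `p` (frequencies summing to 1).
#' @export
allele_frequencies <- function(m, bands = "all") {
  if (!identical(bands, "all")) m <- subset(m, bands = bands)
  counts <- band_presence_counts(m)
  freqs_from_counts(counts)
}

# counts -> allele_freqs; shared with the rarefaction engine, which works
# on raw presence counts for speed.
freqs_from_counts <- function(counts) {
  keep <- counts > 0
  if (!any(keep)) stop("no alleles observed (all-zero matrix)", call. = FALSE)
  p <- counts[keep] / sum(counts[keep])
  structure(list(band_ids = names(counts)[keep], p = unname(p)),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("allele_freqs:", length(x$p), "pooled alleles, sum(p) =",
      format(sum(x$p)), "\n")
  invisible(x)
}

#' Expected heterozygosity (He)
#'
#' `He = 1 - sum(p^2)` over the pooled band-as-allele frequencies.  No
#' small-sample correction is applied: the `n/(n-1)`-type correction is
#' undefined at a sampling size of one, the anchor case for this package.
#'
#' @param f An [allele_frequencies()] object (or a [band_matrix], which is
#'   converted first).
#' @return He in `[0, 1)`; equals `1 - 1/Na` for uniform frequencies.
#' @export
expected_heterozygosity <- function(f) {
  if (inherits(f, "band_matrix")) f <- allele_frequencies(f)
  1 - sum(f$p^2)
}

#' Polymorphism information content (PIC)
#'
#' Botstein's multi-allelic form,
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`,
#' evaluated through the algebraic identity
#' `sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4`.
#'
#' @inheritParams expected_heterozygosity
#' @return PIC, with `0 <= PIC <= He` and equality only for a single allele.
#' @export
pic <- function(f) {
  if (inherits(f, "band_matrix")) f <- allele_frequencies(f)
  s2 <- sum(f$p^2)
  s4 <- sum(f$p^4)
  1 - s2 - (s2^2 - s4)
}

#' Percentage of polymorphic bands (PPB)
#'
#' A band is polymorphic when it is neither absent from nor fixed in the
#' evaluated individuals (`0 < count < n`); the denominator is the number
#' of bands observed (`count > 0`) in the same subset.
#'
#' @param m A [band_matrix] with at least two individuals.
#' @return Percentage in `[0, 100]`.
#' @export
ppb <- function(m) {
  n <- n_individuals(m)
  if (n < 2) stop("PPB needs at least two individuals", call. = FALSE)
  counts <- band_presence_counts(m)
  observed <- counts > 0
  if (!any(observed)) stop("no alleles observed (all-zero matrix)",
                           call. = FALSE)
  100 * sum(counts > 0 & counts < n) / sum(observed)
}

#' Shannon information index (I)
#'
#' Mean per-band binary entropy,
#' `I_j = -(q_j log q_j + (1-q_j) log(1-q_j))` with
#' `q_j = count_j / n_individuals`, averaged over all bands of the matrix
#' (the band universe of the full study); fixed or absent bands contribute
#' zero.  The maximum, `log(2) ~ 0.693`, is reached when every band sits at
#' frequency one half.
#'
#' @param m A [band_matrix].
#' @return I in `[0, log(2)]`.
#' @export
shannon_index <- function(m) {
  q <- band_presence_counts(m) / n_individuals(m)
  h <- ifelse(q <= 0 | q >= 1, 0, -(q * log(q) + (1 - q) * log(1 - q)))
  mean(h)
}

#' Primer resolving power (Rp)
#'
#' `Rp = sum(I_b)` over the primer's bands with band informativeness
#' `I_b = 1 - 2 * |0.5 - q_b|`, where `q_b` is the proportion of
#' individuals carrying band `b`.  Rp measures a primer's ability to
#' distinguish genotypes; it is maximal (one per band) when every band is
#' carried by exactly half the individuals.
#'
#' @param m A [band_matrix].
#' @param primer Primer name; must own at least one band in `m`.
#' @return Rp in `[0, number of bands of the primer]`.
#' @export
resolving_power <- function(m, primer) {
  sel <- m$primer == primer
  if (!any(sel)) stop("primer '", primer, "' has no bands", call. = FALSE)
  q <- colSums(m$scores[, sel, drop = FALSE]) / n_individuals(m)
  sum(1 - 2 * abs(0.5 - q))
}

#' Diversity summary of a band matrix
#'
#' Computes the full set of dominant-marker diversity statistics for a
#' matrix (or any subset of it): observed band number Na, PPB, pooled
#' band-as-allele He and PIC, and the Shannon index.
#'
#' @param m A [band_matrix].
#' @return One-row `data.frame` with columns `n`, `na`, `ppb`, `he`, `pic`,
#'   `shannon`.
#' @export
diversity_summary <- function(m) {
  counts <- band_presence_counts(m)
  f <- freqs_from_counts(counts)
  n <- n_individuals(m)
  data.frame(
    n = n,
    na = sum(counts > 0),
    ppb = if (n >= 2) ppb(m) else NA_real_,
    he = expected_heterozygosity(f),
    pic = pic(f),
    shannon = shannon_index(m))
}

#' Per-primer diversity table
#'
#' One row per primer: number of bands, PPB, He, PIC and Rp restricted to
#' the primer's bands (pooling bands of that primer only).
#'
#' @param m A [band_matrix].
#' @return `data.frame` with columns `primer`, `n_bands`, `na`, `ppb`,
#'   `he`, `pic`, `rp`.
#' @export
primer_summary <- function(m) {
  prims <- unique(m$primer)
  rows <- lapply(prims, function(p) {
    sub <- subset(m, bands = m$band_ids[m$primer == p])
    counts <- band_presence_counts(sub)
    f <- freqs_from_counts(counts)
    data.frame(primer = p,
               n_bands = n_bands(sub),
               na = sum(counts > 0),
               ppb = if (n_individuals(sub) >= 2) ppb(sub) else NA_real_,
               he = expected_heterozygosity(f),
               pic = pic(f),
               rp = resolving_power(m, p))
  })
  do.call(rbind, rows)
}

#' Per-accession, per-primer diversity table
#'
#' Rp, He and PIC of each primer within each population, the layout used to
#' compare primer informativeness across accessions.
#'
#' @param m A [band_matrix].
#' @return `data.frame` with columns `population`, `primer`, `rp`, `he`,
#'   `pic`.
#' @export
accession_primer_table <- function(m) {
  out <- lapply(populations(m), function(pop) {
    sub <- subset(m, individuals = m$individual_ids[m$population == pop])
    tab <- primer_summary(sub)
    data.frame(population = pop, primer = tab$primer, rp = tab$rp,
               he = tab$he, pic = tab$pic)
  })
  do.call(rbind, out)
}
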