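test_that("allele frequencies are occurrence-proportional", {
  # band A in both individuals, band B in one -> p = (2/3, 1/3)
  m <- make_bm(rbind(c(1, 1), c(1, 0)))
  expect_equal(allele_frequencies(m)$p, c(2 / 3, 1 / 3))

  # single individual: uniform over its present bands
  one <- make_bm(rbind(c(1, 0, 1, 1)))
  f <- allele_frequencies(one)
  expect_equal(f$p, rep(1 / 3, 3))
  expect_identical(f$band_ids, c("b01", "b03", "b04"))

  expect_error(allele_frequencies(make_bm(matrix(0, 2, 3))), "no alleles")

  # brute-force count-ratio loop on a random fixture
  set.seed(21)
  m <- make_bm(matrix(rbinom(1500, 1, 0.3), 30, 50))
  f <- allele_frequencies(m)
  counts <- integer(50)
  for (j in 1:50) counts[j] <- sum(m$scores[, j])
  expect_equal(f$p, (counts / sum(counts))[counts > 0])
  expect_equal(sum(f$p), 1, tolerance = 1e-12)
})

test_that("He matches its closed forms", {
  uniform <- function(k) structure(list(band_ids = as.character(1:k),
                                        p = rep(1 / k, k)),
                                   class = "allele_freqs")
  expect_equal(round_half_up(expected_heterozygosity(uniform(67)), 4),
               0.9851)
  expect_equal(expected_heterozygosity(uniform(1)), 0)
  expect_equal(expected_heterozygosity(
    structure(list(band_ids = c("a", "b"), p = c(0.5, 0.5)),
              class = "allele_freqs")), 0.5)
  for (k in seq(2, 200, by = 7))
    expect_equal(expected_heterozygosity(uniform(k)), 1 - 1 / k)
})

test_that("PIC matches the Botstein double-loop oracle and never exceeds He", {
  two <- structure(list(band_ids = c("a", "b"), p = c(0.5, 0.5)),
                   class = "allele_freqs")
  expect_equal(pic(two), 0.375)
  one <- structure(list(band_ids = "a", p = 1), class = "allele_freqs")
  expect_equal(pic(one), 0)

  u67 <- structure(list(band_ids = as.character(1:67), p = rep(1 / 67, 67)),
                   class = "allele_freqs")
  expect_equal(pic(u67), 1 - 1 / 67 - 66 / 67^3)
  expect_equal(pic(u67), brute_pic(u67$p))

  set.seed(9)
  for (i in 1:20) {
    p <- rgamma(sample(2:12, 1), 1)
    p <- p / sum(p)
    f <- structure(list(band_ids = as.character(seq_along(p)), p = p),
                   class = "allele_freqs")
    expect_equal(pic(f), brute_pic(p))
    expect_lte(pic(f), expected_heterozygosity(f))
  }
})

test_that("PPB classifies observed bands as polymorphic or fixed", {
  # every band present in some but not all -> 100
  m <- make_bm(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0)))
  expect_equal(ppb(m), 100)
  # one fixed band, one polymorphic -> 50
  m2 <- make_bm(rbind(c(1, 1), c(1, 0)))
  expect_equal(ppb(m2), 50)
  expect_error(ppb(make_bm(rbind(c(1, 0)))), "two individuals")

  set.seed(31)
  m3 <- make_bm(matrix(rbinom(300, 1, 0.8), 15, 20))
  counts <- colSums(m3$scores)
  expect_equal(ppb(m3),
               100 * sum(counts > 0 & counts < 15) / sum(counts > 0))
})

test_that("Shannon index spans 0 to log(2) and hits the tuned range", {
  half <- make_bm(rbind(c(1, 1, 1), c(0, 0, 0)))   # every q = 0.5
  expect_equal(shannon_index(half), log(2))
  expect_equal(shannon_index(make_bm(matrix(1, 4, 5))), 0)

  # an accession simulated with all band frequencies near one half keeps
  # its mean per-band entropy just below the log(2) ceiling
  sp <- population_spec("X", rare_fraction = 0, divergence = 0,
                        common_range = c(0.45, 0.55), private_band_count = 0)
  g <- generate_band_matrix(list(sp), seed = 4)
  expect_gte(shannon_index(g$matrix), 0.67)
  expect_lte(shannon_index(g$matrix), 0.69)
})

test_that("resolving power sums band informativeness per primer", {
  m <- make_bm(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))  # all q = 0.5
  expect_equal(resolving_power(m, "Pr1"), 4)
  fixed <- make_bm(cbind(matrix(1, 3, 2), matrix(0, 3, 2)))
  expect_equal(resolving_power(fixed, "Pr1"), 0)
  expect_error(resolving_power(m, "nope"), "no bands")

  # brute-force sum over a synthetic 60 x 25 primer block
  g <- generate_band_matrix(list(population_spec("X")), seed = 2)
  m <- g$matrix
  rp <- resolving_power(m, "Scot28")
  sel <- which(m$primer == "Scot28")
  acc <- 0
  for (j in sel) {
    q <- sum(m$scores[, j]) / n_individuals(m)
    acc <- acc + 1 - 2 * abs(0.5 - q)
  }
  expect_equal(rp, acc)
})

test_that("per-accession primer Rp falls in the field-typical 2.67-13.90 span", {
  g <- generate_band_matrix(seed = 8)
  apt <- accession_primer_table(g$matrix)
  expect_identical(nrow(apt), 20L)   # 4 accessions x 5 primers
  expect_true(all(apt$rp >= 2.67 & apt$rp <= 13.90))
  expect_true(all(apt$pic <= apt$he))
})

test_that("He and PIC are invariant to band and individual reordering", {
  set.seed(13)
  m <- make_bm(matrix(rbinom(120, 1, 0.5), 10, 12))
  perm <- subset(m, sample(m$individual_ids), sample(m$band_ids))
  expect_equal(expected_heterozygosity(allele_frequencies(perm)),
               expected_heterozygosity(allele_frequencies(m)))
  expect_equal(pic(allele_frequencies(perm)), pic(allele_frequencies(m)))

  # duplicating an individual keeps every statistic inside its bounds
  dup <- make_bm(m$scores[c(1:10, 1), ])
  s <- diversity_summary(dup)
  expect_true(s$he >= 0 && s$he < 1)
  expect_true(s$pic >= 0 && s$pic <= s$he)
  expect_true(s$ppb >= 0 && s$ppb <= 100)
  expect_true(s$shannon >= 0 && s$shannon <= log(2))
})
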