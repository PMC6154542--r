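test_that("construction validates shape, binarity and id uniqueness", {
  m <- make_bm(matrix(c(1, 0, 1, 1), 2, 2))
  expect_s3_class(m, "band_matrix")
  expect_identical(dim(m$scores), c(2L, 2L))

  expect_error(band_matrix(matrix(c(1, 2, 0, 1), 2, 2),
                           individual_ids = c("a", "b"),
                           population_labels = c("P", "P"),
                           band_ids = c("x", "y"),
                           band_primer = c("p", "p")),
               "non-binary")
  expect_error(band_matrix(matrix(0:1, 2, 2),
                           individual_ids = c("a", "a"),
                           population_labels = c("P", "P"),
                           band_ids = c("x", "y"),
                           band_primer = c("p", "p")),
               "duplicate individual ids")
  expect_error(make_bm(matrix(1, 2, 2), sizes = c(100, -5)),
               "positive")
})

test_that("read/write round-trips exactly in both dialects", {
  set.seed(7)
  m <- make_bm(matrix(rbinom(40, 1, 0.5), 8, 5),
               pops = rep(c("A", "B"), each = 4),
               primers = rep(c("P1", "P2"), c(3, 2)),
               sizes = c(200, 350, 500, 410, 900))
  for (dialect in c("comma", "tab")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_band_matrix(m, f, dialect)
    m2 <- read_band_matrix(f, dialect)
    expect_identical(m2$scores, m$scores)
    expect_identical(m2$population, m$population)
    expect_identical(m2$primer, m$primer)
    expect_identical(m2$size_bp, m$size_bp)
  }
  # no size row
  m$size_bp <- NULL
  f <- withr::local_tempfile()
  write_band_matrix(m, f)
  expect_null(read_band_matrix(f)$size_bp)
})

test_that("writes are byte-stable", {
  m <- make_bm(matrix(c(1, 0, 0, 1, 1, 1), 2, 3))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_band_matrix(m, f1)
  write_band_matrix(m, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("parse errors name the offending row and band", {
  lines <- c("individual_id,population,b1,b2,b3",
             "primer,,P,P,P",
             "i1,A,1,0,1",
             "i2,A,0,1,0",
             "i3,A,1,2,0")
  f <- withr::local_tempfile(lines = lines)
  expect_error(read_band_matrix(f), "row 3.*band 2")

  f2 <- withr::local_tempfile(lines = c(lines[1:4], "i3,A,1,0"))
  expect_error(read_band_matrix(f2), "ragged")
})

test_that("generator output survives a full-scale file round trip", {
  g <- generate_band_matrix(seed = 5)
  m <- g$matrix
  expect_identical(n_individuals(m), 240L)
  expect_identical(sort(table(m$population)),
                   sort(table(rep(populations(m), each = 60))))
  f <- withr::local_tempfile()
  write_band_matrix(m, f, "tab")
  m2 <- read_band_matrix(f, "tab")
  expect_identical(m2$scores, m$scores)
  expect_identical(m2$primer, m$primer)
})

test_that("subset preserves request order and composes", {
  set.seed(11)
  m <- make_bm(matrix(rbinom(60, 1, 0.5), 6, 10),
               pops = rep(c("A", "B"), 3))
  expect_identical(subset(m)$scores, m$scores)

  one <- subset(m, individuals = "i03")
  expect_identical(n_individuals(one), 1L)
  expect_identical(one$population, "A")

  rev_ids <- rev(m$individual_ids)
  expect_identical(subset(m, rev_ids)$individual_ids, rev_ids)

  expect_error(subset(m, individuals = "nope"), "unknown individual")

  # subset(subset(m, A), B) == subset(m, B) whenever B is within A
  for (s in 1:5) {
    set.seed(s)
    A <- sample(m$individual_ids, 4)
    B <- sample(A, 2)
    bA <- sample(m$band_ids, 6)
    bB <- sample(bA, 3)
    expect_identical(subset(subset(m, A, bA), B, bB), subset(m, B, bB))
  }
})

test_that("band presence counts match a brute-force loop and sum to total", {
  expect_identical(band_presence_counts(make_bm(matrix(1, 3, 2))),
                   c(b01 = 3L, b02 = 3L))
  expect_identical(unname(band_presence_counts(make_bm(rbind(c(1, 0, 1))))),
                   c(1L, 0L, 1L))
  set.seed(3)
  m <- make_bm(matrix(rbinom(200, 1, 0.4), 20, 10))
  counts <- band_presence_counts(m)
  manual <- integer(10)
  for (j in 1:10) for (i in 1:20) manual[j] <- manual[j] + m$scores[i, j]
  expect_identical(unname(counts), manual)
  expect_identical(sum(counts), sum(m$scores))
})
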