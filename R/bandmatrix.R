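#' Construct a band matrix
#'
#' A band matrix is the universe every statistic in this package is computed
#' on: a binary individuals-by-bands score matrix (1 = band present on the
#' gel lane, 0 = absent) annotated with a population label per individual
#' and a primer label per band.  Bands from dominant single-primer marker
#' systems (SCoT, ISSR, RAPD) are scored this way after discarding
#' non-reproducible bands; the matrix is assumed post-curation, so missing
#' scores are a hard error rather than something to impute.
#'
#' @param scores Integer (or numeric) matrix, individuals in rows, bands in
#'   columns; every entry must be 0 or 1.
#' @param individual_ids Character vector of unique individual identifiers
#'   (defaults to rownames of `scores`).
#' @param population_labels Character vector, one population/accession label
#'   per individual (e.g. `"LJ. 1"`).
#' @param band_ids Character vector of unique band identifiers (defaults to
#'   colnames of `scores`).
#' @param band_primer Character vector, one primer name per band
#'   (e.g. `"Scot36"`).
#' @param band_size_bp Optional integer vector of fragment lengths in base
#'   pairs, one per band, all positive.
#' @return An object of class `band_matrix`.
#' @export
#' @examples
#' m <- band_matrix(matrix(c(1, 0, 1, 1), 2, 2),
#'                  individual_ids = c("i1", "i2"),
#'                  population_labels = c("A", "A"),
#'                  band_ids = c("b1", "b2"),
#'                  band_primer = c("P1", "P1"))
#' n_individuals(m)
band_matrix <- function(scores, individual_ids = rownames(scores),
                        population_labels, band_ids = colnames(scores),
                        band_primer, band_size_bp = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(scores)))
  if (is.null(band_ids))
    band_ids <- paste0("band", seq_len(ncol(scores)))
  m <- structure(
    list(scores = scores,
         individual_ids = as.character(individual_ids),
         population = as.character(population_labels),
         band_ids = as.character(band_ids),
         primer = as.character(band_primer),
         size_bp = if (is.null(band_size_bp)) NULL else as.integer(band_size_bp)),
    class = "band_matrix")
  rownames(m$scores) <- m$individual_ids
  colnames(m$scores) <- m$band_ids
  validate_band_matrix(m)
}

validate_band_matrix <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  s <- m$scores
  if (nrow(s) != length(m$individual_ids))
    stop("scores has ", nrow(s), " rows but ", length(m$individual_ids),
         " individual ids", call. = FALSE)
  if (nrow(s) != length(m$population))
    stop("need one population label per individual", call. = FALSE)
  if (ncol(s) != length(m$band_ids))
    stop("scores has ", ncol(s), " columns but ", length(m$band_ids),
         " band ids", call. = FALSE)
  if (ncol(s) != length(m$primer))
    stop("need one primer label per band", call. = FALSE)
  if (anyDuplicated(m$individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(m$individual_ids[duplicated(m$individual_ids)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$band_ids))
    stop("duplicate band ids: ",
         paste(unique(m$band_ids[duplicated(m$band_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!(s %in% c(0L, 1L)) | is.na(s))
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(s)) + 1
    c <- ((bad[1] - 1) %/% nrow(s)) + 1
    stop("non-binary score at row ", r, " (", m$individual_ids[r],
         "), band ", c, " (", m$band_ids[c], "): value '",
         s[r, c], "'", call. = FALSE)
  }
  if (!is.null(m$size_bp)) {
    if (length(m$size_bp) != ncol(s))
      stop("need one band size per band", call. = FALSE)
    if (any(is.na(m$size_bp)) || any(m$size_bp <= 0))
      stop("band sizes must be positive integers", call. = FALSE)
  }
  m
}

#' @rdname band_matrix
#' @param m A `band_matrix`.
#' @export
n_individuals <- function(m) nrow(m$scores)

#' @rdname band_matrix
#' @export
n_bands <- function(m) ncol(m$scores)

#' @rdname band_matrix
#' @export
populations <- function(m) unique(m$population)

#' @export
print.band_matrix <- function(x, ...) {
  cat("band_matrix:", n_individuals(x), "individuals x", n_bands(x),
      "bands\n")
  cat("populations:",
      paste(sprintf("%s (%d)", populations(x),
                    tabulate(factor(x$population, populations(x)))),
            collapse = ", "), "\n")
  cat("primers:", paste(unique(x$primer), collapse = ", "), "\n")
  invisible(x)
}

#' Read a band matrix from delimited text
#'
#' The expected layout is: header row 1 gives the band ids (first two cells
#' reserved for the individual-id and population columns), header row 2 the
#' primer per band, an optional header row 3 (first cell `size_bp`) the
#' fragment sizes; every following row is one individual: id, population
#' label, then 0/1 scores.
#'
#' @param path File to read.
#' @param dialect `"comma"` (CSV) or `"tab"` (TSV).
#' @return A validated [band_matrix].
#' @seealso [write_band_matrix()] for the inverse; the two round-trip
#'   exactly.
#' @export
read_band_matrix <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("file too short: need two header rows and at least one individual",
         call. = FALSE)
  cells <- strsplit(lines, sep, fixed = TRUE)
  width <- length(cells[[1]])
  ragged <- which(vapply(cells, length, 1L) != width)
  if (length(ragged))
    stop("ragged row ", ragged[1], ": expected ", width, " fields, got ",
         length(cells[[ragged[1]]]), call. = FALSE)
  band_ids <- cells[[1]][-(1:2)]
  primer <- cells[[2]][-(1:2)]
  has_size <- length(cells) >= 3 && cells[[3]][1] == "size_bp"
  size_bp <- if (has_size) suppressWarnings(as.integer(cells[[3]][-(1:2)]))
  data_rows <- cells[(if (has_size) 4 else 3):length(cells)]
  ids <- vapply(data_rows, `[`, "", 1L)
  pops <- vapply(data_rows, `[`, "", 2L)
  n <- length(data_rows)
  nb <- length(band_ids)
  scores <- matrix(NA_integer_, n, nb)
  for (i in seq_len(n)) {
    raw <- data_rows[[i]][-(1:2)]
    ok <- raw %in% c("0", "1")
    if (!all(ok)) {
      j <- which(!ok)[1]
      stop("non-binary cell at row ", i, " (", ids[i], "), band ", j,
           " (", band_ids[j], "): value '", raw[j], "'", call. = FALSE)
    }
    scores[i, ] <- as.integer(raw)
  }
  band_matrix(scores, individual_ids = ids, population_labels = pops,
              band_ids = band_ids, band_primer = primer,
              band_size_bp = size_bp)
}

#' Write a band matrix to delimited text
#'
#' Inverse of [read_band_matrix()]; the output is byte-stable (two writes of
#' the same matrix produce identical files) and reading it back reproduces
#' the matrix exactly.
#'
#' @param m A [band_matrix].
#' @inheritParams read_band_matrix
#' @return Invisibly, `path`.
#' @export
write_band_matrix <- function(m, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  validate_band_matrix(m)
  lines <- c(
    paste(c("individual_id", "population", m$band_ids), collapse = sep),
    paste(c("primer", "", m$primer), collapse = sep))
  if (!is.null(m$size_bp))
    lines <- c(lines, paste(c("size_bp", "", m$size_bp), collapse = sep))
  body <- vapply(seq_len(n_individuals(m)), function(i)
    paste(c(m$individual_ids[i], m$population[i], m$scores[i, ]),
          collapse = sep), "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Subset a band matrix by individuals and/or bands
#'
#' Order of the request is preserved, which is what makes random
#' subsampling experiments reproducible.
#'
#' @param x A [band_matrix].
#' @param individuals Character vector of individual ids, or `"all"`.
#' @param bands Character vector of band ids, or `"all"`.
#' @param ... Ignored.
#' @return A `band_matrix` restricted to the requested rows/columns.
#' @export
subset.band_matrix <- function(x, individuals = "all", bands = "all", ...) {
  if (identical(individuals, "all")) individuals <- x$individual_ids
  if (identical(bands, "all")) bands <- x$band_ids
  ri <- match(individuals, x$individual_ids)
  if (anyNA(ri))
    stop("unknown individual id(s): ",
         paste(individuals[is.na(ri)], collapse = ", "), call. = FALSE)
  ci <- match(bands, x$band_ids)
  if (anyNA(ci))
    stop("unknown band id(s): ", paste(bands[is.na(ci)], collapse = ", "),
         call. = FALSE)
  band_matrix(x$scores[ri, ci, drop = FALSE],
              individual_ids = x$individual_ids[ri],
              population_labels = x$population[ri],
              band_ids = x$band_ids[ci],
              band_primer = x$primer[ci],
              band_size_bp = if (is.null(x$size_bp)) NULL else x$size_bp[ci])
}

#' Per-band presence counts
#'
#' The shared kernel of every frequency-based statistic: the number of
#' individuals carrying each band.
#'
#' @param m A [band_matrix].
#' @return Named integer vector, one count per band, each in
#'   `[0, n_individuals(m)]`.
#' @export
band_presence_counts <- function(m) {
  counts <- colSums(m$scores)
  storage.mode(counts) <- "integer"
  counts
}
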