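#' Jaccard similarity of two band profiles
#'
#' `J = a / (a + b + c)` where `a` counts shared presences and `b`, `c` the
#' presences unique to each profile; shared absences carry no information
#' about relatedness for dominant markers and are ignored.
#'
#' @param x,y 0/1 vectors of equal length, not both all-zero.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' jaccard_similarity(c(1, 1, 0, 1), c(1, 0, 0, 1))  # 2/3
jaccard_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  a <- sum(x == 1 & y == 1)
  bc <- sum(x != y)
  if (a + bc == 0)
    stop("Jaccard similarity undefined for two all-zero profiles",
         call. = FALSE)
  a / (a + bc)
}

#' Jaccard similarity matrix of a band matrix
#'
#' @param m A [band_matrix]; every individual must carry at least one band.
#' @return Symmetric matrix of pairwise Jaccard similarities with unit
#'   diagonal.
#' @seealso [jaccard_distance()] for the complement used in clustering.
#' @export
similarity_matrix <- function(m) {
  zero <- rowSums(m$scores) == 0
  if (any(zero))
    stop("individual(s) with no bands: ",
         paste(m$individual_ids[zero], collapse = ", "), call. = FALSE)
  x <- m$scores
  a <- tcrossprod(x)                  # shared presences
  r <- rowSums(x)
  union <- outer(r, r, `+`) - a       # a + b + c
  s <- a / union
  dimnames(s) <- list(m$individual_ids, m$individual_ids)
  s
}

#' @rdname similarity_matrix
#' @return `jaccard_distance()` returns the matrix `1 - J`.
#' @export
jaccard_distance <- function(m) 1 - similarity_matrix(m)

# Jaccard distance tolerant of empty profiles, used only inside the band
# bootstrap where resampling columns can leave an individual bandless:
# two empty profiles are treated as identical, an empty vs non-empty pair
# as maximally distant.
jaccard_distance_safe <- function(scores) {
  a <- tcrossprod(scores)
  r <- rowSums(scores)
  union <- outer(r, r, `+`) - a
  d <- 1 - a / union
  d[union == 0] <- 0
  diag(d) <- 0
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group average-linkage agglomeration: at each step the
#' two closest clusters merge and the distance of the merged cluster to any
#' other is the size-weighted mean of its parts (equivalently, the
#' unweighted mean of the original leaf-to-leaf distances).  Each internal
#' node is placed at half its merge distance, producing an ultrametric
#' rooted tree in which all leaves are equidistant from the root.  Exact
#' distance ties are broken towards the smallest (row, column) index pair
#' of the current working matrix, making runs reproducible across
#' platforms.
#'
#' @param d Symmetric non-negative distance matrix (or `dist`) with zero
#'   diagonal.
#' @param labels Leaf labels (defaults to `d`'s dimnames).
#' @return Object of class `upgma_tree`: a list with an `hclust`
#'   representation (`$hclust`, heights = merge distances), an
#'   [ape::phylo] representation (`$phylo`, node heights = merge
#'   distance / 2), `$labels`, and `$support` (bootstrap percentages, `NULL`
#'   until [bootstrap_support()] fills them in).
#' @export
upgma <- function(d, labels = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2, ncol(d) == n)
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("need a symmetric non-negative matrix with zero diagonal",
         call. = FALSE)
  labels <- labels %||% rownames(d) %||% paste0("t", seq_len(n))
  dm <- d
  dimnames(dm) <- NULL
  dm[lower.tri(dm, diag = TRUE)] <- Inf
  code <- -seq_len(n)        # hclust codes: negative = singleton
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  active <- seq_len(n)
  for (s in seq_len(n - 1)) {
    cand <- which(dm == min(dm), arr.ind = TRUE)
    pick <- cand[order(cand[, 1], cand[, 2])[1], ]
    i <- pick[1]; j <- pick[2]          # i < j in the working matrix
    height[s] <- dm[i, j]
    merge[s, ] <- c(code[i], code[j])
    # merged cluster replaces slot i; slot j is dropped
    wi <- size[i]; wj <- size[j]
    newd <- (wi * pmin(dm[i, ], dm[, i]) + wj * pmin(dm[j, ], dm[, j])) /
      (wi + wj)
    dm[i, ] <- newd
    dm[, i] <- newd
    dm[i, ] [lower.tri(dm, diag = TRUE)[i, ]] <- Inf
    dm[, i] [lower.tri(dm, diag = TRUE)[, i]] <- Inf
    dm <- dm[-j, -j, drop = FALSE]
    code <- code[-j]; size <- size[-j]
    code[i] <- s
    size[i] <- wi + wj
  }
  h <- structure(list(merge = merge, height = height,
                      order = upgma_leaf_order(merge),
                      labels = labels, method = "average",
                      call = match.call(), dist.method = NULL),
                 class = "hclust")
  structure(list(hclust = h, phylo = ape::as.phylo(h), labels = labels,
                 heights = height / 2, support = NULL,
                 bootstrap_replicates = NULL),
            class = "upgma_tree")
}

# leaf order for the hclust object (left-to-right traversal of merges)
upgma_leaf_order <- function(merge) {
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("upgma_tree with", length(x$labels), "leaves; root height",
      format(max(x$heights), digits = 4), "\n")
  if (!is.null(x$support)) {
    shown <- ifelse(x$support >= 50, sprintf("%.0f", x$support), "-")
    cat("bootstrap supports (\"-\" = below 50%, retained in $support):\n")
    cat(" ", paste(shown, collapse = " "), "\n")
  }
  invisible(x)
}

#' Cophenetic distances of a UPGMA tree
#'
#' Entry (i, j) is the distance at which leaves i and j first join, i.e.
#' twice the height of their most recent common ancestor.  When the input
#' distance matrix was already ultrametric these reproduce it exactly.
#'
#' @param t An [upgma()] tree.
#' @return Symmetric matrix of cophenetic distances.
#' @export
cophenetic_distances <- function(t) {
  as.matrix(stats::cophenetic(t$hclust))
}

#' Cut a UPGMA tree into k groups
#'
#' @param t An [upgma()] tree.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_upgma <- function(t, k) stats::cutree(t$hclust, k = k)

#' Band-bootstrap clade support for a UPGMA tree
#'
#' Resamples bands (matrix columns) with replacement, rebuilds the
#' Jaccard/UPGMA tree on each replicate, and records for every internal
#' node of the original tree the percentage of replicates recovering its
#' leaf bipartition.  Bands are the characters and individuals the tips,
#' so columns are the natural resampling unit.  Supports below 50% are
#' conventionally not displayed (see `print.upgma_tree`) but are retained
#' in `$support`.
#'
#' @param m A [band_matrix].
#' @param replicates Bootstrap replicates, at least 100 (default 1000).
#' @param seed Integer seed; identical seeds give identical supports.
#' @return The [upgma()] tree of `m` with `$support` set (one percentage
#'   per internal node, in `$phylo` node order) and node labels attached to
#'   the `phylo` representation for Newick export.
#' @export
bootstrap_support <- function(m, replicates = 1000, seed) {
  stopifnot(replicates >= 100)
  ref <- upgma(jaccard_distance(m), labels = m$individual_ids)
  nb <- n_bands(m)
  boots <- with_seed(seed, lapply(seq_len(replicates), function(b) {
    cols <- sample.int(nb, replace = TRUE)
    upgma(jaccard_distance_safe(m$scores[, cols, drop = FALSE]),
          labels = m$individual_ids)$phylo
  }))
  counts <- ape::prop.clades(ref$phylo, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  ref$support <- 100 * counts / replicates
  ref$bootstrap_replicates <- as.integer(replicates)
  ref$phylo$node.label <- sprintf("%.0f", ref$support)
  ref
}

#' Write a UPGMA tree as Newick text
#'
#' Branch lengths are parent height minus child height (so root-to-leaf
#' paths all equal the root height); bootstrap supports, when present, are
#' written as internal node labels.  Re-reading the file reproduces
#' topology, heights and supports.
#'
#' @param t An [upgma()] tree.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t$phylo, file = path)
  invisible(path)
}
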