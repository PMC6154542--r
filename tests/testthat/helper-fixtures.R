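# Small band-matrix builders used across the test files.

make_bm <- function(scores, pops = rep("P1", nrow(scores)),
                    primers = rep("Pr1", ncol(scores)), sizes = NULL) {
  scores <- as.matrix(scores)
  band_matrix(scores,
              individual_ids = sprintf("i%02d", seq_len(nrow(scores))),
              population_labels = pops,
              band_ids = sprintf("b%02d", seq_len(ncol(scores))),
              band_primer = primers,
              band_size_bp = sizes)
}

random_bm <- function(n, nb, p = 0.5, pops = rep("P1", n), seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(make_bm(matrix(rbinom(n * nb, 1, p), n, nb), pops = pops))
}

# A matrix of two populations with disjoint fixed band sets: all variance
# lies among groups, so Phi_ST must be exactly 1.
disjoint_bm <- function(n_per = 4, nb_per = 5) {
  a <- cbind(matrix(1L, n_per, nb_per), matrix(0L, n_per, nb_per))
  b <- cbind(matrix(0L, n_per, nb_per), matrix(1L, n_per, nb_per))
  make_bm(rbind(a, b), pops = rep(c("A", "B"), each = n_per))
}
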