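#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis.  A master seed is
#' mandatory (no wall-clock seeding anywhere); each stage draws its own
#' child seed from it deterministically, so partial reruns reproduce.
#'
#' @param input Path to a band-matrix file (see [read_band_matrix()]), or
#'   `NULL` to generate synthetic data from `specs`.
#' @param dialect File dialect when `input` is given.
#' @param specs List of [population_spec()]s for synthetic input.
#' @param ladder A [sampling_ladder()].
#' @param replicates Subsamples per ladder size (default 200).
#' @param bootstrap_replicates UPGMA band-bootstrap replicates
#'   (default 500).
#' @param permutations AMOVA permutations (default 999).
#' @param k_min,k_max,runs_per_k,iterations,burnin Admixture grid settings
#'   (defaults K = 2..8, 10 runs, 2,000 sweeps, 500 burn-in).
#' @param seed Master seed (required).
#' @param out_dir Output directory; created if missing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, dialect = "comma",
                            specs = default_population_specs(),
                            ladder = sampling_ladder(),
                            replicates = 200,
                            bootstrap_replicates = 500,
                            permutations = 999,
                            k_min = 2, k_max = 8, runs_per_k = 10,
                            iterations = 2000, burnin = 500,
                            seed, out_dir) {
  stopifnot(replicates >= 1, bootstrap_replicates >= 100,
            permutations >= 99, k_min >= 2, k_max >= k_min,
            runs_per_k >= 1, iterations > burnin, burnin >= 0)
  if (missing(seed)) stop("a master seed is required", call. = FALSE)
  structure(list(input = input, dialect = dialect, specs = specs,
                 ladder = ladder, replicates = replicates,
                 bootstrap_replicates = bootstrap_replicates,
                 permutations = permutations, k_min = k_min,
                 k_max = k_max, runs_per_k = runs_per_k,
                 iterations = iterations, burnin = burnin,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

fmt4 <- function(x) sprintf("%.4f", round_half_up(x, 4))

#' Run the full sampling-size analysis
#'
#' Orchestrates every module on one input matrix (read from file or
#' generated synthetically): diversity summaries (overall, per primer, per
#' accession x primer), per-population retention curves with the exact
#' rarefaction expectation and the plateau size at 90% retention, AMOVA
#' with permutation p-value plus the fixation-index sweep, the
#' Jaccard/UPGMA tree with band-bootstrap supports written as Newick, and
#' the admixture grid with the Evanno delta-K table.  All tables are TSV;
#' a run log records the child seed of every stage.  Identical configs
#' produce byte-identical tables.  With a single population the AMOVA and
#' sweep stages are skipped (and the log says why).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `diversity`, `rarefaction`, `amova`, `fst`, `tree`, `delta_k`,
#'   `plateau`) and `files`, the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  seeds <- spawn_seeds(config$seed, 5)
  log_lines <- c(sprintf("scotdiv %s", as.character(utils::packageVersion("scotdiv"))),
                 sprintf("master seed: %d", config$seed),
                 sprintf("stage seeds: data=%d rarefy=%d amova=%d tree=%d admixture=%d",
                         seeds[1], seeds[2], seeds[3], seeds[4], seeds[5]))
  files <- character(0)

  # -- data
  if (!is.null(config$input)) {
    m <- read_band_matrix(config$input, config$dialect)
    log_lines <- c(log_lines, sprintf("input: %s", config$input))
  } else {
    m <- generate_band_matrix(config$specs, seed = seeds[1])$matrix
    log_lines <- c(log_lines,
                   sprintf("input: synthetic (%d populations)",
                           length(config$specs)))
  }
  files <- c(files, write_band_matrix(m, out("band_matrix.tsv"), "tab"))
  pops <- populations(m)

  # -- diversity
  div <- do.call(rbind, lapply(pops, function(p) {
    d <- diversity_summary(subset(m, m$individual_ids[m$population == p]))
    cbind(population = p, d)
  }))
  div_out <- data.frame(population = div$population, n = div$n,
                        na = div$na, ppb = fmt4(div$ppb),
                        he = fmt4(div$he), pic = fmt4(div$pic),
                        shannon = fmt4(div$shannon))
  files <- c(files, write_tsv(div_out, out("diversity_summary.tsv")))
  ps <- primer_summary(m)
  ps[c("ppb", "he", "pic", "rp")] <- lapply(ps[c("ppb", "he", "pic", "rp")],
                                            fmt4)
  files <- c(files, write_tsv(ps, out("primer_summary.tsv")))
  apt <- accession_primer_table(m)
  apt[c("rp", "he", "pic")] <- lapply(apt[c("rp", "he", "pic")], fmt4)
  files <- c(files, write_tsv(apt, out("accession_primer.tsv")))

  # -- rarefaction
  rar_seeds <- spawn_seeds(seeds[2], length(pops))
  curves <- Map(function(p, s)
    subsample_curve(m, p, config$ladder, config$replicates, seed = s),
    pops, rar_seeds)
  rar <- do.call(rbind, Map(function(p, r)
    cbind(population = p, r$per_size), pops, curves))
  num <- setdiff(names(rar), c("population", "size"))
  rar[num] <- lapply(rar[num], fmt4)
  files <- c(files, write_tsv(rar, out("rarefaction.tsv")))
  plateau <- vapply(curves, function(r)
    tryCatch(plateau_size(r, 90), error = function(e) NA_integer_), 1L)

  # -- differentiation
  amv <- NULL; fst <- NULL
  if (length(pops) >= 2) {
    amv <- phi_st_permutation(m, n_permutations = config$permutations,
                              seed = seeds[3])
    amova_tab <- data.frame(
      source = c("among populations", "within populations"),
      df = c(amv$df_among, amv$df_within),
      SS = fmt4(c(amv$ss_among, amv$ss_within)),
      sigma2 = fmt4(c(amv$sigma2_among, amv$sigma2_within)),
      phi_st = c(fmt4(amv$phi_st), ""),
      p_value = c(format(amv$p_value, digits = 4), ""))
    files <- c(files, write_tsv(amova_tab, out("amova.tsv")))
    fst <- fst_sweep(m, config$ladder, replicates = 25, seed = seeds[3],
                     mode = "focal")
    fstf <- fst
    fstf[setdiff(names(fstf), "size")] <-
      lapply(fstf[setdiff(names(fstf), "size")],
             function(x) sprintf("%.2f", round_half_up(x, 2)))
    files <- c(files, write_tsv(fstf, out("fst_sweep.tsv")))
  } else {
    log_lines <- c(log_lines,
                   "amova: skipped (single population, nothing to partition)")
  }

  # -- clustering
  tree <- bootstrap_support(m, config$bootstrap_replicates, seed = seeds[4])
  files <- c(files, write_newick(tree, out("tree.nwk")))
  sim <- similarity_matrix(m)
  files <- c(files, write_tsv(
    data.frame(individual = rownames(sim),
               apply(sim, 2, fmt4), check.names = FALSE),
    out("similarity.tsv")))

  # -- admixture
  fits <- run_grid(m, config$k_min, config$k_max, config$runs_per_k,
                   config$iterations, config$burnin, seed = seeds[5])
  dk <- evanno_delta_k(fits)
  dk_tab <- dk$table
  dk_tab[c("mean_l", "sd_l", "l_second", "delta_k")] <-
    lapply(dk_tab[c("mean_l", "sd_l", "l_second", "delta_k")],
           function(x) ifelse(is.na(x), "NA", fmt4(x)))
  files <- c(files, write_tsv(dk_tab, out("delta_k.tsv")))
  if (!is.na(dk$best_k)) {
    best <- Filter(function(f) f$K == dk$best_k, fits)
    best_fit <- best[[which.max(vapply(best, `[[`, 0, "mean_loglik"))]]
    q_tab <- data.frame(individual = rownames(best_fit$q),
                        population = m$population,
                        apply(best_fit$q, 2, fmt4))
    names(q_tab)[-(1:2)] <- paste0("Q", seq_len(best_fit$K))
    files <- c(files, write_tsv(q_tab, out(sprintf("membership_K%d.tsv",
                                                   dk$best_k))))
    log_lines <- c(log_lines, sprintf("delta-K best K: %d", dk$best_k))
  } else {
    log_lines <- c(log_lines, "delta-K: no signal")
  }

  log_lines <- c(log_lines,
                 sprintf("plateau size at RP >= 90%%: %s",
                         paste(sprintf("%s=%s", pops, plateau),
                               collapse = " ")))
  writeLines(log_lines, out("run_log.txt"))
  files <- c(files, out("run_log.txt"))

  invisible(list(matrix = m, diversity = div, primer_summary = ps,
                 rarefaction = curves, plateau = plateau, amova = amv,
                 fst = fst, tree = tree, delta_k = dk, files = files))
}
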