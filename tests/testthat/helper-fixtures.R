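# Shared fixture builders; every fixture is generated in code under a
# caller-supplied seed.

# A minimal single-condition design with `s` replicate samples, handy for
# normalization tests where the factorial structure is irrelevant.
flat_design <- function(s) {
  make_design(levels = list(cultivar = 1, tissue = 1, stage = 1, soil = 1),
              replicates = s)
}

# Random count matrix wrapped as a count_matrix, with log-normal
# library-size spread.
random_counts <- function(n_genes, n_samples, seed, lib_sd = 0.4) {
  set.seed(seed)
  lib <- exp(rnorm(n_samples, 0, lib_sd))
  mu <- exp(runif(n_genes, 1, 6))
  m <- vapply(seq_len(n_samples), function(s) {
    rnbinom(n_genes, mu = mu * lib[s], size = 5)
  }, numeric(n_genes))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  des <- flat_design(n_samples)
  colnames(m) <- des$sample_id
  count_matrix(m, des)
}

# Six-archetype benchmark simulation at the standard parameters.
benchmark_sim <- function(genes_per_archetype, seed, fold_change = 4,
                          dispersion = 0.05) {
  design <- make_design()
  arch <- archetype_panel(design, fold_change = fold_change,
                          dispersion = dispersion)
  sim <- simulate_counts(design, arch,
                         genes_per_archetype = genes_per_archetype,
                         seed = seed)
  sim$design <- design
  sim
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run code under a local seed without touching the suite's RNG stream
with_seed_for_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
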