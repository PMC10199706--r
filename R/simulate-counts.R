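#' Gene expression archetypes
#'
#' An archetype describes the expected-expression program shared by a block
#' of simulated genes: which design variables drive it, the baseline mean
#' count, per-level log2 effects, and the negative-binomial dispersion
#' (variance = mu + mu^2 * dispersion).
#'
#' `effects` is a named list keyed by driver variable (`"stage"`,
#' `"cultivar"`, `"tissue"`, `"soil"`) or by a single two-way interaction
#' written `"stage:soil"`; each element is a named numeric vector of log2
#' effects keyed by level (or `"level1:level2"` for the interaction).
#' Levels not named get effect 0. An archetype with an empty `effects`
#' list is flat (no driver).
#'
#' @param name Archetype label.
#' @param baseline_mean Expected count at reference levels (> 0).
#' @param dispersion NB dispersion (> 0).
#' @param effects Named list of log2 effects (see Details).
#' @return An object of class `gene_archetype`.
#' @export
#' @examples
#' gene_archetype("soil_up", effects = list(soil = c(soil_c = 2)))
gene_archetype <- function(name, baseline_mean = 100, dispersion = 0.05,
                           effects = list()) {
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    stop("`baseline_mean` must be > 0", call. = FALSE)
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be > 0 for archetype `", name, "`", call. = FALSE)
  }
  if (length(effects) && is.null(names(effects))) {
    stop("`effects` must be a named list", call. = FALSE)
  }
  eff_names <- names(effects) %||% character(0)
  main <- eff_names[!grepl(":", eff_names, fixed = TRUE)]
  inter <- eff_names[grepl(":", eff_names, fixed = TRUE)]
  bad <- setdiff(main, design_factors())
  if (length(bad)) {
    stop("unknown driver variable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(inter) > 1L) {
    stop("at most one two-way interaction per archetype", call. = FALSE)
  }
  drivers <- unique(c(main, unlist(strsplit(inter, ":", fixed = TRUE))))
  structure(
    list(name = name, baseline_mean = baseline_mean, dispersion = dispersion,
         effects = effects, drivers = drivers),
    class = "gene_archetype"
  )
}

#' @export
print.gene_archetype <- function(x, ...) {
  drv <- if (length(x$drivers)) paste(x$drivers, collapse = ", ") else "none"
  cat("<gene_archetype> ", x$name, "\n",
      "  drivers: ", drv, "\n",
      "  baseline mean: ", x$baseline_mean,
      "; dispersion: ", x$dispersion, "\n", sep = "")
  invisible(x)
}

#' Standard six-archetype benchmark panel
#'
#' One archetype per design variable (stage, cultivar, tissue, soil), one
#' stage x soil interaction archetype, and one flat (driverless) archetype.
#' Effect sizes are set so the driven levels differ from baseline by
#' `fold_change`. Level names are taken from `design`.
#'
#' @param design Sample design (see [make_design()]).
#' @param fold_change Fold-change of the driven condition(s) vs baseline.
#' @param baseline_mean,dispersion Shared NB parameters.
#' @return Named list of [gene_archetype()] objects.
#' @export
archetype_panel <- function(design = make_design(), fold_change = 4,
                            baseline_mean = 100, dispersion = 0.05) {
  lfc <- log2(fold_change)
  lv <- lapply(design[design_factors()], levels)
  stage_eff <- setNames(
    lfc * seq(0, 1, length.out = length(lv$stage))[-1],
    lv$stage[-1]
  )
  last <- function(x) x[length(x)]
  list(
    stage = gene_archetype("stage", baseline_mean, dispersion,
                           list(stage = stage_eff)),
    cultivar = gene_archetype("cultivar", baseline_mean, dispersion,
                              list(cultivar = setNames(lfc, last(lv$cultivar)))),
    tissue = gene_archetype("tissue", baseline_mean, dispersion,
                            list(tissue = setNames(lfc, last(lv$tissue)))),
    soil = gene_archetype("soil", baseline_mean, dispersion,
                          list(soil = setNames(lfc, last(lv$soil)))),
    # pure interaction: stage level i is elevated in soil i only, so every
    # stage and every soil marginal is flat and all signal is non-additive
    stage_x_soil = gene_archetype(
      "stage_x_soil", baseline_mean, dispersion,
      list(`stage:soil` = setNames(
        rep(lfc, min(length(lv$stage), length(lv$soil))),
        paste(lv$stage[seq_len(min(length(lv$stage), length(lv$soil)))],
              lv$soil[seq_len(min(length(lv$stage), length(lv$soil)))],
              sep = ":")
      ))
    ),
    flat = gene_archetype("flat", baseline_mean, dispersion, list())
  )
}

# per-sample log2 effect of one archetype given the design rows
archetype_log2_effects <- function(archetype, design) {
  eff <- rep(0, nrow(design))
  for (key in names(archetype$effects)) {
    vals <- archetype$effects[[key]]
    if (grepl(":", key, fixed = TRUE)) {
      vars <- strsplit(key, ":", fixed = TRUE)[[1]]
      combo <- paste(as.character(design[[vars[1]]]),
                     as.character(design[[vars[2]]]), sep = ":")
      hit <- vals[combo]
    } else {
      hit <- vals[as.character(design[[key]])]
    }
    hit[is.na(hit)] <- 0
    eff <- eff + hit
  }
  eff
}

#' Construct a count matrix bound to its sample design
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns; column names must match `design$sample_id` exactly.
#' @param design Sample design tibble (see [make_design()]).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene row names", call. = FALSE)
  }
  if (!identical(colnames(counts), design$sample_id)) {
    stop("count columns must match `design$sample_id` exactly (same order)",
         call. = FALSE)
  }
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", dplyr::n_distinct(x$design$condition), " conditions)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Simulate factorial negative-binomial RNA-seq counts
#'
#' Draws a gene x sample count matrix from the archetype model: for gene g
#' in archetype a and sample s,
#' `count ~ NB(mean = baseline_g * 2^effect_a(s) * libfactor_s, dispersion)`.
#' Library-size factors are log-normal (sd `lib_size_sd` on the log scale)
#' so TMM normalization is non-trivial; per-gene baselines jitter around the
#' archetype baseline by a log2-normal factor (sd `baseline_log2_sd`).
#' Identical seeds give bit-identical matrices.
#'
#' @param design Sample design (see [make_design()]).
#' @param archetypes List of [gene_archetype()] objects.
#' @param genes_per_archetype Integer count, recycled across archetypes.
#' @param seed Integer seed; the sole source of randomness.
#' @param lib_size_sd Log-scale sd of library-size factors.
#' @param baseline_log2_sd Per-gene baseline jitter (log2 sd).
#' @return A list with `counts` (a [count_matrix()]) and `truth`
#'   (a `synthetic_truth` record of the planted archetypes).
#' @export
#' @examples
#' sim <- simulate_counts(make_design(), archetype_panel(),
#'                        genes_per_archetype = 10, seed = 1)
#' dim(sim$counts)
simulate_counts <- function(design, archetypes, genes_per_archetype = 100,
                            seed = 1, lib_size_sd = 0.3,
                            baseline_log2_sd = 0.25) {
  if (length(archetypes) < 1L) stop("need at least one archetype", call. = FALSE)
  if (!all(vapply(archetypes, inherits, logical(1), "gene_archetype"))) {
    stop("`archetypes` must be a list of `gene_archetype` objects",
         call. = FALSE)
  }
  n_arch <- length(archetypes)
  gpa <- rep_len(as.integer(genes_per_archetype), n_arch)
  n_genes <- sum(gpa)
  n_samples <- nrow(design)
  arch_names <- names(archetypes) %||%
    vapply(archetypes, `[[`, character(1), "name")

  with_seed(seed, {
    lib_factors <- exp(rnorm(n_samples, 0, lib_size_sd))
    counts <- matrix(0L, n_genes, n_samples)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    gene_arch <- rep(arch_names, gpa)
    baselines <- numeric(n_genes)
    dispersions <- numeric(n_genes)
    row <- 1L
    for (i in seq_len(n_arch)) {
      a <- archetypes[[i]]
      eff <- archetype_log2_effects(a, design)  # length n_samples
      for (g in seq_len(gpa[i])) {
        base_g <- a$baseline_mean * 2^rnorm(1, 0, baseline_log2_sd)
        mu <- base_g * 2^eff * lib_factors
        counts[row, ] <- rnbinom(n_samples, mu = mu, size = 1 / a$dispersion)
        baselines[row] <- base_g
        dispersions[row] <- a$dispersion
        row <- row + 1L
      }
    }
    dimnames(counts) <- list(gene_ids, design$sample_id)

    truth <- new_synthetic_truth(
      genes = tibble::tibble(
        gene = gene_ids,
        archetype = gene_arch,
        drivers = vapply(gene_arch, function(nm) {
          a <- archetypes[[match(nm, arch_names)]]
          paste(a$drivers, collapse = ",")
        }, character(1), USE.NAMES = FALSE),
        status = "archetype",
        baseline_mean = baselines,
        dispersion = dispersions
      ),
      lib_factors = tibble::tibble(sample_id = design$sample_id,
                                   lib_factor = lib_factors),
      seed = seed
    )
    list(counts = count_matrix(counts, design), truth = truth)
  })
}

new_synthetic_truth <- function(genes = NULL, lib_factors = NULL, seed = NA,
                                motifs = NULL, terms = NULL) {
  structure(
    list(genes = genes, lib_factors = lib_factors, motifs = motifs,
         terms = terms, seed = seed),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed ", x$seed, "\n", sep = "")
  if (!is.null(x$genes)) {
    cat("  genes: ", nrow(x$genes), " (",
        paste(names(table(x$genes$status)), table(x$genes$status),
              sep = "=", collapse = ", "), ")\n", sep = "")
  }
  if (!is.null(x$motifs)) cat("  motif records: ", nrow(x$motifs), "\n", sep = "")
  if (!is.null(x$terms)) cat("  planted terms: ", nrow(x$terms), "\n", sep = "")
  invisible(x)
}

#' Overwrite genes with inadequate expression profiles
#'
#' Replaces a random subset of rows of a simulated count matrix with the
#' three inadequate-profile classes the screening step must discard:
#' effectively unexpressed genes, constitutively expressed genes (identical
#' expected mean in every condition), and genes with a single-sample
#' outlier spike (`outlier_fold` times the gene's flat mean, >= 50x).
#'
#' @param counts A [count_matrix()].
#' @param n_unexpressed,n_constitutive,n_outlier Genes to plant per class.
#' @param seed Integer seed.
#' @param truth Optional `synthetic_truth` to update (library-size factors
#'   are reused from it so planted genes see the same sequencing depths).
#' @param unexpressed_mean Expected count per sample for unexpressed genes.
#' @param constitutive_range Log-uniform range of flat expected means;
#'   the default emulates robustly expressed housekeeping-like genes.
#' @param outlier_fold Spike multiplier for the single outlier sample.
#' @param dispersion NB dispersion of planted genes.
#' @return A list with updated `counts` and `truth`.
#' @export
plant_inadequate_genes <- function(counts, n_unexpressed = 0,
                                   n_constitutive = 0, n_outlier = 0,
                                   seed = 1, truth = NULL,
                                   unexpressed_mean = 0.002,
                                   constitutive_range = c(100, 1000),
                                   outlier_fold = 100, dispersion = 0.05) {
  assert_count_matrix(counts)
  if (dispersion <= 0) stop("`dispersion` must be > 0", call. = FALSE)
  if (outlier_fold < 50) {
    stop("`outlier_fold` must be >= 50 so spikes are unambiguous", call. = FALSE)
  }
  n_plant <- n_unexpressed + n_constitutive + n_outlier
  n_genes <- nrow(counts$counts)
  if (n_plant > n_genes) {
    stop("requested ", n_plant, " planted genes but the matrix has only ",
         n_genes, " rows", call. = FALSE)
  }
  if (n_plant == 0L) {
    return(list(counts = counts, truth = truth %||% new_synthetic_truth(seed = seed)))
  }
  lib <- if (!is.null(truth) && !is.null(truth$lib_factors)) {
    truth$lib_factors$lib_factor[match(colnames(counts$counts),
                                       truth$lib_factors$sample_id)]
  } else {
    rep(1, ncol(counts$counts))
  }
  n_samples <- ncol(counts$counts)

  with_seed(seed, {
    rows <- sample.int(n_genes, n_plant)
    labels <- rep(c("unexpressed", "constitutive", "outlier"),
                  c(n_unexpressed, n_constitutive, n_outlier))
    mat <- counts$counts
    for (i in seq_along(rows)) {
      r <- rows[i]
      if (labels[i] == "unexpressed") {
        mu <- unexpressed_mean * lib
      } else {
        base <- exp(runif(1, log(constitutive_range[1]),
                          log(constitutive_range[2])))
        mu <- base * lib
        if (labels[i] == "outlier") {
          spike <- sample.int(n_samples, 1)
          mu[spike] <- mu[spike] * outlier_fold
        }
      }
      mat[r, ] <- rnbinom(n_samples, mu = mu, size = 1 / dispersion)
    }
    out_counts <- count_matrix(mat, counts$design)

    gene_ids <- rownames(mat)
    truth <- truth %||% new_synthetic_truth(
      genes = tibble::tibble(gene = gene_ids, archetype = NA_character_,
                             drivers = "", status = "archetype",
                             baseline_mean = NA_real_, dispersion = NA_real_),
      seed = seed
    )
    idx <- match(gene_ids[rows], truth$genes$gene)
    truth$genes$status[idx] <- labels
    truth$genes$archetype[idx] <- NA_character_
    truth$genes$drivers[idx] <- ""
    list(counts = out_counts, truth = truth)
  })
}
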