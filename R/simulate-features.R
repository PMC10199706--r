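#' Simulate promoter sequences with planted TF binding sites
#'
#' Generates one fixed-length promoter per gene as i.i.d. draws from a
#' stated base composition. Genes in `bound_set` additionally receive one
#' binding site sampled from the PWM's per-position base probabilities, at
#' a random offset and on a random strand, and a DAP-seq-style peak interval
#' whose midpoint falls in the upstream TSS window is emitted for each
#' bound gene. A synthetic TSS table (gene, chrom, tss, strand) is created
#' alongside so peak offsets can be recomputed strand-aware downstream.
#'
#' @param genes Character vector of gene ids.
#' @param pwm A [make_pwm()] object.
#' @param bound_set Subset of `genes` that carry a planted site.
#' @param length Promoter length in bp (default 600, the scoring window).
#' @param seed Integer seed.
#' @param base_freq Background base probabilities, named A/C/G/T.
#' @param tf Label attached to emitted peaks.
#' @param site `"sample"` draws each planted site from the PWM's
#'   per-position probabilities (sites carry realistic mismatches);
#'   `"consensus"` plants the exact consensus sequence.
#' @param peak_window Interval (relative to the TSS, upstream negative) in
#'   which peak midpoints are placed.
#' @param peak_halfwidth Half-width of emitted peaks in bp.
#' @return A list: `promoters` (tibble gene, sequence), `tss` (tibble gene,
#'   chrom, tss, strand), `peaks` (0-based half-open intervals with tf,
#'   gene and true offset), and `truth` (planted site records).
#' @export
simulate_promoters <- function(genes, pwm, bound_set = character(),
                               length = 600, seed = 1,
                               base_freq = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                               tf = "TF1", site = c("sample", "consensus"),
                               peak_window = c(-2000, 0),
                               peak_halfwidth = 100) {
  site <- match.arg(site)
  stopifnot(inherits(pwm, "pwm"))
  if (pwm$width > length) {
    stop("PWM width exceeds promoter length", call. = FALSE)
  }
  if (!all(bound_set %in% genes)) {
    stop("`bound_set` must be a subset of `genes`", call. = FALSE)
  }
  base_freq <- base_freq[c("A", "C", "G", "T")]
  if (anyNA(base_freq) || any(base_freq < 0)) {
    stop("`base_freq` must be non-negative and named A/C/G/T", call. = FALSE)
  }
  base_freq <- base_freq / sum(base_freq)
  n <- base::length(genes)
  w <- pwm$width
  alphabet <- c("A", "C", "G", "T")

  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet, length, replace = TRUE, prob = base_freq),
            collapse = "")
    }, character(1))
    names(seqs) <- genes

    tss <- tibble::tibble(
      gene = genes,
      chrom = "chr1",
      tss = 10000L + (seq_len(n) - 1L) * 5000L,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )

    motif_truth <- tibble::tibble(
      gene = genes, bound = genes %in% bound_set,
      offset = NA_integer_, strand = NA_character_, site = NA_character_
    )
    peaks <- NULL
    if (base::length(bound_set)) {
      peak_rows <- vector("list", base::length(bound_set))
      for (j in seq_along(bound_set)) {
        g <- bound_set[j]
        site_seq <- if (site == "consensus") {
          pwm$consensus
        } else {
          paste(vapply(seq_len(w), function(p) {
            sample(alphabet, 1, prob = pwm$probs[, p])
          }, character(1)), collapse = "")
        }
        strand <- sample(c("+", "-"), 1)
        inserted <- if (strand == "+") site_seq else revcomp(site_seq)
        off <- sample.int(length - w + 1L, 1)
        s <- seqs[[g]]
        seqs[[g]] <- paste0(substr(s, 1, off - 1L), inserted,
                            substr(s, off + w, length))
        i <- match(g, genes)
        motif_truth$offset[i] <- off
        motif_truth$strand[i] <- strand
        motif_truth$site[i] <- site_seq

        # peak midpoint relative to the TSS, then to genome coordinates
        mid_off <- sample(seq(peak_window[1] + peak_halfwidth,
                              peak_window[2], by = 1L), 1)
        g_strand <- tss$strand[i]
        mid <- if (g_strand == "+") tss$tss[i] + mid_off else tss$tss[i] - mid_off
        peak_rows[[j]] <- tibble::tibble(
          chrom = tss$chrom[i],
          start = as.integer(mid - peak_halfwidth),  # 0-based half-open
          end = as.integer(mid + peak_halfwidth),
          tf = tf, gene = g, score = 0, strand = g_strand
        )
      }
      peaks <- dplyr::bind_rows(peak_rows)
    } else {
      peaks <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        tf = character(), gene = character(), score = numeric(),
        strand = character()
      )
    }

    list(
      promoters = tibble::tibble(gene = genes, sequence = unname(seqs)),
      tss = tss,
      peaks = peaks,
      truth = new_synthetic_truth(motifs = motif_truth, seed = seed)
    )
  })
}

#' Simulate a gene-to-term annotation table with one planted enriched term
#'
#' Background terms annotate every gene independently at `background_rate`.
#' The planted term annotates a fixed fraction of a target gene set and the
#' background rate elsewhere, so hypergeometric enrichment of the target
#' set should single it out.
#'
#' @param genes Gene universe.
#' @param n_terms Number of background terms.
#' @param target_genes Genes the planted term is enriched in (may be empty
#'   to plant nothing).
#' @param planted_fraction Fraction of `target_genes` annotated by the
#'   planted term.
#' @param background_rate Per-gene annotation probability elsewhere.
#' @param enriched_term Label of the planted term.
#' @param seed Integer seed.
#' @return A list: `annotations` (tibble term, gene) and `truth`.
#' @export
simulate_annotations <- function(genes, n_terms = 20,
                                 target_genes = character(),
                                 planted_fraction = 0.5,
                                 background_rate = 0.05,
                                 enriched_term = "T_planted", seed = 1) {
  if (planted_fraction < 0 || planted_fraction > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (!all(target_genes %in% genes)) {
    stop("`target_genes` must be a subset of `genes`", call. = FALSE)
  }
  n <- length(genes)
  with_seed(seed, {
    rows <- list()
    if (n_terms > 0) {
      for (t in seq_len(n_terms)) {
        hit <- genes[runif(n) < background_rate]
        if (length(hit)) {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(term = sprintf("T%03d", t), gene = hit)
        }
      }
    }
    planted <- character()
    if (length(target_genes)) {
      n_hit <- round(planted_fraction * length(target_genes))
      planted <- sample(target_genes, n_hit)
      others <- setdiff(genes, target_genes)
      bg_hit <- others[runif(length(others)) < background_rate]
      hit <- c(planted, bg_hit)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(term = enriched_term, gene = hit)
      }
    }
    ann <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(term = character(), gene = character())
    list(
      annotations = ann,
      truth = new_synthetic_truth(
        terms = tibble::tibble(
          term = if (length(target_genes)) enriched_term else character(),
          n_target = if (length(target_genes)) length(target_genes) else integer(),
          n_planted = if (length(target_genes)) length(planted) else integer()
        ),
        seed = seed
      )
    )
  })
}

#' Simulate phenology (E-L stage) time series per soil and replicate
#'
#' Each replicate follows a monotone template developmental curve; soils
#' may be shifted in time (days) to emulate soil-driven advances or delays.
#' Gaussian noise is added and curves are re-monotonised by a running
#' maximum, as phenological staging cannot regress.
#'
#' @param design Sample design; only its soil levels and replicate count
#'   are used.
#' @param soil_offset Per-soil shift in days: a named vector keyed by soil
#'   level (missing soils get 0), or a single unnamed number applied to the
#'   first soil level.
#' @param noise_sd Noise sd in E-L units.
#' @param seed Integer seed.
#' @param dates Observation days.
#' @param template Function mapping day to E-L value; default a logistic
#'   rise from ~5 to ~38 over the season.
#' @return A tibble: series_id, soil, replicate, date, el.
#' @export
simulate_phenology <- function(design, soil_offset = 0, noise_sd = 0.5,
                               seed = 1, dates = seq(0, 140, by = 7),
                               template = NULL) {
  template <- template %||% function(t) 5 + 33 / (1 + exp(-(t - 70) / 20))
  if (any(diff(template(dates)) < 0)) {
    stop("`template` must be non-decreasing over `dates`", call. = FALSE)
  }
  soils <- levels(design$soil)
  offsets <- setNames(rep(0, length(soils)), soils)
  if (is.null(names(soil_offset))) {
    if (length(soil_offset) != 1L) {
      stop("unnamed `soil_offset` must be a single number", call. = FALSE)
    }
    offsets[1L] <- soil_offset
  } else {
    bad <- setdiff(names(soil_offset), soils)
    if (length(bad)) stop("unknown soil(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    offsets[names(soil_offset)] <- soil_offset
  }
  reps <- sort(unique(design$replicate))
  with_seed(seed, {
    grid <- tidyr::expand_grid(soil = soils, replicate = reps)
    out <- purrr::pmap(grid, function(soil, replicate) {
      el <- template(dates - offsets[[soil]]) + rnorm(length(dates), 0, noise_sd)
      tibble::tibble(
        series_id = paste0(soil, ".r", replicate),
        soil = soil, replicate = replicate, date = dates,
        el = cummax(el)
      )
    })
    dplyr::bind_rows(out)
  })
}

# reverse complement of an ACGTN string
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
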