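#' Position weight matrix with log-odds scores
#'
#' Builds a PWM from per-position base probabilities (or counts, which are
#' normalized after adding `pseudocount`). Scores are log2 odds against a
#' stated background; `N` bases contribute the background-expected score
#' of 0 during scanning.
#'
#' @param x Numeric 4 x width matrix with rownames A/C/G/T: probabilities
#'   or counts per position.
#' @param background Background base probabilities (named A/C/G/T).
#' @param pseudocount Added to counts before normalization.
#' @param name Motif label.
#' @return An object of class `pwm` with `probs`, `log_odds`, `width`,
#'   `consensus`, `background`.
#' @export
#' @examples
#' consensus_pwm("GGTAGGTG")
make_pwm <- function(x, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                     pseudocount = 0.01, name = "motif") {
  x <- as.matrix(x)
  if (nrow(x) != 4L) stop("PWM must have 4 rows (A, C, G, T)", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- c("A", "C", "G", "T")
  x <- x[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(x) < 1L) stop("PWM width must be >= 1", call. = FALSE)
  if (any(x < 0) || any(!is.finite(x))) {
    stop("PWM entries must be finite and non-negative", call. = FALSE)
  }
  colsums <- colSums(x)
  probs <- if (all(abs(colsums - 1) < 1e-6)) {
    x
  } else {
    sweep(x + pseudocount, 2, colsums + 4 * pseudocount, "/")
  }
  background <- background[c("A", "C", "G", "T")]
  background <- background / sum(background)
  log_odds <- log2(probs / background)
  consensus <- paste(rownames(probs)[apply(probs, 2, which.max)],
                     collapse = "")
  structure(
    list(probs = probs, log_odds = log_odds, width = ncol(probs),
         consensus = consensus, background = background, name = name),
    class = "pwm"
  )
}

#' @rdname make_pwm
#' @param sequence Consensus string over ACGT.
#' @param strength Probability of the consensus base at each position
#'   (remainder spread evenly over the other three bases).
#' @export
consensus_pwm <- function(sequence, strength = 0.91,
                          background = c(A = 0.25, C = 0.25,
                                         G = 0.25, T = 0.25),
                          name = sequence) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("consensus must be over ACGT", call. = FALSE)
  }
  probs <- vapply(bases, function(b) {
    p <- rep((1 - strength) / 3, 4)
    names(p) <- c("A", "C", "G", "T")
    p[b] <- strength
    p
  }, numeric(4))
  make_pwm(probs, background = background, name = name)
}

#' @rdname make_pwm
#' @param width Motif width for a random decoy PWM.
#' @param seed Integer seed.
#' @export
random_pwm <- function(width, seed = 1, strength = 0.85,
                       name = paste0("decoy_w", width, "_s", seed)) {
  with_seed(seed, {
    consensus <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                       collapse = "")
    consensus_pwm(consensus, strength = strength, name = name)
  })
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": width ", x$width, ", consensus ", x$consensus,
      "\n", sep = "")
  invisible(x)
}

# reverse-complemented pwm (scanning the minus strand of the sequence)
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)),
                     drop = FALSE]
  rownames(probs) <- c("A", "C", "G", "T")
  out <- pwm
  out$probs <- probs
  out$log_odds <- log2(probs / pwm$background)
  out$consensus <- paste(rownames(probs)[apply(probs, 2, which.max)],
                         collapse = "")
  out
}

encode_sequence <- function(seq) {
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- unname(codes[chars])
  code[is.na(code)] <- 0L  # N and friends
  code
}

# log-odds scores for all windows of an encoded sequence; code 0 scores 0
scan_scores <- function(code, log_odds) {
  w <- ncol(log_odds)
  n <- length(code) - w + 1L
  lo <- unname(rbind(0, log_odds))  # row 1 is the N row
  scores <- numeric(n)
  for (j in seq_len(w)) {
    scores <- scores + lo[code[j:(j + n - 1L)] + 1L, j]
  }
  scores
}

#' Best PWM score in a promoter
#'
#' Scans every window on both strands of a promoter sequence with a PWM
#' and records the best log2-odds score together with its offset (1-based
#' start on the given sequence) and strand. Recording the best score,
#' rather than thresholding hits, avoids an arbitrary binding cutoff and
#' yields one number per promoter for downstream group testing.
#' `N` positions contribute the background-expected score (0). Ties go to
#' the forward strand, then the smallest offset.
#'
#' @param sequence A single ACGT(N) string, at least as long as the PWM.
#' @param pwm A [make_pwm()] object.
#' @return A one-row tibble: score, offset, strand.
#' @export
pwm_best_score <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  code <- encode_sequence(sequence)
  if (length(code) < pwm$width) {
    stop("sequence shorter than the PWM", call. = FALSE)
  }
  fwd <- scan_scores(code, pwm$log_odds)
  rev <- scan_scores(code, pwm_revcomp(pwm)$log_odds)
  best_f <- which.max(fwd)
  best_r <- which.max(rev)
  if (fwd[best_f] >= rev[best_r]) {
    tibble::tibble(score = fwd[best_f], offset = as.integer(best_f),
                   strand = "+")
  } else {
    tibble::tibble(score = rev[best_r], offset = as.integer(best_r),
                   strand = "-")
  }
}

#' Best-score matrix for a promoter set against a PWM panel
#'
#' @param promoters Tibble (gene, sequence) as from [simulate_promoters()],
#'   or a named character vector.
#' @param pwms List of [make_pwm()] objects (names become columns).
#' @return Numeric matrix, promoters x motifs, of best log2-odds scores.
#' @export
pwm_score_matrix <- function(promoters, pwms) {
  if (is.character(promoters)) {
    promoters <- tibble::tibble(gene = names(promoters),
                                sequence = unname(promoters))
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  nm <- names(pwms) %||% vapply(pwms, `[[`, character(1), "name")
  lens <- nchar(promoters$sequence)
  if (length(unique(lens)) == 1L && nrow(promoters) > 1L) {
    # equal-length fast path: scan all promoters as one code matrix
    code <- do.call(rbind, lapply(promoters$sequence, encode_sequence))
    L <- ncol(code)
    out <- vapply(seq_along(pwms), function(j) {
      best <- rep(-Inf, nrow(code))
      for (lo in list(pwms[[j]]$log_odds, pwm_revcomp(pwms[[j]])$log_odds)) {
        w <- ncol(lo)
        n_off <- L - w + 1L
        s <- matrix(0, nrow(code), n_off)
        for (p in seq_len(w)) {
          vals <- c(0, lo[, p])  # leading 0 is the N score
          s <- s + matrix(vals[code[, p:(p + n_off - 1L), drop = FALSE] + 1L],
                          nrow(code), n_off)
        }
        best <- pmax(best, do.call(pmax, asplit(s, 2)))
      }
      best
    }, numeric(nrow(promoters)))
    out <- rbind(out)
  } else {
    codes <- lapply(promoters$sequence, encode_sequence)
    out <- vapply(seq_along(pwms), function(j) {
      lo_f <- pwms[[j]]$log_odds
      lo_r <- pwm_revcomp(pwms[[j]])$log_odds
      vapply(codes, function(code) {
        max(max(scan_scores(code, lo_f)), max(scan_scores(code, lo_r)))
      }, numeric(1))
    }, numeric(nrow(promoters)))
    out <- rbind(out)
  }
  dimnames(out) <- list(promoters$gene, nm)
  out
}

#' Hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the overlap between the study set and the term's annotated
#' genes, given the universe; BH-adjusted across terms. Fold enrichment is
#' observed overlap over the expected `study * term / universe`.
#'
#' @param study Character vector of study genes (subset of the universe).
#' @param annotations Tibble (term, gene).
#' @param universe Character vector of background genes.
#' @return A tibble: term, n_term, overlap, expected, fold_enrichment,
#'   p_value, fdr; ordered by p.
#' @export
hypergeom_enrich <- function(study, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  study <- unique(study)
  if (!all(study %in% universe)) {
    stop("study set must be contained in the universe", call. = FALSE)
  }
  ann <- annotations |>
    dplyr::filter(.data$gene %in% universe) |>
    dplyr::distinct(.data$term, .data$gene)
  n_u <- length(universe)
  n_s <- length(study)
  res <- ann |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      n_term = dplyr::n(),
      overlap = sum(.data$gene %in% study),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      expected = n_s * .data$n_term / n_u,
      fold_enrichment = ifelse(.data$expected > 0,
                               .data$overlap / .data$expected, 0),
      p_value = phyper(.data$overlap - 1, .data$n_term, n_u - .data$n_term,
                       n_s, lower.tail = FALSE),
      fdr = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::arrange(.data$p_value)
  res
}

#' Group-vs-rest test on promoter best scores
#'
#' For each motif, compares the best promoter scores of a gene group
#' against all remaining genes with a two-sample t-test (Welch by
#' default), then BH-adjusts across motifs. A motif whose sites are
#' planted (or biologically enriched) in the group shifts the group's
#' best-score distribution upward.
#'
#' @param scores Promoter x motif score matrix from [pwm_score_matrix()].
#' @param group Logical vector along rows, or character vector of row
#'   names, marking the gene group.
#' @param alternative,var_equal Passed to the t-test; Welch two-sided by
#'   default.
#' @return A tibble: motif, mean_group, mean_rest, statistic, p_value,
#'   fdr; ordered by p.
#' @export
motif_group_test <- function(scores, group, alternative = "two.sided",
                             var_equal = FALSE) {
  scores <- rbind(scores)
  if (is.character(group)) group <- rownames(scores) %in% group
  stopifnot(is.logical(group), length(group) == nrow(scores))
  if (!any(group)) stop("empty group", call. = FALSE)
  if (all(group)) stop("group equals the universe; nothing to compare",
                       call. = FALSE)
  res <- purrr::map_dfr(colnames(scores) %||%
                          as.character(seq_len(ncol(scores))),
                        function(motif) {
    x <- scores[group, motif]
    y <- scores[!group, motif]
    tt <- tryCatch(
      stats::t.test(x, y, alternative = alternative, var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(tt)) {
      # degenerate data (constant groups): equal means carry no evidence,
      # distinct constant means are infinitely strong evidence
      stat <- if (isTRUE(all.equal(mean(x), mean(y)))) 0 else
        Inf * sign(mean(x) - mean(y))
      p <- if (stat == 0) 1 else 0
    } else {
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    tibble::tibble(motif = motif, mean_group = mean(x), mean_rest = mean(y),
                   statistic = stat, p_value = p)
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, .data$p_value)
}

#' Filter TF peaks to an upstream TSS window
#'
#' Keeps, per TF, the genes having at least one peak whose midpoint falls
#' in the window relative to the gene's TSS (strand-aware: upstream is
#' negative). Midpoints, not endpoints, anchor the decision so peak width
#' does not change the call. Also reports overlap counts for every TF
#' combination (the Venn counts).
#'
#' @param peaks Tibble with columns chrom, start, end (0-based half-open),
#'   tf, gene.
#' @param tss Tibble (gene, chrom, tss, strand).
#' @param window Closed interval relative to the TSS, default c(-2000, 0).
#' @return An object of class `window_filter`: `report` (peaks with offset
#'   and retained flag), `genes_by_tf` (named list), `overlaps` (per
#'   TF-combination gene counts).
#' @export
promoter_window_filter <- function(peaks, tss, window = c(-2000, 0)) {
  missing <- setdiff(peaks$gene, tss$gene)
  if (length(missing)) {
    stop("peak gene(s) absent from the TSS table: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(tss$strand %in% c("+", "-"))) {
    stop("unknown strand in TSS table (must be + or -)", call. = FALSE)
  }
  report <- peaks |>
    dplyr::left_join(dplyr::select(tss, "gene", tss_pos = "tss",
                                   gene_strand = "strand"),
                     by = "gene") |>
    dplyr::mutate(
      midpoint = (.data$start + .data$end) / 2,
      offset = ifelse(.data$gene_strand == "+",
                      .data$midpoint - .data$tss_pos,
                      .data$tss_pos - .data$midpoint),
      retained = .data$offset >= window[1] & .data$offset <= window[2]
    )
  retained <- dplyr::filter(report, .data$retained)
  tfs <- sort(unique(peaks$tf))
  genes_by_tf <- setNames(lapply(tfs, function(f) {
    sort(unique(retained$gene[retained$tf == f]))
  }), tfs)
  overlaps <- if (length(tfs)) {
    deg_intersections(genes_by_tf)$counts
  } else {
    tibble::tibble(category = character(), n_genes = integer())
  }
  structure(
    list(report = report, genes_by_tf = genes_by_tf, overlaps = overlaps,
         window = window),
    class = "window_filter"
  )
}

#' @export
print.window_filter <- function(x, ...) {
  cat("<window_filter> window [", x$window[1], ", ", x$window[2], "]: ",
      sum(x$report$retained), "/", nrow(x$report), " peaks retained\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.window_filter <- function(x, ...) x$report
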