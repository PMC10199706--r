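#' TMM (trimmed mean of M-values) normalization factors
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' per-gene log2 expression ratios (M-values) against a reference sample,
#' the standard between-sample normalization for count data. For sample s
#' with library size \eqn{N_s} and reference r, genes with positive counts
#' in both samples contribute a log-ratio, a log-abundance and a
#' delta-method variance
#' \deqn{M_g = \log_2\frac{y_{gs}/N_s}{y_{gr}/N_r},\quad
#'       A_g = \tfrac12 \log_2\frac{y_{gs}}{N_s}\frac{y_{gr}}{N_r},\quad
#'       v_g = \frac{N_s - y_{gs}}{N_s y_{gs}} + \frac{N_r - y_{gr}}{N_r y_{gr}}}
#' The factor is the inverse-variance weighted mean
#' \eqn{2^{\sum (M_g/v_g) / \sum (1/v_g)}} over genes surviving a
#' two-sided trim of `trim_m` on M and `trim_a` on A. The reference is the
#' sample whose 75th-percentile CPM is closest to the mean of those
#' percentiles, and factors are rescaled to geometric mean 1.
#'
#' @param counts A [count_matrix()].
#' @param trim_m Two-sided trim fraction on M-values.
#' @param trim_a Two-sided trim fraction on A-values (log abundance).
#' @return A tibble (sample_id, norm_factor) of class `norm_factors`, with
#'   attributes `ref_sample`, `trim_m`, `trim_a`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  assert_count_matrix(counts)
  x <- counts$counts
  if (ncol(x) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[lib == 0], collapse = ", "), call. = FALSE)
  }
  f75 <- apply(x, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(x)), function(s) {
    tmm_pair_factor(x[, s], x[, ref], lib[s], lib[ref], trim_m, trim_a)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))

  out <- tibble::tibble(sample_id = colnames(x), norm_factor = factors)
  attr(out, "ref_sample") <- colnames(x)[ref]
  attr(out, "trim_m") <- trim_m
  attr(out, "trim_a") <- trim_a
  class(out) <- c("norm_factors", class(out))
  out
}

# single-pair Robinson-Oshlack factor (unscaled)
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]
  ref <- ref[keep0]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- 2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  if (!is.finite(f)) 1 else f
}

new_expression_matrix <- function(values, design, transform,
                                  factors = NULL, params = list()) {
  structure(
    list(values = values, design = design, transform = transform,
         factors = factors, params = params),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples; transform: ", x$transform, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Counts per million on TMM-effective library sizes
#'
#' @param counts A [count_matrix()].
#' @param factors Normalization factors from [tmm_factors()]; `NULL` means
#'   unit factors (raw library-size CPM).
#' @return An `expression_matrix` on the CPM scale.
#' @export
cpm <- function(counts, factors = NULL) {
  assert_count_matrix(counts)
  x <- counts$counts
  lib <- colSums(x)
  f <- rep(1, ncol(x))
  if (!is.null(factors)) {
    idx <- match(colnames(x), factors$sample_id)
    if (anyNA(idx)) stop("factors do not cover all samples", call. = FALSE)
    f <- factors$norm_factor[idx]
  }
  vals <- sweep(x, 2, lib * f, "/") * 1e6
  new_expression_matrix(vals, counts$design, "cpm", factors)
}

#' Variance-stabilizing transform of normalized counts
#'
#' Realized as `log2(CPM + prior)` on TMM-effective library sizes: a
#' deterministic transform whose contract is that replicate variance
#' becomes approximately independent of the mean (the log-log slope of
#' replicate variance against mean drops from ~2 for raw counts to ~0).
#'
#' @inheritParams cpm
#' @param prior Positive pseudo-CPM added before the log.
#' @return An `expression_matrix` on the VST scale; the normalization
#'   factors used are carried in the object for downstream CPM screening.
#' @export
vst <- function(counts, factors = NULL, prior = 0.5) {
  if (!is.numeric(prior) || prior <= 0) {
    stop("`prior` must be > 0", call. = FALSE)
  }
  cp <- cpm(counts, factors)
  new_expression_matrix(log2(cp$values + prior), counts$design,
                        "vst_log2_cpm", factors, params = list(prior = prior))
}
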