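#' Screen genes with inadequate expression profiles
#'
#' Step 1 of the three-step pipeline: before clustering, discard genes
#' whose profiles carry no usable condition signal. Three mutually
#' exclusive classes are flagged, in a fixed order:
#'
#' * **unexpressed** — CPM below `cpm_floor` in all but fewer than
#'   `min_expressed_samples` samples;
#' * **constitutive** — expressed, but the coefficient of variation of the
#'   per-condition mean profile (on the VST scale) is below `cv_floor`:
#'   the gene is flat across all conditions. Condition means, not raw
#'   samples, are tested so replicate noise cannot rescue a flat gene;
#' * **outlier** — expressed and non-constitutive, but its profile is
#'   driven by at most `outlier_max_samples` single-sample spikes with
#'   median/MAD robust z above `outlier_z` (group effects touch more
#'   samples and are retained).
#'
#' All thresholds are recorded in the report; the paper-scale split of a
#' real dataset depends on thresholds chosen there, so reproducibility here
#' means reproducibility of the decision rule, not of any fixed split.
#'
#' @param expr VST `expression_matrix` (from [vst()]); its stored
#'   normalization factors are reused for the CPM floor.
#' @param counts The matching [count_matrix()].
#' @param cpm_floor CPM threshold defining "expressed" in a sample.
#' @param min_expressed_samples Minimum samples at or above the floor.
#' @param cv_floor Coefficient-of-variation floor on condition means.
#' @param outlier_z Robust z threshold for a spike.
#' @param outlier_max_samples Maximum spiking samples for the outlier call.
#' @return An object of class `screen_result`: `report` (tibble gene,
#'   status, metrics), `thresholds`, and `retained` (the filtered
#'   `expression_matrix`). `tidy()` returns the report, `glance()` the
#'   status tally.
#' @export
screen_genes <- function(expr, counts, cpm_floor = 1.0,
                         min_expressed_samples = 3, cv_floor = 0.05,
                         outlier_z = 6.0, outlier_max_samples = 2) {
  assert_expression_matrix(expr)
  assert_count_matrix(counts)
  if (!identical(dimnames(expr$values), dimnames(counts$counts))) {
    stop("`expr` and `counts` must be aligned (same genes and samples)",
         call. = FALSE)
  }
  thr <- c(cpm_floor = cpm_floor,
           min_expressed_samples = min_expressed_samples,
           cv_floor = cv_floor, outlier_z = outlier_z,
           outlier_max_samples = outlier_max_samples)
  if (any(thr < 0)) stop("thresholds must be non-negative", call. = FALSE)

  cpm_vals <- cpm(counts, expr$factors)$values
  v <- expr$values
  design <- expr$design

  n_expressed <- rowSums(cpm_vals >= cpm_floor)
  unexpressed <- n_expressed < min_expressed_samples

  cond_means <- condition_means(expr)$profiles
  cv <- apply(cond_means, 1, function(x) {
    m <- mean(x)
    if (abs(m) < .Machine$double.eps) Inf else sd(x) / abs(m)
  })

  z_stats <- t(apply(v, 1, function(x) {
    med <- median(x)
    s <- mad(x)
    if (s == 0) {
      z <- ifelse(x == med, 0, Inf)
    } else {
      z <- abs(x - med) / s
    }
    c(max_z = max(z), n_spikes = sum(z > outlier_z))
  }))
  n_spikes <- z_stats[, "n_spikes"]

  # a spike-bearing gene is not constitutively expressed, however flat its
  # condition means look after the VST compresses the spike
  constitutive <- !unexpressed & cv < cv_floor & n_spikes == 0L
  outlier <- !unexpressed & !constitutive &
    n_spikes >= 1L & n_spikes <= outlier_max_samples

  status <- rep("retained", nrow(v))
  status[outlier] <- "outlier"
  status[constitutive] <- "constitutive"
  status[unexpressed] <- "unexpressed"

  report <- tibble::tibble(
    gene = rownames(v),
    status = factor(status,
                    levels = c("retained", "unexpressed", "constitutive",
                               "outlier")),
    n_expressed = n_expressed,
    max_cpm = apply(cpm_vals, 1, max),
    profile_cv = cv,
    max_robust_z = z_stats[, "max_z"],
    n_spike_samples = as.integer(z_stats[, "n_spikes"])
  )

  keep <- status == "retained"
  retained <- new_expression_matrix(v[keep, , drop = FALSE], design,
                                    expr$transform, expr$factors, expr$params)
  structure(
    list(report = report, thresholds = thr, retained = retained),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(x$report$status)
  cat("<screen_result> ", nrow(x$report), " genes: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname screen_genes
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) x$report

#' @rdname screen_genes
#' @export
glance.screen_result <- function(x, ...) {
  tab <- table(x$report$status)
  tibble::tibble(
    n_genes = nrow(x$report),
    n_retained = as.integer(tab[["retained"]]),
    n_unexpressed = as.integer(tab[["unexpressed"]]),
    n_constitutive = as.integer(tab[["constitutive"]]),
    n_outlier = as.integer(tab[["outlier"]])
  )
}
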