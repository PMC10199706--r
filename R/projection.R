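# PCA of samples and of cluster average profiles, and the crossing of
# component loadings with cluster importances.

pca_core <- function(x, obs_ids, feature_ids) {
  if (nrow(x) < 2L) stop("PCA needs at least 2 observations", call. = FALSE)
  if (all(apply(x, 2, sd) == 0)) {
    stop("constant matrix: PCA undefined", call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(fit$rotation))) {
    piv <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[piv, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  var_ratio <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x)
  scores <- dplyr::bind_cols(tibble::tibble(.id = obs_ids), scores)
  structure(
    list(scores = scores, loadings = fit$rotation,
         variance_ratio = var_ratio, center = fit$center,
         obs_ids = obs_ids, feature_ids = feature_ids),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", length(x$obs_ids), " observations x ",
      length(x$feature_ids), " features; PC1 ",
      round(100 * x$variance_ratio[1], 1), "% of variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -".id", names_to = "component",
                      values_to = "score")
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$variance_ratio),
    pc1_variance = x$variance_ratio[1],
    pc2_variance = if (length(x$variance_ratio) > 1) x$variance_ratio[2]
                   else NA_real_
  )
}

#' PCA of samples in expression space
#'
#' Samples are observations, genes are (centered, unscaled) features. The
#' sign of each component is fixed by making its largest-magnitude loading
#' positive, so results are fully deterministic. The scores tibble carries
#' the design columns for direct plotting of which factor separates along
#' which component.
#'
#' @param expr An `expression_matrix` (typically VST).
#' @return A `pca_result`; `$scores` has one row per sample with design
#'   columns attached.
#' @export
sample_pca <- function(expr) {
  assert_expression_matrix(expr)
  res <- pca_core(t(expr$values), colnames(expr$values),
                  rownames(expr$values))
  res$scores <- dplyr::left_join(
    dplyr::rename(res$scores, sample_id = ".id"),
    expr$design, by = "sample_id"
  )
  res
}

#' PCA of cluster average profiles
#'
#' Conditions are observations and clusters are features, so component
#' loadings say how strongly each cluster's profile contributes to each
#' axis of condition-space variation.
#'
#' @param clusters A `cluster_set`.
#' @return A `pca_result` with cluster loadings.
#' @export
cluster_profile_pca <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  x <- t(clusters$centroids)  # condition x cluster
  colnames(x) <- paste0("cluster_", seq_len(clusters$k))
  res <- pca_core(x, rownames(x), colnames(x))
  res$scores <- dplyr::rename(res$scores, condition = ".id")
  res
}

#' Associate principal components with design variables via importances
#'
#' Crosses the cluster-profile PCA with the importance table: for each
#' design variable, finds the component whose absolute cluster loadings
#' correlate best (absolute Spearman rho) with the clusters' importance
#' for that variable. A high rho means that component's axis of variation
#' is the one that variable drives.
#'
#' @param pca A `pca_result` from [cluster_profile_pca()].
#' @param vim_table A `vim_table` aligned with the clusters.
#' @return A tibble: variable, component, rho (in \[0, 1\]).
#' @export
associate_components <- function(pca, vim_table) {
  stopifnot(inherits(pca, "pca_result"))
  k <- nrow(vim_table)
  if (k < 3L) stop("need at least 3 clusters to correlate", call. = FALSE)
  if (nrow(pca$loadings) != k) {
    stop("loadings and vim_table describe different cluster sets",
         call. = FALSE)
  }
  # align loading rows to vim_table cluster order
  ord <- match(paste0("cluster_", vim_table$cluster), rownames(pca$loadings))
  if (anyNA(ord)) ord <- seq_len(k)
  load_abs <- abs(pca$loadings[ord, , drop = FALSE])
  vim_cols <- grep("^vim_", names(vim_table), value = TRUE)
  purrr::map_dfr(vim_cols, function(col) {
    rho <- apply(load_abs, 2, function(l) {
      suppressWarnings(cor(l, vim_table[[col]], method = "spearman"))
    })
    rho[is.na(rho)] <- 0
    best <- which.max(abs(rho))
    tibble::tibble(
      variable = sub("^vim_", "", col),
      component = colnames(load_abs)[best],
      rho = unname(abs(rho[best]))
    )
  })
}
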