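#' Run the full three-step pipeline on a count matrix
#'
#' Convenience wrapper chaining the whole analysis: TMM normalization and
#' VST, screening of inadequate profiles, condition-profile clustering
#' (k chosen by the variance-explained target unless given), per-gene
#' boosting importances summarised per cluster, top-k rank intersections,
#' and the cluster-profile PCA crossed with the importances.
#'
#' @param counts A [count_matrix()].
#' @param k Number of clusters; `NULL` selects k via [choose_k()].
#' @param k_grid Grid for [choose_k()] when `k` is `NULL`.
#' @param target_variance Variance-explained target for k selection.
#' @param k_top Top-set size for the rank intersections (capped at the
#'   number of clusters).
#' @param n_trees,depth,learning_rate,subsample Boosting hyperparameters
#'   (see [fit_gbm()]).
#' @param seed Integer seed for every stochastic stage.
#' @return A list with every intermediate: factors, expr, screen,
#'   profiles, clusters, gene_vims, vim_table, topk, sample_pca,
#'   cluster_pca, associations.
#' @export
run_pipeline <- function(counts, k = NULL, k_grid = c(2, 5, 10, 20, 50),
                         target_variance = 0.80, k_top = 30, n_trees = 500,
                         depth = 3, learning_rate = 0.05, subsample = 0.8,
                         seed = 1) {
  assert_count_matrix(counts)
  factors <- tmm_factors(counts)
  expr <- vst(counts, factors)
  screen <- screen_genes(expr, counts)
  profiles <- standardize_profiles(condition_means(screen$retained))
  if (is.null(k)) {
    k <- choose_k(profiles, target_variance = target_variance,
                  k_grid = k_grid, seed = derive_seed(seed, 1),
                  standardize = FALSE)
  }
  clusters <- kmeans_clusters(profiles, k = as.integer(k),
                              seed = derive_seed(seed, 2),
                              standardize = FALSE)
  gv <- gene_vims(screen$retained, n_trees = n_trees, depth = depth,
                  learning_rate = learning_rate, subsample = subsample,
                  seed = derive_seed(seed, 3))
  vim_table <- cluster_vims(gv, clusters)
  topk <- top_k_intersections(vim_table,
                              k_top = min(k_top, nrow(vim_table)))
  cluster_pca <- cluster_profile_pca(clusters)
  list(
    factors = factors,
    expr = expr,
    screen = screen,
    profiles = profiles,
    clusters = clusters,
    gene_vims = gv,
    vim_table = vim_table,
    topk = topk,
    sample_pca = sample_pca(expr),
    cluster_pca = cluster_pca,
    associations = if (nrow(vim_table) >= 3)
      associate_components(cluster_pca, vim_table) else NULL,
    seed = seed
  )
}
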