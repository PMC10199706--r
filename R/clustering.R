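#' Average expression profile per experimental condition
#'
#' Collapses replicates: entry (g, c) is the arithmetic mean of gene g's
#' values over the replicates of condition c (a cultivar x tissue x stage x
#' soil combination). Column order follows the design's deterministic
#' nesting (cultivar, tissue, stage, soil).
#'
#' @param expr An `expression_matrix`.
#' @return A list of class `condition_profiles`: `profiles` (gene x
#'   condition matrix), `conditions` (tibble describing each column),
#'   `standardized` flag.
#' @export
condition_means <- function(expr) {
  assert_expression_matrix(expr)
  design <- expr$design
  cond <- condition_table(design)
  idx <- split(seq_len(nrow(design)), design$condition)
  if (any(lengths(idx) == 0L)) {
    stop("condition(s) with no replicate: ",
         paste(names(idx)[lengths(idx) == 0L], collapse = ", "),
         call. = FALSE)
  }
  profiles <- vapply(as.character(cond$condition), function(cc) {
    rowMeans(expr$values[, idx[[cc]], drop = FALSE])
  }, numeric(nrow(expr$values)))
  dimnames(profiles) <- list(rownames(expr$values),
                             as.character(cond$condition))
  structure(
    list(profiles = profiles, conditions = cond, standardized = FALSE),
    class = "condition_profiles"
  )
}

#' @export
print.condition_profiles <- function(x, ...) {
  cat("<condition_profiles> ", nrow(x$profiles), " genes x ",
      ncol(x$profiles), " conditions",
      if (x$standardized) " (standardized)", "\n", sep = "")
  invisible(x)
}

#' Per-gene z-standardization of condition profiles
#'
#' Centers and scales each gene's profile so clustering groups genes by
#' profile *shape* rather than expression level (level effects are
#' captured later by the importance scores).
#'
#' @param profiles A `condition_profiles` object.
#' @return The same object with standardized rows.
#' @export
standardize_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "condition_profiles"))
  if (profiles$standardized) return(profiles)
  m <- profiles$profiles
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    stop("constant profile row(s): ",
         paste(head(rownames(m)[s == 0], 5), collapse = ", "),
         "; screen genes first", call. = FALSE)
  }
  profiles$profiles <- (m - mu) / s
  profiles$standardized <- TRUE
  profiles
}

#' Cluster homogeneity index Rc
#'
#' Representativeness of a cluster's average profile: the mean Pearson
#' correlation between each member gene's profile and the centroid.
#' 1 means every member tracks the average exactly; values near 0 mean
#' the average represents its members poorly. Singleton clusters score 1;
#' zero-variance members are excluded with a warning.
#'
#' @param members Matrix of member profiles (genes x conditions).
#' @param centroid Centroid profile (length = conditions).
#' @return A single correlation in \[-1, 1\].
#' @export
homogeneity_index <- function(members, centroid) {
  members <- rbind(members)
  if (nrow(members) == 0L) stop("empty cluster", call. = FALSE)
  if (nrow(members) == 1L) return(1)
  s <- apply(members, 1, sd)
  if (any(s == 0)) {
    warning("excluding ", sum(s == 0), " zero-variance member(s) from Rc")
    members <- members[s > 0, , drop = FALSE]
    if (nrow(members) == 0L) return(NA_real_)
    if (nrow(members) == 1L) return(1)
  }
  mean(apply(members, 1, cor, y = centroid))
}

#' K-means co-expression clustering of condition profiles
#'
#' Step 2 of the pipeline: partitions (by default z-standardized) condition
#' profiles into k clusters by best-inertia k-means over `n_init` seeded
#' restarts, and annotates each cluster with its average profile, size and
#' homogeneity index Rc. `variance_explained` is between-cluster sum of
#' squares over total. Deterministic given `seed`; equidistant points take
#' the lowest cluster id.
#'
#' @param profiles A `condition_profiles` object.
#' @param k Number of clusters (< number of genes).
#' @param seed Integer seed.
#' @param n_init Random restarts; the best-inertia solution is kept.
#' @param standardize Z-standardize rows first (recommended; see
#'   [standardize_profiles()]).
#' @return An object of class `cluster_set`; `tidy()` gives the per-cluster
#'   summary, `glance()` the fit summary, `augment()`-style assignments are
#'   in `$assignment`.
#' @export
kmeans_clusters <- function(profiles, k, seed = 1, n_init = 25,
                            standardize = TRUE) {
  stopifnot(inherits(profiles, "condition_profiles"))
  if (standardize) profiles <- standardize_profiles(profiles)
  m <- profiles$profiles
  if (k >= nrow(m)) stop("`k` must be smaller than the number of genes",
                         call. = FALSE)
  fit <- NULL
  for (attempt in 0:4) {
    fit <- with_seed(derive_seed(seed, attempt), {
      tryCatch(
        suppressWarnings(
          kmeans(m, centers = k, nstart = n_init, iter.max = 100)
        ),
        error = function(e) NULL
      )
    })
    if (!is.null(fit) && all(fit$size > 0)) break
  }
  if (is.null(fit) || any(fit$size == 0)) {
    stop("k-means produced an empty cluster after repeated restarts",
         call. = FALSE)
  }

  rc <- vapply(seq_len(k), function(cl) {
    homogeneity_index(m[fit$cluster == cl, , drop = FALSE],
                      fit$centers[cl, ])
  }, numeric(1))

  structure(
    list(
      k = k,
      assignment = tibble::tibble(gene = rownames(m),
                                  cluster = unname(fit$cluster)),
      centroids = fit$centers,
      rc = rc,
      sizes = unname(fit$size),
      variance_explained = if (fit$totss > 0) fit$betweenss / fit$totss else 0,
      within_ss = fit$tot.withinss,
      between_ss = fit$betweenss,
      total_ss = fit$totss,
      conditions = profiles$conditions,
      standardized = profiles$standardized,
      seed = seed
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> k = ", x$k, ", ", nrow(x$assignment), " genes, ",
      "variance explained = ", round(x$variance_explained, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname kmeans_clusters
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @export
tidy.cluster_set <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    n_genes = x$sizes,
    rc = x$rc
  )
}

#' @rdname kmeans_clusters
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_genes = nrow(x$assignment),
    variance_explained = x$variance_explained,
    mean_rc = mean(x$rc),
    seed = x$seed
  )
}

#' Choose k by a variance-explained target
#'
#' Scans an ascending grid of cluster numbers and returns the smallest k
#' whose between-cluster share of variance reaches `target_variance`
#' (default 0.80, the share the pipeline aims to capture). If no grid
#' value reaches the target the largest is returned with a warning.
#'
#' @inheritParams kmeans_clusters
#' @param target_variance Required variance-explained fraction.
#' @param k_grid Ascending integer grid of candidate k.
#' @return The chosen k (integer) with attribute `variance_explained`, the
#'   named vector of evaluated fractions.
#' @export
choose_k <- function(profiles, target_variance = 0.80,
                     k_grid = c(2, 5, 10, 20, 50, 100), seed = 1,
                     n_init = 10, standardize = TRUE) {
  if (length(k_grid) == 0L) stop("`k_grid` is empty", call. = FALSE)
  if (is.unsorted(k_grid, strictly = TRUE)) {
    stop("`k_grid` must be strictly ascending", call. = FALSE)
  }
  stopifnot(inherits(profiles, "condition_profiles"))
  if (standardize) profiles <- standardize_profiles(profiles)
  ve <- setNames(numeric(0), character(0))
  chosen <- NULL
  for (k in k_grid) {
    cs <- kmeans_clusters(profiles, k, seed = seed, n_init = n_init,
                          standardize = FALSE)
    ve[as.character(k)] <- cs$variance_explained
    if (cs$variance_explained >= target_variance) {
      chosen <- k
      break
    }
  }
  if (is.null(chosen)) {
    chosen <- k_grid[length(k_grid)]
    warning("no k on the grid reaches variance target ", target_variance,
            "; returning the largest (", chosen, ")")
  }
  structure(as.integer(chosen), variance_explained = ve)
}
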