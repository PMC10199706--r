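# Step 3: gradient-boosting variable-importance scoring.

vim_vars <- function() c("stage", "cultivar", "tissue", "soil")

encode_design <- function(design, vars = vim_vars()) {
  X <- vapply(vars, function(v) as.integer(design[[v]]) - 1L,
              integer(nrow(design)))
  nlev <- vapply(vars, function(v) length(levels(design[[v]])), integer(1))
  list(X = X, nlev = nlev, vars = vars,
       levels = lapply(design[vars], levels))
}

#' Fit a gradient-boosting model of one expression profile on the design
#'
#' Boosted depth-limited regression trees (squared-error loss) of a single
#' gene's expression on the four categorical design variables. Variable
#' importance per factor is the relative-influence definition: the total
#' squared-error reduction of all splits on that factor, summed over trees.
#' Boosting discovers interactions among factors without specifying them a
#' priori; [interaction_strength()] quantifies them pairwise.
#'
#' @param y Numeric response (one gene's expression across samples).
#' @param design Sample design aligned with `y`.
#' @param n_trees,depth,learning_rate,subsample,min_node Boosting
#'   hyperparameters: number of trees, maximum tree depth, shrinkage,
#'   per-tree row subsampling fraction, minimum samples per child node.
#' @param seed Integer seed driving the subsampling.
#' @param vars Design variables to use as predictors.
#' @return An object of class `gbm_fit` with `vim` (named importances),
#'   `total_gain` and the fitted forest; supports `predict()`, `tidy()`
#'   and `glance()`.
#' @export
fit_gbm <- function(y, design, n_trees = 500, depth = 3,
                    learning_rate = 0.05, subsample = 0.8, min_node = 10,
                    seed = 1, vars = vim_vars()) {
  stopifnot(length(y) == nrow(design), all(is.finite(y)))
  enc <- encode_design(design, vars)
  if (any(enc$nlev < 2L)) {
    warning("factor(s) with a single level carry no information: ",
            paste(vars[enc$nlev < 2L], collapse = ", "))
  }
  constant <- sd(y) == 0
  fit <- if (constant) {
    list(vim = rep(0, length(vars)), total_gain = 0, init = mean(y),
         trees = list())
  } else {
    .gbm_fit_cpp(y, enc$X, enc$nlev, as.integer(n_trees), as.integer(depth),
                 learning_rate, subsample, as.integer(min_node),
                 as.integer(seed), TRUE)
  }
  structure(
    list(
      vim = setNames(fit$vim, vars),
      total_gain = fit$total_gain,
      init = fit$init,
      trees = fit$trees,
      encoding = enc,
      constant = constant,
      params = list(n_trees = n_trees, depth = depth,
                    learning_rate = learning_rate, subsample = subsample,
                    min_node = min_node, seed = seed)
    ),
    class = "gbm_fit"
  )
}

#' @export
print.gbm_fit <- function(x, ...) {
  cat("<gbm_fit> ", length(x$trees), " trees; VIM: ",
      paste(names(x$vim), round(x$vim, 2), sep = "=", collapse = ", "),
      if (x$constant) " (constant response)", "\n", sep = "")
  invisible(x)
}

#' @export
predict.gbm_fit <- function(object, newdata = NULL, ...) {
  if (object$constant || length(object$trees) == 0L) {
    n <- if (is.null(newdata)) nrow(object$encoding$X) else nrow(newdata)
    return(rep(object$init, n))
  }
  X <- if (is.null(newdata)) {
    object$encoding$X
  } else {
    vapply(object$encoding$vars, function(v) {
      as.integer(factor(as.character(newdata[[v]]),
                        levels = object$encoding$levels[[v]])) - 1L
    }, integer(nrow(newdata)))
  }
  .gbm_predict_cpp(object$trees, object$init,
                   object$params$learning_rate, X)
}

#' @rdname fit_gbm
#' @param x A `gbm_fit`.
#' @param ... Unused.
#' @export
tidy.gbm_fit <- function(x, ...) {
  tot <- sum(x$vim)
  tibble::tibble(
    variable = names(x$vim),
    vim = unname(x$vim),
    relative_influence = if (tot > 0) unname(x$vim) / tot else 0
  )
}

#' @rdname fit_gbm
#' @export
glance.gbm_fit <- function(x, ...) {
  tibble::tibble(
    n_trees = x$params$n_trees, depth = x$params$depth,
    learning_rate = x$params$learning_rate,
    subsample = x$params$subsample, seed = x$params$seed,
    total_gain = x$total_gain, constant = x$constant
  )
}

#' Per-gene variable importances for a whole expression matrix
#'
#' Fits one boosting model per gene (gene g uses child seed `seed + g - 1`
#' so any subset refit reproduces the same scores) and returns the four
#' importances per gene. Constant genes get all-zero importances and are
#' flagged.
#'
#' @param expr An `expression_matrix` (typically the screened VST matrix).
#' @inheritParams fit_gbm
#' @return A tibble: gene, vim_stage, vim_cultivar, vim_tissue, vim_soil,
#'   constant.
#' @export
gene_vims <- function(expr, n_trees = 500, depth = 3, learning_rate = 0.05,
                      subsample = 0.8, min_node = 10, seed = 1,
                      vars = vim_vars()) {
  assert_expression_matrix(expr)
  enc <- encode_design(expr$design, vars)
  v <- expr$values
  vim <- .gbm_vim_matrix_cpp(v, enc$X, enc$nlev, as.integer(n_trees),
                             as.integer(depth), learning_rate, subsample,
                             as.integer(min_node), as.integer(seed))
  colnames(vim) <- paste0("vim_", vars)
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(v)),
    tibble::as_tibble(vim),
    tibble::tibble(constant = apply(v, 1, sd) == 0)
  )
}

#' Median cluster importances and per-variable ranks
#'
#' Summarises per-gene importances to the cluster level by the median over
#' member genes, then ranks clusters per variable (rank 1 = most
#' important); ties break toward the lower cluster id.
#'
#' @param gene_vims Tibble from [gene_vims()].
#' @param clusters A `cluster_set`.
#' @return A `vim_table` tibble: cluster, n_genes, vim_<var> medians and
#'   rnk_vim_<var> ranks (each rank column a permutation of 1..k).
#' @export
cluster_vims <- function(gene_vims, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  joined <- dplyr::inner_join(clusters$assignment, gene_vims, by = "gene")
  missing <- setdiff(clusters$assignment$gene, gene_vims$gene)
  if (length(missing)) {
    stop(length(missing), " clustered gene(s) have no importance scores",
         call. = FALSE)
  }
  vim_cols <- grep("^vim_", names(gene_vims), value = TRUE)
  out <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      dplyr::across(dplyr::all_of(vim_cols), median),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
  if (nrow(out) < clusters$k) {
    stop("cluster(s) without modeled genes", call. = FALSE)
  }
  for (col in vim_cols) {
    out[[sub("^vim_", "rnk_vim_", col)]] <-
      rank(-out[[col]], ties.method = "first")
  }
  class(out) <- c("vim_table", class(out))
  out
}

#' Top-k rank intersections: variable-specific and shared clusters
#'
#' Takes the `k_top` best-ranked clusters per variable and partitions the
#' union of these top sets by exact membership pattern: a cluster in the
#' top set of a single variable is *specific* to it, one in several top
#' sets is *shared* between them.
#'
#' @param vim_table A `vim_table` from [cluster_vims()].
#' @param k_top Size of each per-variable top set (default 30).
#' @return An object of class `topk_intersection`: `top_sets` (named list
#'   of cluster ids), `membership` (per-cluster logicals + category), and
#'   `categories` (category sizes). `tidy()` returns the membership table.
#' @export
top_k_intersections <- function(vim_table, k_top = 30) {
  rnk_cols <- grep("^rnk_vim_", names(vim_table), value = TRUE)
  vars <- sub("^rnk_vim_", "", rnk_cols)
  if (k_top > nrow(vim_table)) {
    stop("`k_top` exceeds the number of clusters", call. = FALSE)
  }
  top_sets <- setNames(lapply(rnk_cols, function(col) {
    vim_table$cluster[vim_table[[col]] <= k_top]
  }), vars)

  union_ids <- sort(unique(unlist(top_sets)))
  member <- vapply(vars, function(v) union_ids %in% top_sets[[v]],
                   logical(length(union_ids)))
  member <- rbind(member)  # guard length-1 union
  category <- apply(member, 1, function(row) paste(vars[row], collapse = "+"))
  membership <- dplyr::bind_cols(
    tibble::tibble(cluster = union_ids),
    tibble::as_tibble(`colnames<-`(member, paste0("in_", vars))),
    tibble::tibble(
      category = category,
      specific = rowSums(member) == 1L
    )
  )
  categories <- membership |>
    dplyr::count(.data$category, name = "n_clusters") |>
    dplyr::arrange(dplyr::desc(.data$n_clusters))
  structure(
    list(k_top = k_top, top_sets = top_sets, membership = membership,
         categories = categories),
    class = "topk_intersection"
  )
}

#' @export
print.topk_intersection <- function(x, ...) {
  cat("<topk_intersection> top-", x$k_top, " sets; union ",
      nrow(x$membership), " clusters in ", nrow(x$categories),
      " categories\n", sep = "")
  print(x$categories)
  invisible(x)
}

#' @rdname top_k_intersections
#' @param x A `topk_intersection`.
#' @param ... Unused.
#' @export
tidy.topk_intersection <- function(x, ...) x$membership

#' Friedman H-statistic for a pair of design variables
#'
#' Interaction strength of a fitted boosting model for variables j and k:
#' the share of the joint partial-dependence variance not explained by the
#' two one-way partial dependences, square-rooted, in \[0, 1\]. Purely
#' additive responses give H near 0.
#'
#' @param fit A `gbm_fit`.
#' @param pair Character vector of two variable names (or `NULL` for all
#'   pairs).
#' @param design The design the model was fitted on.
#' @return A tibble: var1, var2, h_statistic.
#' @export
interaction_strength <- function(fit, design, pair = NULL) {
  stopifnot(inherits(fit, "gbm_fit"))
  if (length(fit$trees) == 0L && !fit$constant) {
    stop("model has no trees; fit it first", call. = FALSE)
  }
  vars <- fit$encoding$vars
  pairs <- if (is.null(pair)) {
    utils::combn(vars, 2, simplify = FALSE)
  } else {
    stopifnot(length(pair) == 2L, all(pair %in% vars))
    list(pair)
  }
  pd1 <- function(v) {
    # partial dependence at each observed level of v, evaluated per row
    levs <- fit$encoding$levels[[v]]
    pd <- vapply(levs, function(a) {
      nd <- design
      nd[[v]] <- factor(a, levels = levs)
      mean(predict(fit, nd))
    }, numeric(1))
    pd - mean(pd[as.integer(design[[v]])])  # center over the data
  }
  purrr::map_dfr(pairs, function(pr) {
    j <- pr[1]; k <- pr[2]
    lj <- fit$encoding$levels[[j]]
    lk <- fit$encoding$levels[[k]]
    if (length(lj) < 2L || length(lk) < 2L || fit$constant) {
      return(tibble::tibble(var1 = j, var2 = k, h_statistic = 0))
    }
    grid <- tidyr::expand_grid(a = lj, b = lk)
    pdjk <- matrix(purrr::map2_dbl(grid$a, grid$b, function(a, b) {
      nd <- design
      nd[[j]] <- factor(a, levels = lj)
      nd[[k]] <- factor(b, levels = lk)
      mean(predict(fit, nd))
    }), nrow = length(lj), byrow = TRUE)
    ja <- as.integer(design[[j]])
    kb <- as.integer(design[[k]])
    f_jk <- pdjk[cbind(ja, kb)]
    f_jk <- f_jk - mean(f_jk)
    f_j <- pd1(j)[ja]
    f_k <- pd1(k)[kb]
    denom <- sum(f_jk^2)
    h2 <- if (denom > 0) sum((f_jk - f_j - f_k)^2) / denom else 0
    tibble::tibble(var1 = j, var2 = k,
                   h_statistic = sqrt(max(0, min(1, h2))))
  })
}
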