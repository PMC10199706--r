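#' Per-stratum one-way soil differential-expression screen
#'
#' Within every cultivar x tissue x stage stratum (12 strata in the
#' default design, 3 soils x 3 replicates each), tests each gene for a
#' soil effect with a one-way fixed-effects F test on variance-stabilized
#' values, and adjusts p-values by Benjamini-Hochberg within the stratum.
#' This is a documented approximation of the count-GLM ANOVA-like screen
#' used on real data: the acceptance surface is calibration (type-I error
#' and power), not numeric identity with a count model.
#'
#' @param expr A VST `expression_matrix`.
#' @param group Factor tested (default `"soil"`).
#' @param strata Variables defining the strata.
#' @param p_threshold,fdr_threshold Flag thresholds for the exploratory
#'   (p < 0.01) and confirmatory (FDR < 0.05) DEG sets.
#' @return A `deg_result` tibble: stratum columns, gene, statistic,
#'   p_value, fdr, deg_p, deg_fdr. Constant genes within a stratum get
#'   statistic 0 and p 1.
#' @export
soil_anova <- function(expr, group = "soil",
                       strata = c("cultivar", "tissue", "stage"),
                       p_threshold = 0.01, fdr_threshold = 0.05) {
  assert_expression_matrix(expr)
  design <- expr$design
  strata_tbl <- dplyr::distinct(design[, strata, drop = FALSE])
  out <- purrr::pmap(strata_tbl, function(...) {
    levels_now <- list(...)
    keep <- rep(TRUE, nrow(design))
    for (v in names(levels_now)) {
      keep <- keep & design[[v]] == levels_now[[v]]
    }
    sub <- design[keep, , drop = FALSE]
    g <- droplevels(sub[[group]])
    if (nlevels(g) < nlevels(design[[group]])) {
      stop("stratum ", paste(unlist(levels_now), collapse = "/"),
           " is missing ", group, " level(s)", call. = FALSE)
    }
    stats_tbl <- anova_f_rows(expr$values[, keep, drop = FALSE], g)
    dplyr::bind_cols(
      tibble::as_tibble(levels_now)[rep(1, nrow(stats_tbl)), ],
      stats_tbl
    )
  })
  res <- dplyr::bind_rows(out) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::mutate(fdr = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      deg_p = .data$p_value < p_threshold,
      deg_fdr = .data$fdr < fdr_threshold
    )
  class(res) <- c("deg_result", class(res))
  attr(res, "group") <- group
  attr(res, "strata") <- strata
  res
}

# vectorized one-way F over the rows of a matrix
anova_f_rows <- function(x, g) {
  g <- droplevels(as.factor(g))
  n <- ncol(x)
  k <- nlevels(g)
  stopifnot(k >= 2L, n > k)
  counts <- as.vector(table(g))
  group_sums <- t(rowsum(t(x), g))          # gene x level
  group_means <- sweep(group_sums, 2, counts, "/")
  grand_mean <- rowMeans(x)
  ssb <- rowSums(sweep(group_means - grand_mean, 2, counts, "*") *
                   (group_means - grand_mean))
  ssw <- rowSums((x - group_means[, as.integer(g), drop = FALSE])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  # constant genes: no variance anywhere -> no evidence
  degenerate <- ssw <= .Machine$double.eps & ssb <= .Machine$double.eps
  f[degenerate] <- 0
  p[degenerate] <- 1
  tibble::tibble(gene = rownames(x), statistic = unname(f),
                 p_value = unname(p))
}

#' @export
glance.deg_result <- function(x, ...) {
  strata <- attr(x, "strata")
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_deg_p = sum(.data$deg_p),
      n_deg_fdr = sum(.data$deg_fdr),
      .groups = "drop"
    )
}

#' Exact intersections of DEG (or any) gene sets
#'
#' Partitions the union of named gene sets by exact membership pattern,
#' the per-intersection counts an UpSet plot displays. A gene is *private*
#' to a set when it belongs to that set only.
#'
#' @param sets Named list of character vectors.
#' @return An object of class `set_intersections`: `membership` (gene x
#'   set logicals + category + private) and `counts` (category sizes).
#' @export
deg_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) {
    empty <- tibble::tibble(gene = character())
    for (nm in names(sets)) empty[[paste0("in_", nm)]] <- logical()
    empty$category <- character()
    empty$private <- logical()
    return(structure(
      list(membership = empty,
           counts = tibble::tibble(category = character(),
                                   n_genes = integer())),
      class = "set_intersections"
    ))
  }
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- rbind(member)
  membership <- dplyr::bind_cols(
    tibble::tibble(gene = universe),
    tibble::as_tibble(`colnames<-`(member, paste0("in_", names(sets)))),
    tibble::tibble(
      category = apply(member, 1, function(row) {
        paste(names(sets)[row], collapse = "+")
      }),
      private = rowSums(member) == 1L
    )
  )
  counts <- membership |>
    dplyr::count(.data$category, name = "n_genes") |>
    dplyr::arrange(dplyr::desc(.data$n_genes))
  structure(list(membership = membership, counts = counts),
            class = "set_intersections")
}

#' @export
print.set_intersections <- function(x, ...) {
  cat("<set_intersections> ", nrow(x$membership), " genes in ",
      nrow(x$counts), " membership categories\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.set_intersections <- function(x, ...) x$membership

#' Phenology dendrogram on correlation distance
#'
#' Clusters developmental (E-L scale) time series: every series is divided
#' by the dataset-wide median, the distance between two series is
#' `1 - Pearson r`, and the tree is built by average-linkage hierarchical
#' clustering. Constant series have undefined correlation and are
#' rejected.
#'
#' @param pheno Tibble from [simulate_phenology()] or with the same
#'   columns (`series_id`, `date`, value column).
#' @param value Name of the value column.
#' @return An object of class `phenology_tree` wrapping the `hclust` fit;
#'   see [phenology_newick()] for export and `stats::cutree` on
#'   `$hclust` for partitions.
#' @export
phenology_dendrogram <- function(pheno, value = "el") {
  wide <- pheno |>
    dplyr::select("series_id", "date", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "date", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$series_id
  if (nrow(m) < 2L) stop("need at least 2 series", call. = FALSE)
  if (anyNA(m)) stop("series must share one date grid", call. = FALSE)
  m <- m / median(m)
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop("constant series: ", paste(rownames(m)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  structure(
    list(hclust = hc, labels = rownames(m), dist = d, linkage = "average",
         normalizer = "dataset median"),
    class = "phenology_tree"
  )
}

#' @export
print.phenology_tree <- function(x, ...) {
  cat("<phenology_tree> ", length(x$labels),
      " series, average linkage on 1 - Pearson r\n", sep = "")
  invisible(x)
}

#' Export a phenology tree as newick
#'
#' @param tree A `phenology_tree`.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @export
phenology_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phenology_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("package `ape` is required for newick export", call. = FALSE)
  }
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(file)
  }
}
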