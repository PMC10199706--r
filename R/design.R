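#' Build a complete-crossing factorial sample design
#'
#' Constructs the sample sheet for a fully crossed bulk RNA-seq experiment
#' over the four design variables cultivar, tissue, stage and soil, with a
#' fixed number of biological replicates per condition. The default mirrors
#' a 2 cultivar x 2 tissue x 3 stage x 3 soil x 3 replicate design
#' (36 conditions, 108 samples).
#'
#' Samples are ordered deterministically with factors nested in the order
#' cultivar, tissue, stage, soil, replicate (replicate varying fastest).
#'
#' @param levels Named list of level labels per factor, or a named integer
#'   vector of level counts (labels are then generated). Must contain
#'   `cultivar`, `tissue`, `stage` and `soil`.
#' @param replicates Number of biological replicates per condition.
#' @return A tibble with columns `sample_id`, `cultivar`, `tissue`, `stage`
#'   (ordered factor), `soil`, `replicate` and `condition` (the
#'   cultivar.tissue.stage.soil combination).
#' @export
#' @examples
#' design <- make_design()
#' nrow(design)           # 108
#' dplyr::n_distinct(design$condition)  # 36
make_design <- function(levels = default_design_levels(), replicates = 3) {
  if (is.numeric(levels)) {
    levels <- as.list(levels)
  }
  needed <- c("cultivar", "tissue", "stage", "soil")
  if (!all(needed %in% names(levels))) {
    stop("`levels` must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  defaults <- default_design_levels()
  labs <- lapply(needed, function(f) {
    lv <- levels[[f]]
    if (is.null(lv)) stop("factor `", f, "` has no levels", call. = FALSE)
    if (is.numeric(lv)) {
      n <- as.integer(lv)
      if (is.na(n) || n < 1L) stop("factor `", f, "` is empty", call. = FALSE)
      if (n <= length(defaults[[f]])) defaults[[f]][seq_len(n)]
      else paste0(f, "_", seq_len(n))
    } else {
      lv <- as.character(lv)
      if (length(lv) < 1L) stop("factor `", f, "` is empty", call. = FALSE)
      if (anyDuplicated(lv)) stop("duplicate levels in factor `", f, "`",
                                  call. = FALSE)
      lv
    }
  })
  names(labs) <- needed
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("`replicates` must be >= 1", call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    cultivar = labs$cultivar,
    tissue = labs$tissue,
    stage = labs$stage,
    soil = labs$soil,
    replicate = seq_len(replicates)
  )
  design <- grid |>
    dplyr::mutate(
      cultivar = factor(.data$cultivar, levels = labs$cultivar),
      tissue = factor(.data$tissue, levels = labs$tissue),
      stage = factor(.data$stage, levels = labs$stage, ordered = TRUE),
      soil = factor(.data$soil, levels = labs$soil),
      condition = paste(.data$cultivar, .data$tissue, .data$stage, .data$soil,
                        sep = "."),
      sample_id = paste0(.data$condition, ".r", .data$replicate)
    ) |>
    dplyr::select("sample_id", "cultivar", "tissue", "stage", "soil",
                  "replicate", "condition")
  design$condition <- factor(design$condition, levels = unique(design$condition))
  design
}

#' @rdname make_design
#' @export
default_design_levels <- function() {
  list(
    cultivar = c("cv_a", "cv_b"),
    tissue = c("pulp", "skin"),
    stage = c("S1", "S2", "S3"),
    soil = c("soil_a", "soil_b", "soil_c")
  )
}

design_factors <- function() c("cultivar", "tissue", "stage", "soil")

# condition levels in deterministic nesting order
condition_table <- function(design) {
  design |>
    dplyr::distinct(.data$cultivar, .data$tissue, .data$stage, .data$soil,
                    .data$condition) |>
    dplyr::arrange(.data$condition)
}
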