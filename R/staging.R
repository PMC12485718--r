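#' Joint PCA embedding of two or more datasets
#'
#' Concatenates the cells of all datasets over their shared gene universe,
#' selects highly variable genes on the concatenated matrix, scales, and
#' computes an exact PCA. This produces the common PC space in which query
#' cells are staged against reference cells; no batch correction is applied
#' (externally corrected coordinates can be supplied to the kNN functions
#' directly).
#'
#' @param datasets named list of [NormalizedMatrix()] objects sharing gene
#'   ids (map cross-species data with [map_homologs()] first).
#' @param d number of PCs (default 30).
#' @param n_hvg highly variable genes selected on the concatenated matrix
#'   (default 2,500, capped at the shared gene count).
#' @return An `Embedding` whose `labels` data.frame carries `cell_id` and
#'   `dataset` per cell.
#' @export
joint_embed <- function(datasets, d = 30, n_hvg = 2500) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  shared <- Reduce(intersect, lapply(datasets, function(x) rownames(x$values)))
  if (length(shared) == 0) stop("empty shared gene universe")
  mats <- lapply(datasets, function(x) x$values[shared, , drop = FALSE])
  values <- do.call(cbind, mats)
  labels <- data.frame(
    cell_id = unlist(lapply(mats, colnames), use.names = FALSE),
    dataset = rep(names(datasets), vapply(mats, ncol, 0L)),
    stringsAsFactors = FALSE)
  colnames(values) <- sprintf("%s|%s", labels$dataset, labels$cell_id)
  joint <- NormalizedMatrix(values, datasets[[1]]$scale_factor)
  hvg <- select_hvg(joint, min(n_hvg, length(shared)))
  scaled <- scale_and_regress(joint, genes = hvg)
  emb <- pca_embed(scaled, d)
  emb$labels <- labels
  emb
}

#' Reference index for kNN staging and composition
#'
#' @param coordinates reference-cells x D coordinate matrix (same D as the
#'   query embedding).
#' @param stage per-cell ordinal stage labels (required for staging).
#' @param cell_type,dataset optional per-cell labels.
#' @return An object of class `ReferenceIndex`.
#' @export
reference_index <- function(coordinates, stage = NULL, cell_type = NULL,
                            dataset = NULL) {
  coordinates <- as.matrix(coordinates)
  n <- nrow(coordinates)
  for (lab in list(stage, cell_type, dataset))
    if (!is.null(lab) && length(lab) != n)
      stop("labels must have one entry per reference cell")
  structure(list(coordinates = coordinates, stage = stage,
                 cell_type = cell_type, dataset = dataset),
            class = "ReferenceIndex")
}

#' Label composition of each query cell's reference neighbourhood
#'
#' For every query cell, finds its k nearest reference cells in the shared
#' PC space (Euclidean distance) and reports the fraction of each label
#' among them. Two neighbour-search modes:
#' \describe{
#'   \item{`per_stage_pool`}{(staging, k = 15): the k nearest reference
#'     cells are found within each stage separately, the per-stage
#'     candidates are pooled, and the k globally nearest of the pool are
#'     kept. With a single-stage reference this reduces to `global`.}
#'   \item{`global`}{(cell-type composition, k = 20): plain kNN over all
#'     reference cells.}
#' }
#' Distance ties are broken by reference row order.
#'
#' @param query an `Embedding` or a query-cells x D coordinate matrix.
#' @param reference a [reference_index()].
#' @param k neighbours kept per query cell.
#' @param label_kind `"stage"` or `"cell_type"`: which reference label the
#'   fractions are computed over.
#' @param mode `"per_stage_pool"` or `"global"`.
#' @return list of class `NeighborComposition`: `fractions` (query x label
#'   matrix, rows summing to 1 in multiples of 1/k), `k`, `label_kind`.
#' @export
knn_reference_composition <- function(query, reference, k = 15,
                                      label_kind = c("stage", "cell_type"),
                                      mode = c("per_stage_pool", "global")) {
  label_kind <- match.arg(label_kind)
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "ReferenceIndex"))
  q <- if (inherits(query, "Embedding")) query$coordinates else as.matrix(query)
  r <- reference$coordinates
  if (ncol(q) != ncol(r)) stop("query/reference dimensionality mismatch")
  labels <- reference[[label_kind]]
  if (is.null(labels)) stop("reference lacks ", label_kind, " labels")
  if (mode == "per_stage_pool") {
    if (is.null(reference$stage)) stop("per_stage_pool requires stage labels")
    per_stage <- table(reference$stage)
    if (k > min(per_stage))
      stop("k exceeds the smallest per-stage reference count")
  } else if (k > nrow(r)) stop("k exceeds the reference size")

  d2 <- .pairwise_sqdist(q, r)
  lab_levels <- sort(unique(as.character(labels)))
  frac <- matrix(0, nrow(q), length(lab_levels),
                 dimnames = list(rownames(q), lab_levels))
  stage_groups <- if (mode == "per_stage_pool")
    split(seq_len(nrow(r)), reference$stage) else list(seq_len(nrow(r)))
  for (i in seq_len(nrow(q))) {
    pool <- unlist(lapply(stage_groups, function(ix) {
      ix[order(d2[i, ix], ix)[seq_len(min(k, length(ix)))]]
    }), use.names = FALSE)
    chosen <- pool[order(d2[i, pool], pool)[seq_len(k)]]
    tab <- table(factor(as.character(labels[chosen]), levels = lab_levels))
    frac[i, ] <- as.numeric(tab) / k
  }
  structure(list(fractions = frac, k = k, label_kind = label_kind),
            class = "NeighborComposition")
}

#' Aggregate neighbour compositions over query groups
#'
#' Averages the per-cell label-fraction vectors within each query group
#' (e.g. per annotated cell type), renormalizes, and reports the modal
#' label per group (argmax; ties broken by label order) together with the
#' `top_m` most abundant labels.
#'
#' @param composition a `NeighborComposition` from
#'   [knn_reference_composition()].
#' @param groups per-query-cell group labels (NA cells are dropped with a
#'   warning).
#' @param top_m how many most-abundant labels to report per group
#'   (default 5).
#' @return list with `fractions` (group x label matrix), `modal` (named
#'   character vector), `top_labels` (named list of up-to-`top_m` labels,
#'   most abundant first).
#' @export
aggregate_composition <- function(composition, groups, top_m = 5) {
  stopifnot(inherits(composition, "NeighborComposition"))
  frac <- composition$fractions
  if (length(groups) != nrow(frac)) stop("one group label per query required")
  if (anyNA(groups)) {
    warning(sum(is.na(groups)), " ungrouped query cell(s) dropped")
    frac <- frac[!is.na(groups), , drop = FALSE]
    groups <- groups[!is.na(groups)]
  }
  glev <- sort(unique(as.character(groups)))
  out <- matrix(0, length(glev), ncol(frac),
                dimnames = list(glev, colnames(frac)))
  for (g in glev) {
    m <- colMeans(frac[groups == g, , drop = FALSE])
    out[g, ] <- m / sum(m)
  }
  modal <- colnames(out)[apply(out, 1, which.max)]
  top_labels <- lapply(glev, function(g) {
    ord <- order(-out[g, ], seq_len(ncol(out)))
    colnames(out)[ord[seq_len(min(top_m, ncol(out)))]]
  })
  list(fractions = out, modal = stats::setNames(modal, glev),
       top_labels = stats::setNames(top_labels, glev))
}
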