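#' Pseudobulk cluster expression profiles
#'
#' Averages log-normalized expression over the cells of each cluster,
#' optionally after downsampling large clusters to a fixed number of cells
#' (without replacement, seeded) to balance cell numbers across types —
#' e.g. 200 cells per in vitro type vs 500 per in vivo type. Clusters are
#' processed in sorted label order so draws are reproducible.
#'
#' @param norm a [NormalizedMatrix()].
#' @param cluster_labels per-cell cluster labels (no empty clusters).
#' @param downsample_n cap on cells per cluster, or `NULL` for none.
#' @param seed RNG seed for the downsampling draws.
#' @return An object of class `ClusterProfile`: list with `profiles`
#'   (clusters x genes), `n_cells` (cells used per cluster), `downsample_n`,
#'   `seed`.
#' @export
pseudobulk_profiles <- function(norm, cluster_labels, downsample_n = NULL,
                                seed = 1L) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (length(cluster_labels) != ncol(norm$values))
    stop("one cluster label per cell required")
  if (anyNA(cluster_labels)) stop("NA cluster labels")
  labs <- sort(unique(as.character(cluster_labels)))
  set.seed(as.integer(seed))
  prof <- matrix(0, length(labs), nrow(norm$values),
                 dimnames = list(labs, rownames(norm$values)))
  n_used <- stats::setNames(integer(length(labs)), labs)
  for (l in labs) {
    ix <- which(cluster_labels == l)
    if (length(ix) == 0) stop("empty cluster: ", l)
    if (!is.null(downsample_n) && length(ix) > downsample_n)
      ix <- sort(sample(ix, downsample_n))
    prof[l, ] <- Matrix::rowMeans(norm$values[, ix, drop = FALSE])
    n_used[l] <- length(ix)
  }
  structure(list(profiles = prof, n_cells = n_used,
                 downsample_n = downsample_n, seed = as.integer(seed)),
            class = "ClusterProfile")
}

#' Gene set for one correspondence target: expressed union specific
#'
#' Returns the union of the `n_expr` genes with the highest mean expression
#' in the target cluster and the `n_spec` genes with the highest
#' specificity, where `specificity(g) = target(g) / (mean over all clusters
#' of profile(g) + 1e-8)`. Genes not expressed in the target are excluded
#' from the specificity ranking; ties resolve in gene order.
#'
#' @param target named numeric vector: the target cluster's profile.
#' @param all_profiles a `ClusterProfile` for the target's own dataset
#'   (used as the specificity background), or a clusters x genes matrix.
#' @param n_expr,n_spec sizes of the two rankings (default 1,500 each).
#' @return Character vector of gene ids (size between
#'   `min(n_expr, n_genes)` and `n_expr + n_spec`).
#' @export
select_genes_for_target <- function(target, all_profiles, n_expr = 1500,
                                    n_spec = 1500) {
  prof <- if (inherits(all_profiles, "ClusterProfile")) all_profiles$profiles
          else as.matrix(all_profiles)
  ids <- names(target)
  if (is.null(ids)) ids <- colnames(prof)
  if (length(ids) < 1) stop("no shared genes")
  n_genes <- length(ids)
  top_expr <- ids[order(-target, seq_len(n_genes))[seq_len(min(n_expr, n_genes))]]
  spec <- target / (colMeans(prof) + 1e-8)
  spec[target == 0] <- -Inf
  ok <- which(is.finite(spec))
  top_spec <- ids[ok][order(-spec[ok], ok)[seq_len(min(n_spec, length(ok)))]]
  union(top_expr, top_spec)
}

#' Non-negative least squares fit with a free intercept
#'
#' Solves `min || target - (b0 + design %*% beta) ||_2` subject to
#' `beta >= 0` with `b0` unconstrained, by augmenting the design with +1
#' and -1 constant columns inside a single Lawson-Hanson NNLS solve
#' (`b0 = b_plus - b_minus`).
#'
#' @param target numeric vector (gene values of the target cluster).
#' @param design genes x clusters matrix of predictor profiles.
#' @return list of class `NNLSFit`: `beta0`, `beta` (named by design
#'   columns), `residual_norm`, `gene_set_size`.
#' @export
nnls_fit <- function(target, design) {
  design <- as.matrix(design)
  if (any(!is.finite(target)) || any(!is.finite(design)))
    stop("non-finite values in NNLS inputs")
  if (length(target) != nrow(design))
    stop("target length must match design rows")
  a <- cbind(design, 1, -1)
  x <- pracma::lsqnonneg(a, as.numeric(target))$x
  p <- ncol(design)
  beta <- stats::setNames(x[seq_len(p)], colnames(design))
  beta0 <- x[p + 1] - x[p + 2]
  fitted <- as.numeric(a %*% x)
  structure(list(beta0 = beta0, beta = beta,
                 residual_norm = sqrt(sum((target - fitted)^2)),
                 gene_set_size = length(target)),
            class = "NNLSFit")
}

#' Combine the two directed NNLS coefficients
#'
#' The reciprocal correspondence statistic between cluster a of dataset A
#' and cluster b of dataset B: `2 * (beta_ab + 0.01) * (beta_ba + 0.01)`,
#' where `beta_ab` is b's coefficient when predicting a and `beta_ba` is
#' a's coefficient when predicting b. High values require both directions
#' to assign substantial weight ("reciprocal, specific predictivity"); the
#' floor at `2 * 0.01^2 = 2e-4` keeps the statistic positive.
#'
#' @param beta_ab,beta_ba non-negative scalars (vectorized).
#' @return `2 * (beta_ab + 0.01) * (beta_ba + 0.01)`.
#' @export
combine_betas <- function(beta_ab, beta_ba) {
  if (any(beta_ab < 0) || any(beta_ba < 0))
    stop("NNLS coefficients must be non-negative")
  2 * (beta_ab + 0.01) * (beta_ba + 0.01)
}

#' Reciprocal NNLS correspondence between two sets of cluster profiles
#'
#' For every target cluster in A, selects its expressed-union-specific gene
#' set and fits NNLS against all of B's profiles; then switches the roles.
#' The directed coefficient matrices are combined per (a, b) pair with
#' [combine_betas()], and each row of the combined matrix is scaled by its
#' maximum for display.
#'
#' @param profiles_a,profiles_b `ClusterProfile` objects (>= 2 clusters
#'   each); the gene universe is their intersection.
#' @param n_expr,n_spec gene-ranking sizes per target (default 1,500 each).
#' @return list of class `CorrespondenceResult`: `combined` (A x B),
#'   `row_scaled`, `beta_ab` (A-targets x B-clusters), `beta_ba` (B-targets
#'   x A-clusters), `gene_set_sizes` (per-target list).
#' @export
correspondence_matrix <- function(profiles_a, profiles_b, n_expr = 1500,
                                  n_spec = 1500) {
  stopifnot(inherits(profiles_a, "ClusterProfile"),
            inherits(profiles_b, "ClusterProfile"))
  pa <- profiles_a$profiles; pb <- profiles_b$profiles
  if (nrow(pa) < 2 || nrow(pb) < 2) stop("need >= 2 clusters per dataset")
  shared <- intersect(colnames(pa), colnames(pb))
  if (length(shared) == 0) stop("no shared genes between the profile sets")
  pa <- pa[, shared, drop = FALSE]; pb <- pb[, shared, drop = FALSE]

  fit_direction <- function(targets, predictors) {
    out <- matrix(0, nrow(targets), nrow(predictors),
                  dimnames = list(rownames(targets), rownames(predictors)))
    sizes <- stats::setNames(integer(nrow(targets)), rownames(targets))
    for (a in rownames(targets)) {
      gs <- select_genes_for_target(targets[a, ], targets, n_expr, n_spec)
      fit <- nnls_fit(targets[a, gs], t(predictors[, gs, drop = FALSE]))
      out[a, ] <- fit$beta
      sizes[a] <- length(gs)
    }
    list(beta = out, sizes = sizes)
  }
  ab <- fit_direction(pa, pb)
  ba <- fit_direction(pb, pa)
  combined <- combine_betas(ab$beta, t(ba$beta))
  row_scaled <- combined / apply(combined, 1, max)
  structure(list(combined = combined, row_scaled = row_scaled,
                 beta_ab = ab$beta, beta_ba = ba$beta,
                 gene_set_sizes = list(a = ab$sizes, b = ba$sizes)),
            class = "CorrespondenceResult")
}

#' @exportS3Method base::print
print.CorrespondenceResult <- function(x, ...) {
  cat(sprintf("CorrespondenceResult: %d x %d clusters; best matches:\n",
              nrow(x$combined), ncol(x$combined)))
  best <- colnames(x$combined)[apply(x$combined, 1, which.max)]
  print(stats::setNames(best, rownames(x$combined)))
  invisible(x)
}

#' Collapse a normalized matrix onto homologous genes
#'
#' Maps a dataset's gene universe onto another species' gene ids through a
#' (possibly many-to-many) homolog table: for each target id the relative
#' counts (`expm1` of the log-normalized values) of all mapped source genes
#' are summed, per-cell totals over the mapped universe are renormalized to
#' the scale factor, and the log transform reapplied. Because per-cell
#' normalization is scale-free this equals collapsing raw counts and
#' re-normalizing over the mapped genes.
#'
#' @param norm a [NormalizedMatrix()].
#' @param homolog_table data.frame whose first two columns are source gene
#'   id and target gene id.
#' @return A [NormalizedMatrix()] over the distinct target ids.
#' @export
map_homologs <- function(norm, homolog_table) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  ht <- data.frame(source = as.character(homolog_table[[1]]),
                   target = as.character(homolog_table[[2]]),
                   stringsAsFactors = FALSE)
  ht <- unique(ht[ht$source %in% rownames(norm$values), ])
  if (nrow(ht) == 0) stop("empty homolog mapping after intersection")
  targets <- sort(unique(ht$target))
  map <- Matrix::sparseMatrix(i = match(ht$target, targets),
                              j = match(ht$source, rownames(norm$values)),
                              x = 1,
                              dims = c(length(targets), nrow(norm$values)))
  rel <- norm$values
  rel@x <- expm1(rel@x)                      # back to relative counts
  collapsed <- methods::as(methods::as(map %*% rel, "generalMatrix"),
                           "CsparseMatrix")
  totals <- Matrix::colSums(collapsed)
  if (any(totals == 0)) stop("cells with no expression on mapped genes")
  collapsed@x <- log1p(norm$scale_factor * collapsed@x /
                         rep.int(totals, diff(collapsed@p)))
  dimnames(collapsed) <- list(targets, colnames(norm$values))
  NormalizedMatrix(collapsed, norm$scale_factor, cells = norm$cells)
}
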