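#' Total-count log-normalization
#'
#' Divides each cell's counts by its UMI total, multiplies by a pseudocount
#' scale (10,000) and applies `log(1 + x)`. For every cell the sum over
#' genes of `expm1(value)` therefore equals the scale factor exactly.
#'
#' @param cm a [CountMatrix()]; every cell must have a positive UMI total
#'   (filter with [apply_cell_filters()] first).
#' @param scale_factor pseudocount scale, default 10,000.
#' @return A [NormalizedMatrix()] carrying the gene/cell annotations.
#' @export
lognormalize <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) stop("cells with zero total counts; QC-filter first")
  v <- cm$counts
  v@x <- log1p(scale_factor * v@x / rep.int(totals, diff(v@p)))
  NormalizedMatrix(v, scale_factor, genes = cm$genes, cells = cm$cells)
}

.row_stats <- function(values) {
  n <- ncol(values)
  mu <- Matrix::rowMeans(values)
  ex2 <- Matrix::rowMeans(values^2)
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Select highly variable genes
#'
#' Ranks genes by standardized dispersion: a loess trend of log10 variance
#' on log10 mean (fitted over genes with positive mean and variance) gives
#' each gene an expected variance; the dispersion is observed / expected.
#' Zero-variance genes rank last. Ties resolve in gene order.
#'
#' @param norm a [NormalizedMatrix()].
#' @param n number of genes to return (`<=` total genes).
#' @param span loess span for the mean-variance trend.
#' @return Character vector of `n` gene ids, most variable first.
#' @export
select_hvg <- function(norm, n, span = 0.3) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  ids <- rownames(norm$values)
  if (n > length(ids)) stop("n exceeds the number of genes")
  st <- .row_stats(norm$values)
  disp <- rep(-Inf, length(ids))
  use <- st$mean > 0 & st$var > 0
  trend <- NULL
  if (sum(use) >= 10)
    trend <- tryCatch(
      suppressWarnings(stats::loess(log10(st$var[use]) ~ log10(st$mean[use]),
                                    span = span, degree = 2)),
      error = function(e) NULL)
  if (!is.null(trend)) {
    disp[use] <- st$var[use] / 10^stats::fitted(trend)
  } else {
    disp[use] <- st$var[use] / st$mean[use]   # trend-free fallback at tiny n
  }
  ids[order(-disp, seq_along(ids))[seq_len(n)]]
}

#' Expression-bin-matched module score
#'
#' Scores each cell for a gene set as the mean expression of the set minus
#' the mean expression of a control pool: for every set gene, `n_ctrl`
#' control genes are sampled (seeded) from the same average-expression bin
#' (`n_bins` equal-frequency bins over all genes). This is the standard
#' construction behind cell-cycle scoring; supply S or G2/M gene lists to
#' obtain a cell-cycle index suitable for [scale_and_regress()].
#'
#' @param norm a [NormalizedMatrix()].
#' @param gene_set character vector of gene ids (must intersect the matrix).
#' @param n_bins number of equal-frequency expression bins (default 25).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 25, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  ids <- rownames(norm$values)
  gene_set <- intersect(gene_set, ids)
  if (length(gene_set) == 0) stop("gene_set has no genes in the matrix")
  set.seed(as.integer(seed))
  avg <- Matrix::rowMeans(norm$values)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = min(n_bins, length(ids)), labels = FALSE)
  names(bins) <- ids
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- ids[bins == bins[g]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE)
  score <- Matrix::colMeans(norm$values[gene_set, , drop = FALSE]) -
    Matrix::colMeans(norm$values[ctrl, , drop = FALSE])
  stats::setNames(as.numeric(score), colnames(norm$values))
}

#' Scale genes to zero mean / unit variance after regressing out covariates
#'
#' Per gene, expression is regressed (ordinary least squares, with
#' intercept) on the supplied per-cell covariates; the residuals are then
#' standardized to mean 0, variance 1. Genes with zero residual variance
#' become all-zero rows and are flagged via the `"zero_variance"` attribute.
#'
#' @param norm a [NormalizedMatrix()].
#' @param genes gene ids to scale (e.g. the HVGs); default all genes.
#' @param covariates numeric vector, matrix or data.frame of per-cell
#'   covariates (e.g. a cell-cycle index), or `NULL` for plain scaling.
#' @return Dense genes x cells matrix of scaled residuals.
#' @export
scale_and_regress <- function(norm, genes = NULL, covariates = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (is.null(genes)) genes <- rownames(norm$values)
  y <- t(as.matrix(norm$values[genes, , drop = FALSE]))  # cells x genes
  n <- nrow(y)
  x <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop("covariates must have one row per cell")
    if (any(!is.finite(cv))) stop("covariates must be finite")
    x <- cbind(x, cv)
    if (qr(x)$rank < ncol(x))
      stop("covariates are collinear with the intercept")
  }
  beta <- solve(crossprod(x), crossprod(x, y))
  res <- y - x %*% beta
  sds <- sqrt(colSums(res^2) / (n - 1))
  zero <- sds < 1e-12
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero residual variance set to 0")
    sds[zero] <- 1
  }
  out <- t(res) / sds
  out[zero, ] <- 0
  dimnames(out) <- list(genes, colnames(norm$values))
  attr(out, "zero_variance") <- genes[zero]
  out
}

#' Exact PCA of a scaled expression matrix
#'
#' Computes the top-`d` principal components of the cells x genes matrix by
#' singular value decomposition of the column-centred data. Each loading
#' vector is oriented so that its largest-magnitude entry is positive,
#' making the output sign-deterministic.
#'
#' @param scaled genes x cells matrix as from [scale_and_regress()].
#' @param d number of components (default 30; must not exceed the matrix
#'   rank).
#' @return An object of class `Embedding`: list with `coordinates` (cells x
#'   d), `explained_variance` (length d), `loadings` (genes x d,
#'   orthonormal columns), `total_variance` and `labels` (NULL; attach with
#'   downstream helpers).
#' @export
pca_embed <- function(scaled, d = 30) {
  x <- t(as.matrix(scaled))                    # cells x genes
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (d > rank) stop(sprintf("d = %d exceeds the matrix rank (%d)", d, rank))
  u <- sv$u[, seq_len(d), drop = FALSE]
  v <- sv$v[, seq_len(d), drop = FALSE]
  dd <- sv$d[seq_len(d)]
  for (j in seq_len(d)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u * rep(dd, each = n)
  dimnames(coords) <- list(colnames(scaled), paste0("PC", seq_len(d)))
  dimnames(v) <- list(rownames(scaled), paste0("PC", seq_len(d)))
  structure(list(coordinates = coords,
                 explained_variance = dd^2 / (n - 1),
                 loadings = v,
                 total_variance = sum(sv$d^2) / (n - 1),
                 labels = NULL),
            class = "Embedding")
}

#' @exportS3Method base::print
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d PCs (%.1f%% of variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

#' Neighbourhood-graph community detection
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance on the embedding
#' coordinates) and partitions it with Louvain modularity optimization at
#' the given resolution. Community detection is delegated to igraph; the
#' contract here is determinism given the seed, every cell labelled, and at
#' least one cluster.
#'
#' @param embedding an `Embedding` from [pca_embed()], or a cells x d
#'   coordinate matrix.
#' @param k neighbours per cell (positive, `< n` cells).
#' @param resolution Louvain resolution (default 1).
#' @param seed RNG seed.
#' @return Integer vector of cluster labels, one per cell.
#' @export
neighbor_graph_cluster <- function(embedding, k = 20, resolution = 1,
                                   seed = 1L) {
  coords <- if (inherits(embedding, "Embedding")) embedding$coordinates
            else as.matrix(embedding)
  n <- nrow(coords)
  if (k <= 0) stop("k must be positive")
  k <- min(k, n - 1)
  d2 <- .pairwise_sqdist(coords, coords)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    from <- c(from, rep.int(i, k)); to <- c(to, nb)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(as.integer(seed))
  memb <- igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  as.integer(memb)
}

# squared Euclidean distances, rows of a vs rows of b
.pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
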