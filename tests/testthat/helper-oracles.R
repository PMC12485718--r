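# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exhaustive enumeration, explicit loops and
# direct arithmetic only.

# Constrained least squares min ||t - (b0 + D beta)||, beta >= 0, b0 free,
# by enumerating every active set: for each subset S of columns solve the
# unconstrained LS restricted to S (plus a free intercept) and keep the
# best feasible solution. Exact for p <= ~10 columns.
oracle_nnls <- function(target, design) {
  p <- ncol(design)
  best <- list(rss = Inf)
  for (mask in 0:(2^p - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    x <- cbind(1, design[, s, drop = FALSE])
    fit <- stats::lsfit(x, target, intercept = FALSE)
    cf <- fit$coefficients
    if (any(cf[-1] < -1e-9)) next
    rss <- sum(fit$residuals^2)
    if (rss < best$rss - 1e-12) {
      beta <- numeric(p)
      beta[s] <- pmax(cf[-1], 0)
      best <- list(rss = rss, beta0 = cf[1], beta = beta)
    }
  }
  best
}

# All-pairs-distance kNN composition by explicit loops and full sorts.
oracle_knn_composition <- function(q, r, stage, labels, k,
                                   mode = c("per_stage_pool", "global")) {
  mode <- match.arg(mode)
  lev <- sort(unique(as.character(labels)))
  out <- matrix(0, nrow(q), length(lev), dimnames = list(rownames(q), lev))
  for (i in seq_len(nrow(q))) {
    d <- numeric(nrow(r))
    for (j in seq_len(nrow(r))) d[j] <- sqrt(sum((q[i, ] - r[j, ])^2))
    if (mode == "global") {
      pool <- seq_len(nrow(r))
    } else {
      pool <- integer(0)
      for (s in sort(unique(stage))) {
        ix <- which(stage == s)
        pool <- c(pool, ix[order(d[ix], ix)][seq_len(min(k, length(ix)))])
      }
    }
    sel <- pool[order(d[pool], pool)][seq_len(k)]
    cnt <- stats::setNames(numeric(length(lev)), lev)
    for (l in as.character(labels[sel])) cnt[l] <- cnt[l] + 1
    out[i, ] <- cnt / k
  }
  out
}

# Tiny dense random CountMatrix for arithmetic checks.
random_count_matrix <- function(n_genes, n_cells, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  z <- which(colSums(m) == 0)
  if (length(z)) m[1, z] <- 1    # guard: no all-zero cell
  CountMatrix(Matrix::Matrix(m, sparse = TRUE),
              data.frame(gene_id = sprintf("G%03d", seq_len(n_genes))),
              data.frame(cell_id = sprintf("C%03d", seq_len(n_cells))))
}

# NormalizedMatrix straight from a dense value matrix (bypasses
# lognormalize so tests can plant exact values).
norm_from_values <- function(values, scale_factor = 1e4) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("C%03d", seq_len(ncol(values)))
  NormalizedMatrix(methods::as(Matrix::Matrix(values, sparse = TRUE),
                               "CsparseMatrix"), scale_factor)
}
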