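#' Principal-axis analysis of a cell subset with PC-correlated genes
#'
#' Extracts a subset of cells (e.g. the neural-tube-related types),
#' re-selects highly variable genes on the subset, scales and computes a
#' PCA, then correlates every gene's log-normalized expression (all genes,
#' not only the HVGs) with the PC1 scores. Significance is assessed by the
#' t-transform of Pearson's r (n - 2 df) with Benjamini-Hochberg adjustment
#' across genes. Zero-variance genes report r = 0 and are flagged so the
#' output gene universe stays stable.
#'
#' @param norm a [NormalizedMatrix()].
#' @param cell_subset cell ids (or logical/integer index) to analyse.
#' @param n_hvg highly variable genes for the PCA (default 2,500, capped).
#' @param d number of PCs to report (default 3; the subset must exceed
#'   `d` cells).
#' @return list of class `AxisAnalysis`: `pc_scores` (cells x d),
#'   `variance_fraction` (per-PC fraction of the scaled matrix's total
#'   variance), `gene_correlations` (data.frame `gene_id`, `r`, `p`,
#'   `p_adj`, `zero_variance`), `embedding`.
#' @export
axis_pc1_analysis <- function(norm, cell_subset, n_hvg = 2500, d = 3) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  ci <- cell_subset
  if (is.character(ci)) ci <- match(ci, colnames(norm$values))
  if (is.logical(ci)) ci <- which(ci)
  if (length(ci) == 0 || anyNA(ci)) stop("invalid cell subset")
  if (length(ci) < d + 1) stop("cell subset smaller than d + 1")
  sub <- NormalizedMatrix(norm$values[, ci, drop = FALSE], norm$scale_factor)
  hvg <- select_hvg(sub, min(n_hvg, nrow(sub$values)))
  scaled <- scale_and_regress(sub, genes = hvg)
  emb <- pca_embed(scaled, d)
  pc1 <- emb$coordinates[, 1]

  y <- as.matrix(sub$values)
  n <- length(pc1)
  ym <- y - rowMeans(y)
  sdy <- sqrt(rowSums(ym^2))
  pcc <- pc1 - mean(pc1)
  r <- as.numeric(ym %*% pcc) / (sdy * sqrt(sum(pcc^2)))
  zero <- sdy < 1e-12
  r[zero] <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[zero] <- 1
  structure(list(
    pc_scores = emb$coordinates,
    variance_fraction = emb$explained_variance / emb$total_variance,
    gene_correlations = data.frame(
      gene_id = rownames(y), r = r, p = p,
      p_adj = stats::p.adjust(p, method = "BH"),
      zero_variance = zero, row.names = NULL, stringsAsFactors = FALSE),
    embedding = emb), class = "AxisAnalysis")
}

#' Normalize segment RT-qPCR Ct values to a housekeeping gene and z-score
#'
#' Expression of each gene is first normalized to the reference
#' (housekeeping) gene within each segment as `rel = 2^-(Ct_gene -
#' Ct_ref)`, then z-scored across the segments (anterior, middle,
#' posterior): subtract the row mean and divide by the sample standard
#' deviation. Genes with any undetected (NA) Ct are emitted as all-NA rows;
#' genes with identical relative expression in every segment get a zero row
#' and are flagged via the `"zero_sd"` attribute.
#'
#' @param ct genes x segments numeric matrix of Ct values, rows named by
#'   gene; must include the reference gene measured in every segment.
#' @param reference_gene housekeeping gene row name (default "GAPDH").
#' @return genes x segments matrix of z-scores (reference row dropped),
#'   with attribute `zero_sd`.
#' @export
hox_qpcr_normalize <- function(ct, reference_gene = "GAPDH") {
  ct <- as.matrix(ct)
  if (!reference_gene %in% rownames(ct))
    stop("reference gene absent from the Ct table")
  ref <- ct[reference_gene, ]
  if (anyNA(ref)) stop("reference gene not detected in every segment")
  genes <- setdiff(rownames(ct), reference_gene)
  rel <- 2^-(sweep(ct[genes, , drop = FALSE], 2, ref))
  z <- rel * NA_real_
  zero_sd <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    if (anyNA(rel[g, ])) next                     # not-detected row stays NA
    s <- stats::sd(rel[g, ])
    if (s == 0) {
      z[g, ] <- 0
      zero_sd[g] <- TRUE
    } else z[g, ] <- (rel[g, ] - mean(rel[g, ])) / s
  }
  attr(z, "zero_sd") <- zero_sd
  z
}

#' Line-of-origin composition per cell type
#'
#' Tabulates, for each annotated cell type and overall, the fraction of
#' cells assigned to each donor line (plus doublet / unassigned
#' categories). The confident-only view renormalizes over the line labels
#' alone, matching how "confidently assigned" proportions are reported.
#'
#' @param assignments per-cell donor labels (e.g. `"lineA"`, `"lineB"`,
#'   `"doublet"`, `"unassigned"`).
#' @param cell_types per-cell type labels, aligned with `assignments`.
#' @param confident_only if `TRUE`, restrict to the line categories (all
#'   labels except `exclude`) and renormalize.
#' @param exclude categories treated as non-line labels for the confident
#'   view (default `c("doublet", "unassigned")`).
#' @return data.frame with one row per cell type plus `"overall"`, a
#'   `n_cells` column, and one fraction column per category (rows sum
#'   to 1).
#' @export
line_composition <- function(assignments, cell_types, confident_only = FALSE,
                             exclude = c("doublet", "unassigned")) {
  if (length(assignments) != length(cell_types))
    stop("assignments and cell_types must be aligned per cell")
  assignments <- as.character(assignments)
  cell_types <- as.character(cell_types)
  if (confident_only) {
    keep <- !assignments %in% exclude
    assignments <- assignments[keep]
    cell_types <- cell_types[keep]
  }
  cats <- sort(unique(assignments))
  rows <- c(sort(unique(cell_types)), "overall")
  out <- data.frame(cell_type = rows, n_cells = 0L, stringsAsFactors = FALSE)
  for (cc in cats) out[[cc]] <- 0
  for (i in seq_along(rows)) {
    ix <- if (rows[i] == "overall") seq_along(cell_types)
          else which(cell_types == rows[i])
    out$n_cells[i] <- length(ix)
    tab <- table(factor(assignments[ix], levels = cats))
    out[i, cats] <- as.numeric(tab) / length(ix)
  }
  out
}
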