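#' Per-cell quality-control summaries
#'
#' Computes, for every cell, the UMI total, the number of detected genes and
#' the percentage of UMIs mapping to mitochondrial and ribosomal genes.
#' Cells with zero total counts get MT% / Ribo% of 0 and are flagged.
#'
#' @param cm a [CountMatrix()] whose gene table carries `is_mt` and
#'   `is_ribo` flags.
#' @return data.frame with columns `cell_id`, `umi_total`, `genes_detected`,
#'   `mt_pct`, `ribo_pct`, `doublet_score` (NA when absent from the cell
#'   metadata) and `zero_total` flag.
#' @export
compute_cell_qc <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  umi <- Matrix::colSums(cm$counts)
  ngene <- Matrix::colSums(cm$counts > 0)
  mt <- Matrix::colSums(cm$counts[cm$genes$is_mt, , drop = FALSE])
  ribo <- Matrix::colSums(cm$counts[cm$genes$is_ribo, , drop = FALSE])
  zero <- umi == 0
  if (any(zero)) warning(sum(zero), " cell(s) with zero total counts")
  denom <- ifelse(zero, 1, umi)
  data.frame(cell_id = cm$cells$cell_id, umi_total = umi,
             genes_detected = ngene,
             mt_pct = 100 * mt / denom, ribo_pct = 100 * ribo / denom,
             doublet_score = if (is.null(cm$cells$doublet_score)) NA_real_
                             else cm$cells$doublet_score,
             zero_total = zero, row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene-level retention filters
#'
#' Two named filter stages: `"primary"` keeps genes on chromosomes 1-22, X,
#' Y and MT only (applied to the raw matrix before any cell filtering);
#' `"embedding"` keeps protein-coding and lincRNA genes and drops sex
#' chromosomes (applied before normalization and embedding).
#'
#' @param cm a [CountMatrix()] with `chromosome` and `biotype` annotations.
#' @param stage `"primary"` or `"embedding"`.
#' @return A filtered [CountMatrix()].
#' @export
apply_gene_filters <- function(cm, stage = c("primary", "embedding")) {
  stopifnot(inherits(cm, "CountMatrix"))
  stage <- match.arg(stage)
  chr <- cm$genes$chromosome
  keep <- if (stage == "primary") {
    chr %in% c(as.character(1:22), "X", "Y", "MT")
  } else {
    cm$genes$biotype %in% c("protein_coding", "lincRNA") & !chr %in% c("X", "Y")
  }
  subset_counts(cm, genes = which(keep))
}

#' Default two-pass cell-filtering rule set
#'
#' Pass 1 removes cells with fewer than 1,000 UMIs or fewer than 500
#' detected genes. Pass 2, evaluated on the pass-1 survivors, removes cells
#' with fewer than 5,000 UMIs, the top 0.1% of cells by UMI total, doublet
#' scores over 0.2, MT% over 10 or Ribo% over 40. All inequalities are
#' strict, so boundary values are retained.
#'
#' @return A list of two ordered rule lists (`pass1`, `pass2`); each rule is
#'   `list(rule = <name>, value = <threshold>)` with names drawn from
#'   `umi_min`, `genes_min`, `umi_top_frac`, `doublet_max`, `mt_max`,
#'   `ribo_max`.
#' @export
default_cell_filters <- function() {
  list(pass1 = list(list(rule = "umi_min", value = 1000),
                    list(rule = "genes_min", value = 500)),
       pass2 = list(list(rule = "umi_min", value = 5000),
                    list(rule = "umi_top_frac", value = 0.001),
                    list(rule = "doublet_max", value = 0.2),
                    list(rule = "mt_max", value = 10),
                    list(rule = "ribo_max", value = 40)))
}

.rule_violates <- function(qc, rule) {
  switch(rule$rule,
         umi_min = qc$umi_total < rule$value,
         genes_min = qc$genes_detected < rule$value,
         doublet_max = qc$doublet_score > rule$value,
         mt_max = qc$mt_pct > rule$value,
         ribo_max = qc$ribo_pct > rule$value,
         stop("unknown rule: ", rule$rule))
}

# "exceeding the top f of the total cells": remove the ceiling(f * N)
# highest-UMI cells among the N entering this pass; ties resolved by
# removing later cell ids first.
.top_frac_violates <- function(qc, f) {
  n <- nrow(qc)
  out <- rep(FALSE, n)
  m <- ceiling(f * n)
  if (m > 0) {
    ord <- order(-qc$umi_total, -seq_len(n))
    out[ord[seq_len(m)]] <- TRUE
  }
  out
}

#' Apply the two-pass cell filters
#'
#' Rules within a pass are conjunctive: a cell is retained iff it violates
#' none. The `umi_top_frac` rule is evaluated on the population entering
#' pass 2 (the pass-1 survivors). A per-rule report counts removals in the
#' listed order.
#'
#' @param qc data.frame from [compute_cell_qc()].
#' @param rules rule set as returned by [default_cell_filters()].
#' @return list with `retained` (character vector of cell ids) and `report`
#'   (data.frame `rule`, `n_removed`, `n_retained`; removals attributed
#'   sequentially in rule order).
#' @export
apply_cell_filters <- function(qc, rules = default_cell_filters()) {
  if (nrow(qc) == 0) stop("empty QC table")
  report <- data.frame(rule = character(0), n_removed = integer(0),
                       n_retained = integer(0))
  alive <- rep(TRUE, nrow(qc))
  run_pass <- function(pass_rules, pool) {
    for (r in pass_rules) {
      bad <- if (r$rule == "umi_top_frac") {
        v <- rep(FALSE, nrow(qc))
        v[pool][.top_frac_violates(qc[pool, , drop = FALSE], r$value)] <- TRUE
        v
      } else .rule_violates(qc, r)
      removed <- alive & bad
      alive <<- alive & !bad
      report <<- rbind(report, data.frame(
        rule = sprintf("%s(%g)", r$rule, r$value),
        n_removed = sum(removed), n_retained = sum(alive)))
    }
  }
  run_pass(rules$pass1, seq_len(nrow(qc)))
  pass1_survivors <- which(alive)
  run_pass(rules$pass2, pass1_survivors)
  if (!any(alive)) warning("all cells removed by the filters")
  list(retained = qc$cell_id[alive], report = report)
}

#' Flag clusters enriched for high doublet scores
#'
#' A cluster is flagged when its mean doublet score exceeds `score_factor`
#' times the median of the per-cluster mean scores. This reconstructs the
#' practice of discarding whole clusters that concentrate doublets after
#' inspecting the per-cluster score distribution.
#'
#' @param qc data.frame from [compute_cell_qc()] (uses `doublet_score`).
#' @param cluster_labels per-cell cluster labels, aligned with `qc` rows.
#' @param score_factor multiple of the median per-cluster mean score above
#'   which a cluster is flagged (default 2).
#' @return Character vector of flagged cluster labels (possibly empty).
#' @export
flag_doublet_clusters <- function(qc, cluster_labels, score_factor = 2) {
  stopifnot(nrow(qc) == length(cluster_labels))
  means <- tapply(qc$doublet_score, cluster_labels, mean)
  if (length(means) < 2) {
    warning("fewer than 2 clusters; nothing flagged")
    return(character(0))
  }
  names(means)[means > score_factor * stats::median(means)]
}
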