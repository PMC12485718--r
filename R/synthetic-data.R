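#' Simulation specification for synthetic scRNA-seq data
#'
#' Bundles every knob of the negative-binomial count simulator. Counts for
#' cell c are drawn NB around `lambda_gc = libsize_c * softmax_g(base_g +
#' type_effect * marker_gc + stage_effect * stage_c * gradient_g + batch_g)`,
#' i.e. cell types are defined by additive log-mean marker shifts, the
#' developmental stage moves expression monotonically along one fixed random
#' gene direction, and a dataset-wide batch shift perturbs all genes.
#'
#' @param n_genes number of genes.
#' @param frac_mt,frac_ribo,frac_coding fractions of genes annotated as
#'   mitochondrial (chromosome "MT"), ribosomal (RPS/RPL symbols) and
#'   protein-coding; the non-coding remainder is split evenly between
#'   "lincRNA" and "other".
#' @param n_types number of planted cell types.
#' @param cells_per_type singlet cells simulated per type.
#' @param n_stages number of ordinal stage labels (S1..Sn).
#' @param stage_effect log-mean shift per unit of (normalized) stage along
#'   the gradient direction.
#' @param type_effect log-fold marker shift defining each type.
#' @param n_markers_per_type marker genes per type (disjoint sets).
#' @param batch_effect sd of the per-gene dataset-wide log-mean shift.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsize_logmean,libsize_logsd log-normal library-size parameters.
#' @param doublet_rate fraction of emitted cells that are doublets (< 0.5).
#' @param seed integer RNG seed; identical specs give identical output.
#' @return A validated list of class `SimSpec`.
#' @export
sim_spec <- function(n_genes = 2000, frac_mt = 0.02, frac_ribo = 0.05,
                     frac_coding = 0.75, n_types = 5, cells_per_type = 200,
                     n_stages = 4, stage_effect = 1, type_effect = 2,
                     n_markers_per_type = 25, batch_effect = 0.3,
                     nb_dispersion = 0.5, libsize_logmean = log(2e4),
                     libsize_logsd = 0.35, doublet_rate = 0.05, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), frac_mt = frac_mt,
               frac_ribo = frac_ribo, frac_coding = frac_coding,
               n_types = as.integer(n_types),
               cells_per_type = as.integer(cells_per_type),
               n_stages = as.integer(n_stages), stage_effect = stage_effect,
               type_effect = type_effect,
               n_markers_per_type = as.integer(n_markers_per_type),
               batch_effect = batch_effect, nb_dispersion = nb_dispersion,
               libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
               doublet_rate = doublet_rate, seed = as.integer(seed))
  fr <- c(spec$frac_mt, spec$frac_ribo, spec$frac_coding, spec$doublet_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (spec$doublet_rate >= 0.5) stop("doublet_rate must be below 0.5")
  if (spec$n_genes < 1 || spec$n_types < 1 || spec$cells_per_type < 1 ||
      spec$n_stages < 1 || spec$n_markers_per_type < 1)
    stop("counts must be >= 1")
  if (spec$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(c(spec$stage_effect, spec$type_effect, spec$batch_effect) < 0))
    stop("effect sizes must be non-negative")
  if (spec$n_markers_per_type * spec$n_types > spec$n_genes)
    stop("marker sets exceed the gene universe")
  structure(spec, class = "SimSpec")
}

# Gene table with exact annotation counts (proportions honoured to +/- 1
# gene by rounding). MT and ribosomal genes are excluded from marker and
# gradient roles so QC fractions stay stable across types and stages.
.sim_gene_table <- function(spec) {
  n <- spec$n_genes
  n_mt <- round(spec$frac_mt * n)
  n_ribo <- round(spec$frac_ribo * n)
  chrom <- sample(as.character(1:22), n, replace = TRUE)
  n_rest <- n - n_mt - n_ribo
  sex <- sample(seq_len(n)[-seq_len(n_mt + n_ribo)],
                size = min(n_rest, round(0.06 * n)))
  chrom[sex] <- sample(c("X", "Y"), length(sex), replace = TRUE,
                       prob = c(0.8, 0.2))
  chrom[seq_len(n_mt)] <- "MT"
  symbol <- sprintf("GENE%04d", seq_len(n))
  symbol[seq_len(n_mt)] <- sprintf("MT-G%02d", seq_len(n_mt))
  if (n_ribo > 0)
    symbol[n_mt + seq_len(n_ribo)] <- sprintf("RPS%03d", seq_len(n_ribo))
  n_cod <- round(spec$frac_coding * n)
  n_linc <- round((n - n_cod) / 2)
  biotype <- rep("other", n)
  bio_order <- sample.int(n)
  biotype[bio_order[seq_len(n_cod)]] <- "protein_coding"
  if (n_linc > 0) biotype[bio_order[n_cod + seq_len(n_linc)]] <- "lincRNA"
  data.frame(gene_id = sprintf("G%04d", seq_len(n)), symbol = symbol,
             chromosome = chrom, biotype = biotype,
             is_mt = chrom == "MT", is_ribo = grepl("^RP[SL]", symbol),
             stringsAsFactors = FALSE)
}

# Draw NB counts for one block of cells sharing per-(type,stage) softmax
# profiles. Returns a dgCMatrix plus realized library sizes.
.sim_draw_counts <- function(eta, combo_of_cell, libsizes, nb_dispersion) {
  p <- apply(eta, 2, function(e) { w <- exp(e - max(e)); w / sum(w) })
  n_genes <- nrow(eta)
  n_cells <- length(combo_of_cell)
  size <- 1 / nb_dispersion
  ii <- vector("list", n_cells); xx <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    lam <- libsizes[c] * p[, combo_of_cell[c]]
    cnt <- stats::rnbinom(n_genes, size = size, mu = lam)
    nz <- which(cnt > 0L)
    ii[[c]] <- nz; xx[[c]] <- cnt[nz]
  }
  Matrix::sparseMatrix(i = unlist(ii),
                       j = rep.int(seq_len(n_cells), lengths(ii)),
                       x = unlist(xx), dims = c(n_genes, n_cells))
}

.truncnorm01 <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)

# Simulate one dataset from pre-drawn structure. `profiles` is a list with
# base, markers (list of gene index vectors per type), gradient, batch.
.sim_dataset <- function(spec, genes, profiles, type_names, prefix) {
  n_types <- length(type_names)
  n_sing <- n_types * spec$cells_per_type
  type_idx <- rep(seq_len(n_types), each = spec$cells_per_type)
  stage_idx <- rep_len(seq_len(spec$n_stages), n_sing)
  stage_frac <- (stage_idx - 1) / max(spec$n_stages - 1, 1)

  eta_type <- vapply(seq_len(n_types), function(t) {
    e <- profiles$base + profiles$batch
    e[profiles$markers[[t]]] <- e[profiles$markers[[t]]] + spec$type_effect
    e
  }, numeric(spec$n_genes))
  # distinct softmax profile per (type, stage) combination
  s_frac <- (seq_len(spec$n_stages) - 1) / max(spec$n_stages - 1, 1)
  eta <- matrix(0, spec$n_genes, n_types * spec$n_stages)
  for (t in seq_len(n_types)) for (s in seq_len(spec$n_stages))
    eta[, (t - 1) * spec$n_stages + s] <-
      eta_type[, t] + spec$stage_effect * s_frac[s] * profiles$gradient
  combo <- (type_idx - 1) * spec$n_stages + stage_idx

  libsizes <- exp(stats::rnorm(n_sing, spec$libsize_logmean, spec$libsize_logsd))
  counts <- .sim_draw_counts(eta, combo, libsizes, spec$nb_dispersion)

  n_doub <- round(spec$doublet_rate * n_sing)
  parents <- NULL
  if (n_doub > 0) {
    t1 <- integer(n_doub); t2 <- integer(n_doub); ds <- integer(n_doub)
    for (d in seq_len(n_doub)) {
      pair <- sample.int(n_types, 2)
      t1[d] <- pair[1]; t2[d] <- pair[2]
      ds[d] <- sample.int(spec$n_stages, 1)
    }
    lib1 <- exp(stats::rnorm(n_doub, spec$libsize_logmean, spec$libsize_logsd))
    lib2 <- exp(stats::rnorm(n_doub, spec$libsize_logmean, spec$libsize_logsd))
    p1 <- .sim_draw_counts(eta, (t1 - 1) * spec$n_stages + ds, lib1,
                           spec$nb_dispersion)
    p2 <- .sim_draw_counts(eta, (t2 - 1) * spec$n_stages + ds, lib2,
                           spec$nb_dispersion)
    counts <- cbind(counts, p1 + p2)
    parents <- list(parent1 = p1, parent2 = p2,
                    type1 = type_names[t1], type2 = type_names[t2])
    type_idx <- c(type_idx, t1)       # doublet labelled by its first parent
    stage_idx <- c(stage_idx, ds)
  }
  n_cells <- n_sing + n_doub
  is_doublet <- c(rep(FALSE, n_sing), rep(TRUE, n_doub))
  score <- numeric(n_cells)
  score[!is_doublet] <- .truncnorm01(n_sing, 0.05, 0.05)
  if (n_doub > 0) score[is_doublet] <- .truncnorm01(n_doub, 0.5, 0.05)

  cell_id <- sprintf("%s_cell%05d", prefix, seq_len(n_cells))
  dimnames(counts) <- list(genes$gene_id, cell_id)
  cells <- data.frame(cell_id = cell_id,
                      cell_type = type_names[type_idx],
                      stage = sprintf("S%d", stage_idx),
                      is_doublet = is_doublet, doublet_score = score,
                      umi_total = Matrix::colSums(counts),
                      stringsAsFactors = FALSE)
  list(cm = CountMatrix(counts, genes, cells), parents = parents)
}

.marker_pool <- function(genes) which(!genes$is_mt & !genes$is_ribo)

#' Generate one synthetic scRNA-seq dataset with planted structure
#'
#' Draws singlet cells for each planted type (types defined by disjoint
#' marker-gene sets), spreads cells across ordinal stages along a fixed
#' random log-mean gradient, and appends doublets formed as the elementwise
#' sum of two freshly drawn singlet profiles from two distinct types.
#' Doublets carry elevated simulated doublet scores (mean 0.5 vs 0.05,
#' sd 0.05, truncated to \[0, 1\]) so a 0.2 threshold separates them.
#'
#' @param spec a [sim_spec()].
#' @return A list with `cm` (a [CountMatrix()], cell metadata holding type,
#'   stage, doublet flag/score and realized library size) and `truth`
#'   (class `GroundTruth`: `cells` table, `marker_genes`, empty
#'   `correspondence`). The two parent count matrices of each doublet are
#'   attached as `attr(truth, "doublet_parents")` for verification.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  genes <- .sim_gene_table(spec)
  pool <- .marker_pool(genes)
  if (spec$n_markers_per_type * spec$n_types > length(pool))
    stop("marker sets exceed the non-MT/non-ribosomal gene pool")
  marker_idx <- sample(pool, spec$n_markers_per_type * spec$n_types)
  markers <- split(marker_idx,
                   rep(seq_len(spec$n_types), each = spec$n_markers_per_type))
  gradient <- stats::rnorm(spec$n_genes)
  gradient[genes$is_mt | genes$is_ribo] <- 0
  profiles <- list(base = stats::rnorm(spec$n_genes, 0, 1),
                   markers = markers, gradient = gradient,
                   batch = stats::rnorm(spec$n_genes, 0, spec$batch_effect))
  type_names <- sprintf("T%02d", seq_len(spec$n_types))
  sim <- .sim_dataset(spec, genes, profiles, type_names, "A")
  truth <- structure(
    list(cells = sim$cm$cells[, c("cell_id", "cell_type", "stage",
                                  "is_doublet", "doublet_score")],
         marker_genes = stats::setNames(
           lapply(markers, function(ix) genes$gene_id[ix]), type_names),
         correspondence = stats::setNames(character(0), character(0))),
    class = "GroundTruth")
  attr(truth, "doublet_parents") <- sim$parents
  list(cm = sim$cm, truth = truth)
}

#' Generate two synthetic datasets sharing planted cell types
#'
#' Emulates an in vitro dataset (A) paired with an in vivo reference (B):
#' `shared_types` of the types are drawn from identical type-level mean
#' profiles in both datasets (B under shuffled labels), each dataset gets an
#' independent per-gene batch shift of sd `batch_effect`, and both carry
#' stage labels from the same planted gradient. The injective planted map
#' from A-type to B-type labels is recorded in the ground truth.
#'
#' @param spec a [sim_spec()].
#' @param shared_types number of types common to both datasets
#'   (`<= n_types`).
#' @return A list with `a`, `b` (two [CountMatrix()]) and `truth`
#'   (`GroundTruth` with `cells_a`, `cells_b`, `correspondence`,
#'   `marker_genes`).
#' @export
generate_paired_datasets <- function(spec, shared_types) {
  stopifnot(inherits(spec, "SimSpec"))
  shared_types <- as.integer(shared_types)
  if (shared_types < 0 || shared_types > spec$n_types)
    stop("shared_types must lie in [0, n_types]")
  set.seed(spec$seed)
  genes <- .sim_gene_table(spec)
  pool <- .marker_pool(genes)
  n_sets <- 2L * spec$n_types - shared_types
  if (spec$n_markers_per_type * n_sets > length(pool))
    stop("marker sets exceed the non-MT/non-ribosomal gene pool")
  marker_idx <- sample(pool, spec$n_markers_per_type * n_sets)
  sets <- split(marker_idx, rep(seq_len(n_sets), each = spec$n_markers_per_type))
  base <- stats::rnorm(spec$n_genes, 0, 1)
  gradient <- stats::rnorm(spec$n_genes)
  gradient[genes$is_mt | genes$is_ribo] <- 0

  type_a <- sprintf("A%02d", seq_len(spec$n_types))
  type_b <- sprintf("B%02d", seq_len(spec$n_types))
  # B slot j <- A type perm[j] for the shared block; rest are B-private
  perm <- if (shared_types > 0) sample.int(shared_types) else integer(0)
  markers_a <- sets[seq_len(spec$n_types)]
  markers_b <- vector("list", spec$n_types)
  for (j in seq_len(spec$n_types)) {
    markers_b[[j]] <- if (j <= shared_types) markers_a[[perm[j]]]
                      else sets[[spec$n_types + (j - shared_types)]]
  }
  corr <- stats::setNames(type_b[seq_len(shared_types)],
                          type_a[perm])

  seed_a <- spec$seed * 2L + 1L
  seed_b <- spec$seed * 2L + 2L
  set.seed(seed_a)
  prof_a <- list(base = base, markers = markers_a, gradient = gradient,
                 batch = stats::rnorm(spec$n_genes, 0, spec$batch_effect))
  sim_a <- .sim_dataset(spec, genes, prof_a, type_a, "A")
  set.seed(seed_b)
  prof_b <- list(base = base, markers = markers_b, gradient = gradient,
                 batch = stats::rnorm(spec$n_genes, 0, spec$batch_effect))
  sim_b <- .sim_dataset(spec, genes, prof_b, type_b, "B")

  keep <- c("cell_id", "cell_type", "stage", "is_doublet", "doublet_score")
  truth <- structure(
    list(cells_a = sim_a$cm$cells[, keep], cells_b = sim_b$cm$cells[, keep],
         correspondence = corr,
         marker_genes = list(
           a = stats::setNames(lapply(markers_a, function(ix) genes$gene_id[ix]), type_a),
           b = stats::setNames(lapply(markers_b, function(ix) genes$gene_id[ix]), type_b))),
    class = "GroundTruth")
  list(a = sim_a$cm, b = sim_b$cm, truth = truth)
}

#' Construct a fixture straddling every cell-QC decision boundary
#'
#' Deterministically plants cells sitting just inside and just outside each
#' filtering rule: UMI totals 999/1,000 and 4,999/5,000, 499/500 detected
#' genes, 9.9/10.1 MT%, 39/41 Ribo%, doublet scores 0.19/0.21, plus one
#' extreme-UMI cell caught by the top-fraction rule; remaining cells are
#' unremarkable passers. The intended per-rule and overall pass/fail status
#' is recorded in the cell metadata (computed by direct arithmetic on the
#' planted quantities, independently of the filtering code).
#'
#' @param n_cells total cells (>= 10; the first up-to-13 are boundary cells).
#' @param seed RNG seed for the filler cells.
#' @return A [CountMatrix()] whose cell table carries `intent`,
#'   `doublet_score` and logical `pass_*` columns (including `pass_overall`).
#' @export
generate_qc_fixture <- function(n_cells, seed = 1L) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 10) stop("n_cells must be at least 10")
  set.seed(as.integer(seed))
  n_genes <- 700L
  chrom <- c("MT", rep(as.character(1:22), length.out = n_genes - 1))
  symbol <- c("MT-G01", "RPS001", sprintf("GENE%04d", 3:n_genes))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                      symbol = symbol, chromosome = chrom,
                      biotype = "protein_coding",
                      is_mt = chrom == "MT", is_ribo = grepl("^RP[SL]", symbol),
                      stringsAsFactors = FALSE)

  # intent: umi total, detected genes, mt umis, ribo umis, doublet score
  proto <- list(
    umi_999    = c(999,  600, 0, 0, 0.05),
    umi_1000   = c(1000, 600, 0, 0, 0.05),
    genes_499  = c(5500, 499, 0, 0, 0.05),
    genes_500  = c(5500, 500, 0, 0, 0.05),
    umi_4999   = c(4999, 600, 0, 0, 0.05),
    umi_5000   = c(5000, 600, 0, 0, 0.05),
    mt_9.9     = c(10000, 600, 990, 0, 0.05),
    mt_10.1    = c(10000, 600, 1010, 0, 0.05),
    ribo_39    = c(10000, 600, 0, 3900, 0.05),
    ribo_41    = c(10000, 600, 0, 4100, 0.05),
    dblt_0.19  = c(10000, 600, 0, 0, 0.19),
    dblt_0.21  = c(10000, 600, 0, 0, 0.21),
    umi_top    = c(300000, 600, 0, 0, 0.05))
  n_proto <- min(length(proto), n_cells)
  intent <- c(names(proto)[seq_len(n_proto)],
              rep("filler", n_cells - n_proto))
  umi <- numeric(n_cells); ngene <- numeric(n_cells)
  mt <- numeric(n_cells); ribo <- numeric(n_cells); score <- numeric(n_cells)
  for (i in seq_len(n_proto)) {
    v <- proto[[i]]
    umi[i] <- v[1]; ngene[i] <- v[2]; mt[i] <- v[3]; ribo[i] <- v[4]
    score[i] <- v[5]
  }
  if (n_cells > n_proto) {
    fill <- (n_proto + 1):n_cells
    umi[fill] <- sample(8000:20000, length(fill), replace = TRUE)
    ngene[fill] <- sample(550:650, length(fill), replace = TRUE)
    mt[fill] <- round(umi[fill] * stats::runif(length(fill), 0.005, 0.03))
    ribo[fill] <- round(umi[fill] * stats::runif(length(fill), 0.02, 0.08))
    score[fill] <- round(stats::runif(length(fill), 0.01, 0.1), 3)
  }

  ii <- vector("list", n_cells); xx <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    n_other <- ngene[c] - (mt[c] > 0) - (ribo[c] > 0)
    other <- umi[c] - mt[c] - ribo[c]
    per <- other %/% n_other
    extra <- other - per * n_other
    cnt <- rep(per, n_other) + c(rep(1, extra), rep(0, n_other - extra))
    idx <- 2L + seq_len(n_other)
    if (ribo[c] > 0) { idx <- c(2L, idx); cnt <- c(ribo[c], cnt) }
    if (mt[c] > 0) { idx <- c(1L, idx); cnt <- c(mt[c], cnt) }
    keep <- cnt > 0
    ii[[c]] <- idx[keep]; xx[[c]] <- cnt[keep]
  }
  counts <- Matrix::sparseMatrix(i = unlist(ii),
                                 j = rep.int(seq_len(n_cells), lengths(ii)),
                                 x = unlist(xx), dims = c(n_genes, n_cells))
  cell_id <- sprintf("QC_cell%05d", seq_len(n_cells))

  # intended flags, straight from the rule definitions (strict inequalities)
  mt_pct <- ifelse(umi > 0, 100 * mt / umi, 0)
  ribo_pct <- ifelse(umi > 0, 100 * ribo / umi, 0)
  p_umi1000 <- !(umi < 1000)
  p_genes500 <- !(ngene < 500)
  pass1 <- p_umi1000 & p_genes500
  p_umi5000 <- !(umi < 5000)
  p_dblt <- !(score > 0.2)
  p_mt <- !(mt_pct > 10)
  p_ribo <- !(ribo_pct > 40)
  # top-fraction rule over the pass-1 survivors: remove the ceil(f*N)
  # highest-UMI cells, ties resolved by removing later cell ids first
  p_top <- rep(TRUE, n_cells)
  surv <- which(pass1)
  m <- ceiling(0.001 * length(surv))
  ord <- surv[order(-umi[surv], -seq_along(surv))]
  p_top[ord[seq_len(m)]] <- FALSE
  overall <- pass1 & p_umi5000 & p_top & p_dblt & p_mt & p_ribo

  cells <- data.frame(cell_id = cell_id, intent = intent,
                      doublet_score = score, umi_planted = umi,
                      genes_planted = ngene,
                      pass_umi1000 = p_umi1000, pass_genes500 = p_genes500,
                      pass_umi5000 = p_umi5000, pass_topfrac = p_top,
                      pass_doublet = p_dblt, pass_mt = p_mt,
                      pass_ribo = p_ribo, pass_overall = overall,
                      stringsAsFactors = FALSE)
  CountMatrix(counts, genes, cells)
}

#' Write simulated ground truth to disk
#'
#' Emits a per-cell TSV (`cell_id`, `cell_type`, `stage`, `is_doublet`,
#' `doublet_score`) and, when present, the planted type-correspondence map
#' as JSON.
#'
#' @param truth a `GroundTruth` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- truth[grep("^cells", names(truth))]
  for (nm in names(tabs))
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(truth$correspondence),
                       file.path(dir, "correspondence.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
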