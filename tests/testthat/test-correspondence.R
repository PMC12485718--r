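test_that("pseudobulk profiles average, downsample and reproduce", {
  cm <- random_count_matrix(30, 12, seed = 4)
  norm <- lognormalize(cm)
  labs <- rep(c("x", "y", "z"), times = c(1, 5, 6))
  pr <- pseudobulk_profiles(norm, labs)
  # singleton cluster: profile equals that cell's values
  expect_equal(pr$profiles["x", ], as.numeric(norm$values[, 1]),
               ignore_attr = TRUE)
  # downsample_n larger than every cluster: identical to no downsampling
  pr2 <- pseudobulk_profiles(norm, labs, downsample_n = 50, seed = 2)
  expect_equal(pr$profiles, pr2$profiles)
  # identical cells: downsampled mean equals the full mean
  v <- matrix(rep(1:30, 40), nrow = 30)
  nm <- norm_from_values(v)
  pr3 <- pseudobulk_profiles(nm, rep("c", 40), downsample_n = 10, seed = 1)
  expect_equal(unname(pr3$profiles["c", ]), as.numeric(1:30))
  expect_equal(unname(pr3$n_cells["c"]), 10)
  expect_error(pseudobulk_profiles(norm, labs[-1]), "per cell")
})

test_that("target gene selection is the union of two exact rankings", {
  # saturation: everything returned when n_expr covers the universe
  prof <- matrix(runif(5 * 40), 5, 40,
                 dimnames = list(paste0("c", 1:5), sprintf("g%02d", 1:40)))
  tgt <- prof[1, ]
  expect_setequal(select_genes_for_target(tgt, prof, n_expr = 40, n_spec = 0),
                  names(tgt))
  # a gene expressed only in the target is always in the specificity set
  prof2 <- prof
  prof2[, "g07"] <- 0
  prof2[1, "g07"] <- 0.5
  sel <- select_genes_for_target(prof2[1, ], prof2, n_expr = 0, n_spec = 3)
  expect_true("g07" %in% sel)

  # brute-force two-ranking oracle on a random profile set
  set.seed(19)
  big <- matrix(rexp(10 * 5000), 10, 5000,
                dimnames = list(paste0("c", 1:10), sprintf("g%04d", 1:5000)))
  big[big < 0.1] <- 0
  tgt <- big[3, ]
  got <- select_genes_for_target(tgt, big, n_expr = 1500, n_spec = 1500)
  # oracle: independent sorts
  ids <- names(tgt)
  o_expr <- ids[head(order(tgt, decreasing = TRUE), 1500)]
  spec_score <- tgt / (colMeans(big) + 1e-8)
  spec_score[tgt == 0] <- NA
  o_spec <- ids[head(order(-spec_score, na.last = TRUE), 1500)]
  expect_setequal(got, union(o_expr, o_spec))
  expect_true(length(got) >= 1500 && length(got) <= 3000)
})

test_that("NNLS fits exact cases and matches the active-set oracle", {
  # orthogonal indicators: exact representation
  d <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  f <- nnls_fit(3 * d[, 1], d)
  expect_equal(unname(f$beta), c(3, 0), tolerance = 1e-10)
  expect_equal(f$beta0, 0, tolerance = 1e-10)
  expect_equal(f$residual_norm, 0, tolerance = 1e-10)
  # negative constant target is absorbed by the free intercept
  f2 <- nnls_fit(rep(-1, 4), d)
  expect_equal(unname(f2$beta), c(0, 0), tolerance = 1e-10)
  expect_equal(f2$beta0, -1, tolerance = 1e-10)
  expect_error(nnls_fit(c(1, NA, 1, 1), d), "finite")

  set.seed(23)
  for (i in 1:25) {
    p <- sample(1:8, 1)
    n <- sample(max(p + 2, 5):50, 1)
    design <- matrix(runif(n * p), n, p)
    beta_true <- ifelse(runif(p) < 0.5, 0, rexp(p))
    tgt <- design %*% beta_true + rnorm(n, 0, 0.5) + runif(1, -1, 1)
    fit <- nnls_fit(as.numeric(tgt), design)
    orc <- oracle_nnls(as.numeric(tgt), design)
    expect_lt(max(abs(fit$beta - orc$beta)), 1e-6)
    expect_lt(abs(fit$beta0 - orc$beta0), 1e-6)
    # intercept-only fit is always feasible, so never beaten
    expect_lte(fit$residual_norm,
               sqrt(sum((tgt - mean(tgt))^2)) + 1e-10)
  }
})

test_that("NNLS residuals never increase when a column is added", {
  set.seed(29)
  for (i in 1:10) {
    n <- 40
    design <- matrix(runif(n * 6), n, 6)
    tgt <- runif(n)
    r_prev <- Inf
    for (p in 1:6) {
      r <- nnls_fit(tgt, design[, 1:p, drop = FALSE])$residual_norm
      expect_lte(r, r_prev + 1e-10)
      r_prev <- r
    }
  }
})

test_that("combined beta follows the printed formula and is symmetric", {
  expect_identical(combine_betas(0, 0), 2e-4)
  expect_equal(combine_betas(0.99, 0.99), 2, tolerance = 1e-12)
  set.seed(31)
  a <- rexp(1000); b <- rexp(1000)
  expect_equal(combine_betas(a, b), combine_betas(b, a))
  expect_error(combine_betas(-0.1, 1), "non-negative")
})

test_that("correspondence matrix recovers matched duplicate clusters", {
  # two pairs of near-identical profiles made distinct by marker blocks
  set.seed(37)
  base <- rexp(400)
  mk <- function(markers) { p <- base; p[markers] <- p[markers] + 3; p }
  pa <- rbind(a1 = mk(1:20), a2 = mk(21:40))
  pb <- rbind(b1 = mk(1:20) + rnorm(400, 0, 0.05),
              b2 = mk(21:40) + rnorm(400, 0, 0.05))
  pb <- pmax(pb, 0)
  colnames(pa) <- colnames(pb) <- sprintf("g%03d", 1:400)
  cpa <- structure(list(profiles = pa, n_cells = c(a1 = 1, a2 = 1),
                        downsample_n = NULL, seed = 1L),
                   class = "ClusterProfile")
  cpb <- structure(list(profiles = pb, n_cells = c(b1 = 1, b2 = 1),
                        downsample_n = NULL, seed = 1L),
                   class = "ClusterProfile")
  cr <- correspondence_matrix(cpa, cpb, n_expr = 100, n_spec = 100)
  expect_equal(colnames(cr$combined)[apply(cr$combined, 1, which.max)],
               c("b1", "b2"))
  expect_true(all(cr$combined > 0))
  expect_equal(unname(apply(cr$row_scaled, 1, max)), c(1, 1))
  expect_true(all(cr$row_scaled > 0 & cr$row_scaled <= 1))

  # permuting B's clusters permutes the columns identically
  cpb_perm <- cpb
  cpb_perm$profiles <- pb[c("b2", "b1"), ]
  cpb_perm$n_cells <- cpb$n_cells[c("b2", "b1")]
  cr2 <- correspondence_matrix(cpa, cpb_perm, n_expr = 100, n_spec = 100)
  expect_equal(cr2$combined[, c("b1", "b2")], cr$combined)
})

test_that("planted type correspondences are recovered from paired data", {
  sp <- sim_spec(n_genes = 1500, n_types = 6, cells_per_type = 150,
                 type_effect = 2, doublet_rate = 0, seed = 41)
  pd <- generate_paired_datasets(sp, shared_types = 6)
  pa <- pseudobulk_profiles(lognormalize(pd$a), pd$a$cells$cell_type,
                            downsample_n = 200, seed = 1)
  pb <- pseudobulk_profiles(lognormalize(pd$b), pd$b$cells$cell_type,
                            downsample_n = 500, seed = 1)
  cr <- correspondence_matrix(pa, pb, n_expr = 750, n_spec = 750)
  best <- setNames(colnames(cr$combined)[apply(cr$combined, 1, which.max)],
                   rownames(cr$combined))
  corr <- pd$truth$correspondence
  expect_gte(sum(best[names(corr)] == corr), 5)
})

test_that("homolog collapse sums counts and renormalizes", {
  # one-to-one full-coverage mapping preserves values exactly
  cm <- random_count_matrix(20, 6, seed = 43)
  norm <- lognormalize(cm)
  ids <- rownames(norm$values)
  tab <- data.frame(source = ids, target = paste0("h_", ids))
  out <- map_homologs(norm, tab)
  expect_equal(as.matrix(out$values[paste0("h_", ids), ]),
               as.matrix(norm$values), ignore_attr = TRUE)

  # hand-enumerated many-to-many collapse: 3 source, 2 target, 4 edges
  counts <- matrix(c(2, 3, 5,
                     0, 5, 5), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  cm2 <- CountMatrix(Matrix::Matrix(counts, sparse = TRUE),
                     data.frame(gene_id = rownames(counts)),
                     data.frame(cell_id = colnames(counts)))
  n2 <- lognormalize(cm2, scale_factor = 10)
  edges <- data.frame(source = c("g1", "g2", "g2", "g3"),
                      target = c("t1", "t1", "t2", "t2"))
  got <- map_homologs(n2, edges)
  # t1 = g1+g2 = (5, 5); t2 = g2+g3 = (8, 10); totals (13, 15)
  expected <- log1p(10 * matrix(c(5 / 13, 8 / 13, 5 / 15, 10 / 15), 2, 2))
  expect_equal(as.matrix(got$values[c("t1", "t2"), ]), expected,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(map_homologs(norm, data.frame(source = "zz", target = "t")),
               "empty")
})
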