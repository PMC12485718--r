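test_that("joint embedding co-locates duplicate datasets", {
  sp <- sim_spec(n_genes = 500, n_types = 2, cells_per_type = 40,
                 doublet_rate = 0, seed = 3)
  g <- generate_dataset(sp)
  norm <- lognormalize(g$cm)
  emb <- joint_embed(list(one = norm, two = norm), d = 5, n_hvg = 200)
  n <- ncol(norm$values)
  expect_equal(emb$coordinates[1:n, ], emb$coordinates[n + 1:n, ],
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(emb$labels$dataset, rep(c("one", "two"), each = n))
  # captured variance cannot exceed the total
  expect_lte(sum(emb$explained_variance), emb$total_variance + 1e-8)

  bad <- norm
  rownames(bad$values) <- paste0("other_", rownames(bad$values))
  expect_error(joint_embed(list(norm, bad), d = 2), "shared gene")
})

test_that("a dominant planted gradient lands on PC1", {
  sp <- sim_spec(n_genes = 1000, n_types = 1, cells_per_type = 400,
                 n_stages = 4, stage_effect = 2, doublet_rate = 0, seed = 7)
  g <- generate_dataset(sp)
  norm <- lognormalize(g$cm)
  half <- seq_len(200)
  emb <- joint_embed(list(a = NormalizedMatrix(norm$values[, half], 1e4),
                          b = NormalizedMatrix(norm$values[, -half], 1e4)),
                     d = 1, n_hvg = 300)
  stage_num <- as.integer(sub("S", "", g$cm$cells$stage[c(half, setdiff(seq_len(400), half))]))
  expect_gt(abs(cor(emb$coordinates[, 1], stage_num)), 0.9)
})

test_that("kNN composition handles coincident and symmetric queries", {
  ref_xy <- rbind(c(0, 0), c(10, 10), c(20, 0))
  ref <- reference_index(ref_xy, stage = c("CS11", "CS12", "CS12"))
  comp <- knn_reference_composition(rbind(c(0, 0)), ref, k = 1,
                                    label_kind = "stage", mode = "global")
  expect_equal(comp$fractions[1, ], c(CS11 = 1, CS12 = 0))
  # two single-point stages, equidistant query, k = 2, per-stage pooling
  ref2 <- reference_index(rbind(c(-1, 0), c(1, 0)), stage = c("A", "B"))
  comp2 <- knn_reference_composition(rbind(c(0, 0)), ref2, k = 1,
                                     label_kind = "stage",
                                     mode = "per_stage_pool")
  expect_equal(comp2$fractions[1, ], c(A = 1, B = 0))  # tie -> earlier row
  ref3 <- reference_index(rbind(c(-1, 0), c(1, 0), c(-1, 1), c(1, 1)),
                          stage = c("A", "B", "A", "B"))
  comp3 <- knn_reference_composition(rbind(c(0, 0.5)), ref3, k = 2,
                                     label_kind = "stage",
                                     mode = "per_stage_pool")
  expect_equal(comp3$fractions[1, ], c(A = 0.5, B = 0.5))
  expect_error(knn_reference_composition(rbind(c(0, 0, 0)), ref2, k = 1),
               "mismatch")
  expect_error(knn_reference_composition(rbind(c(0, 0)), ref2, k = 3,
                                         mode = "per_stage_pool"), "k exceeds")
})

test_that("kNN composition equals the brute-force all-pairs oracle", {
  set.seed(11)
  r <- matrix(rnorm(500 * 4), 500, 4)
  stage <- sample(c("S1", "S2", "S3"), 500, replace = TRUE)
  ctype <- sample(letters[1:5], 500, replace = TRUE)
  ref <- reference_index(r, stage = stage, cell_type = ctype)
  q <- matrix(rnorm(50 * 4), 50, 4)
  for (mode in c("per_stage_pool", "global")) {
    got <- knn_reference_composition(q, ref, k = 15, label_kind = "stage",
                                     mode = mode)
    orc <- oracle_knn_composition(q, r, stage, stage, k = 15, mode = mode)
    expect_identical(unname(got$fractions), unname(orc))
  }
  gotc <- knn_reference_composition(q, ref, k = 20, label_kind = "cell_type",
                                    mode = "global")
  orcc <- oracle_knn_composition(q, r, stage, ctype, k = 20, mode = "global")
  expect_identical(unname(gotc$fractions), unname(orcc))
  # fractions are multiples of 1/k summing to one
  expect_true(all(abs(rowSums(gotc$fractions) - 1) < 1e-12))
  expect_true(all(abs(gotc$fractions * 20 - round(gotc$fractions * 20)) < 1e-9))
})

test_that("single-stage references make the two modes coincide", {
  set.seed(13)
  r <- matrix(rnorm(200 * 3), 200, 3)
  ref <- reference_index(r, stage = rep("S1", 200),
                         cell_type = sample(c("x", "y"), 200, replace = TRUE))
  q <- matrix(rnorm(20 * 3), 20, 3)
  a <- knn_reference_composition(q, ref, k = 10, label_kind = "cell_type",
                                 mode = "per_stage_pool")
  b <- knn_reference_composition(q, ref, k = 10, label_kind = "cell_type",
                                 mode = "global")
  expect_identical(a$fractions, b$fractions)
})

test_that("reference row order does not change compositions", {
  set.seed(17)
  r <- matrix(rnorm(300 * 3), 300, 3)
  stage <- sample(c("S1", "S2"), 300, replace = TRUE)
  q <- matrix(rnorm(25 * 3), 25, 3)
  perm <- sample(300)
  a <- knn_reference_composition(q, reference_index(r, stage = stage), k = 10)
  b <- knn_reference_composition(q, reference_index(r[perm, ],
                                                    stage = stage[perm]),
                                 k = 10)
  expect_equal(a$fractions, b$fractions)
})

test_that("group aggregation averages fractions and reports modal labels", {
  frac <- rbind(c(1, 0), c(0, 1), c(1, 0))
  colnames(frac) <- c("CS11", "CS12")
  comp <- structure(list(fractions = frac, k = 1, label_kind = "stage"),
                    class = "NeighborComposition")
  agg <- aggregate_composition(comp, c("g1", "g2", "g1"))
  expect_equal(agg$fractions["g1", ], c(CS11 = 1, CS12 = 0))
  expect_equal(unname(agg$modal["g1"]), "CS11")
  # exact tie resolves to the first label in column order
  agg2 <- aggregate_composition(comp, c("g", "g", "h"))
  expect_equal(agg2$fractions["g", ], c(CS11 = 0.5, CS12 = 0.5))
  expect_equal(unname(agg2$modal["g"]), "CS11")
  expect_equal(agg2$top_labels$g, c("CS11", "CS12"))
  expect_warning(aggregate_composition(comp, c("g", NA, "g")), "dropped")
})

test_that("held-out cells recover their planted stage via kNN staging", {
  sp <- sim_spec(n_genes = 1000, n_types = 2, cells_per_type = 600,
                 n_stages = 4, stage_effect = 2, doublet_rate = 0, seed = 19)
  g <- generate_dataset(sp)
  norm <- lognormalize(g$cm)
  hvg <- select_hvg(norm, 300)
  emb <- pca_embed(scale_and_regress(norm, hvg), 10)
  stages <- g$cm$cells$stage
  set.seed(20)
  qix <- unlist(lapply(split(seq_along(stages), stages), sample, size = 30))
  ref <- reference_index(emb$coordinates[-qix, ], stage = stages[-qix])
  comp <- knn_reference_composition(emb$coordinates[qix, ], ref, k = 15,
                                    label_kind = "stage",
                                    mode = "per_stage_pool")
  agg <- aggregate_composition(comp, groups = stages[qix])
  expect_gte(mean(agg$modal == names(agg$modal)), 0.8)
})
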