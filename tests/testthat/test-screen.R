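test_that("partitioning gives exact disjoint blocks and drops remainders", {
  g32 <- paste0("g", 1:32)
  p <- partition_gene_set(g32, 16, seed = 1)
  expect_length(p, 2)
  expect_setequal(unlist(lapply(p, `[[`, "gene_ids")), g32)

  p30 <- partition_gene_set(paste0("g", 1:30), 16, seed = 1)
  expect_length(p30, 1)
  expect_length(p30[[1]]$gene_ids, 16)

  expect_length(partition_gene_set(paste0("g", 1:15), 16, seed = 1), 0)
  expect_length(partition_gene_set(character(), 16, seed = 1), 0)

  # property: sizes and disjointness for arbitrary lengths
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:200, 1); k <- sample(1:20, 1)
    parts <- partition_gene_set(paste0("x", seq_len(n)), k, seed = rep)
    expect_length(parts, n %/% k)
    ids <- unlist(lapply(parts, `[[`, "gene_ids"))
    expect_length(ids, (n %/% k) * k)
    expect_false(anyDuplicated(ids) > 0)
  }
  # seeded shuffle is reproducible
  expect_identical(partition_gene_set(g32, 8, seed = 5),
                   partition_gene_set(g32, 8, seed = 5))
})

test_that("silhouette matches the hand-derived two-cluster value", {
  coords <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labs <- c("A", "A", "B", "B")
  # a = 1 for every point; b = (10 + sqrt(101)) / 2
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_score(coords, labs), (b - 1) / b, tolerance = 1e-12)
  expect_equal(round(silhouette_score(coords, labs), 3), 0.900)
})

test_that("silhouette agrees with independent implementations to 1e-12", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 30
    coords <- matrix(rnorm(2 * n), n, 2)
    labs <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    mine <- silhouette_score(coords, labs)
    expect_equal(mine, brute_silhouette(coords, labs), tolerance = 1e-12)
    sil <- cluster::silhouette(as.integer(factor(labs)), stats::dist(coords))
    expect_equal(mine, mean(sil[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("silhouette degenerate cases: overlap, singletons, one cluster", {
  set.seed(13)
  cloud <- matrix(rnorm(40), 20, 2)
  overlapping <- rbind(cloud, cloud)
  expect_lte(silhouette_score(overlapping, rep(c("a", "b"), each = 20)), 0)
  # singleton cluster contributes s = 0 (checked against the brute force,
  # which implements the same convention independently)
  coords <- rbind(c(0, 0), c(5, 5), c(5, 6))
  s3 <- silhouette_score(coords, c("solo", "pair", "pair"))
  expect_equal(s3, brute_silhouette(coords, c("solo", "pair", "pair")),
               tolerance = 1e-12)
  expect_gte(s3, -1)
  expect_lte(s3, 1)
  expect_error(silhouette_score(coords, rep("a", 3)), "two clusters")
})

test_that("extreme selection thresholds on mean +/- k population sd", {
  res <- data.frame(parent_set = "p", subset_index = 1:4, genes = "",
                    silhouette = c(0, 0, 0, 1), selected = "neither")
  out <- select_extremes(res, k_sd = 1)
  # m = 0.25, population sd = 0.433; only the 1 exceeds 0.683
  expect_identical(out$selected, c("neither", "neither", "neither", "high"))
  expect_equal(attr(out, "sil_mean"), 0.25)
  expect_equal(attr(out, "sil_sd"), sqrt(3) / 4, tolerance = 1e-12)

  flat <- res; flat$silhouette <- rep(0.4, 4)
  expect_true(all(select_extremes(flat, 1)$selected == "neither"))

  out0 <- select_extremes(res, k_sd = 0)
  expect_identical(out0$selected, c("low", "low", "low", "high"))
})

test_that("UMAP embedding is shaped, seeded, and separates distant blobs", {
  set.seed(20)
  blobs <- rbind(matrix(rnorm(60 * 2), 60, 2),
                 matrix(rnorm(60 * 2, mean = 10), 60, 2))
  labs <- rep(c("a", "b"), each = 60)
  e1 <- embed_2d(blobs, n_neighbors = 15, min_dist = 0.3, seed = 5)
  expect_identical(dim(e1), c(120L, 2L))
  e2 <- embed_2d(blobs, n_neighbors = 15, min_dist = 0.3, seed = 5)
  expect_identical(e1, e2)
  expect_gt(silhouette_score(e1, labs), 0.8)
  # n_neighbors larger than the sample count is reduced with a warning
  expect_warning(embed_2d(blobs[1:10, ], n_neighbors = 90, seed = 1),
                 "reduced")
})

test_that("screening ranks planted subsets above null subsets", {
  sim <- generate_two_state_gem(synthetic_spec(100, 64, 8, 3, seed = 31))
  pp <- preprocess_gem(sim$gem, 0.67, seed = 31)
  full <- gem(rbind(pp$train$values, pp$test$values),
              labels = c(pp$train$labels, pp$test$labels))
  nulls <- setdiff(colnames(full$values), sim$signal_genes)  # 56 genes
  subsets <- c(
    list(structure(list(parent_set_name = "planted", subset_index = 1L,
                        gene_ids = c(sim$signal_genes, nulls[1:8])),
                   class = "gene_subset")),
    lapply(1:3, function(i) {
      structure(list(parent_set_name = "null", subset_index = i,
                     gene_ids = nulls[8 + (i - 1) * 16 + (1:16)]),
                class = "gene_subset")
    }))
  res <- screen_subsets(full, subsets, n_neighbors = 30, seed = 31)
  expect_equal(nrow(res), 4)
  expect_true(all(res$silhouette >= -1 & res$silhouette <= 1))
  planted <- res$silhouette[res$parent_set == "planted"]
  expect_gt(planted, max(res$silhouette[res$parent_set == "null"]))
  # permuting phenotype labels destroys the separation (same embedding)
  emb <- embed_2d(full$values[, subsets[[1]]$gene_ids], n_neighbors = 30,
                  seed = 31)
  perm <- withr::with_seed(31, sample(full$labels))
  expect_lt(silhouette_score(emb, perm), planted)
  expect_lt(silhouette_score(emb, perm), 0.1)
  # determinism of the whole screen
  res2 <- screen_subsets(full, subsets, n_neighbors = 30, seed = 31)
  expect_identical(res$silhouette, res2$silhouette)
  # missing gene is named
  bad <- list(structure(list(parent_set_name = "p", subset_index = 1L,
                             gene_ids = c("ghost_gene", nulls[1:7])),
                        class = "gene_subset"))
  expect_error(screen_subsets(full, bad, seed = 1), "ghost_gene")
})

test_that("random background summarises seeded draws", {
  sim <- generate_two_state_gem(synthetic_spec(60, 24, 4, 3, seed = 17))
  pp <- preprocess_gem(sim$gem, 0.67, seed = 17)
  nulls <- setdiff(colnames(pp$train$values), sim$signal_genes)
  bg <- random_background(pp$train, subset_size = 8, n_reps = 3, seed = 17,
                          pool = nulls, n_neighbors = 20)
  expect_length(bg$silhouettes, 3)
  expect_gte(bg$sd, 0)
  bg2 <- random_background(pp$train, subset_size = 8, n_reps = 3, seed = 17,
                           pool = nulls, n_neighbors = 20)
  expect_identical(bg$silhouettes, bg2$silhouettes)
})
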