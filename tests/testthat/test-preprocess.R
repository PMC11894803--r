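test_that("log2(n+1) maps the documented anchor points", {
  g <- gem(matrix(c(0, 1, 7, 3), 2, 2,
                  dimnames = list(c("s1", "s2"), c("gA", "gB"))))
  lg <- log2p1(g)
  expect_equal(lg$values["s1", "gA"], 0)
  expect_equal(lg$values["s2", "gA"], 1)
  expect_equal(lg$values["s1", "gB"], 3)
  g$values[1, 1] <- -0.5
  expect_error(log2p1(g), "negative")
})

test_that("scaler endpoints, midpoint, clipping and constants behave", {
  tr <- gem(matrix(c(0, 2, 4, 3, 3, 3), 3, 2,
                   dimnames = list(paste0("s", 1:3), c("gA", "gB"))))
  p <- fit_scaler(tr)
  expect_equal(p$min, c(0, 3))
  expect_equal(p$max, c(4, 3))
  expect_identical(p$constant, c(FALSE, TRUE))
  expect_identical(fit_scaler(tr), p)

  sc <- apply_scaler(tr, p)
  expect_equal(sc$values[, "gA"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(sc$values[, "gB"], c(0, 0, 0), ignore_attr = TRUE)

  new <- gem(matrix(c(9, -1, 5, 5), 2, 2,
                    dimnames = list(c("n1", "n2"), c("gA", "gB"))))
  scn <- apply_scaler(new, p)
  expect_equal(scn$values[1, "gA"], 1)    # above max -> clipped
  expect_equal(scn$values[2, "gA"], -1)   # below min -> clipped
  expect_true(all(scn$values[, "gB"] == 0))
})

test_that("inverse scaling is exact and restores constants", {
  set.seed(1)
  tr <- gem(matrix(runif(60, 0, 12), 10, 6,
                   dimnames = list(paste0("s", 1:10), paste0("g", 1:6))))
  tr$values[, 6] <- 5  # constant gene
  p <- fit_scaler(tr)
  sc <- apply_scaler(tr, p)
  back <- invert_scaler(sc$values, p)
  expect_lt(max(abs(back[, 1:5] - tr$values[, 1:5])), 1e-9)
  expect_true(all(back[, 6] == 5))
  # -1 maps to the per-gene minimum
  lo <- invert_scaler(matrix(-1, 1, 6, dimnames = list("x", paste0("g", 1:6))), p)
  expect_equal(unname(lo[1, 1:5]), p$min[1:5])
  # fpkm inversion is the full inverse of the chain
  raw <- gem(matrix(runif(40, 0, 500), 8, 5,
                    dimnames = list(paste0("r", 1:8), paste0("g", 1:5))))
  lg <- log2p1(raw)
  p2 <- fit_scaler(lg)
  round2 <- invert_scaler(apply_scaler(lg, p2)$values, p2, to_fpkm = TRUE)
  expect_lt(max(abs(round2 - raw$values)), 1e-6)
})

test_that("scaler params survive a TSV round trip", {
  tr <- gem(matrix(runif(30), 5, 6,
                   dimnames = list(paste0("s", 1:5), paste0("g", 1:6))))
  p <- fit_scaler(tr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaler(p, path)
  q <- read_scaler(path)
  expect_equal(q$min, p$min, tolerance = 1e-12)
  expect_equal(q$max, p$max, tolerance = 1e-12)
  expect_identical(q$gene_ids, p$gene_ids)
})

test_that("scaling is affine: correlation with the raw values is 1", {
  set.seed(2)
  tr <- gem(matrix(runif(200, 0, 10), 20, 10,
                   dimnames = list(paste0("s", 1:20), paste0("g", 1:10))))
  sc <- apply_scaler(tr, fit_scaler(tr))
  cors <- vapply(1:10, function(j) cor(tr$values[, j], sc$values[, j]), 1.0)
  expect_equal(cors, rep(1, 10), tolerance = 1e-12)
})

test_that("stratified split arithmetic follows floor-and-remainder", {
  sim <- generate_two_state_gem(synthetic_spec(50, 5, 0, 0, seed = 3))
  sp <- split_train_test(sim$gem, 0.67, seed = 3)
  expect_equal(nrow(sp$train$values), 67)
  expect_equal(nrow(sp$test$values), 33)
  counts <- table(sp$train$labels)
  expect_true(all(counts %in% c(33, 34)))
  # disjoint and exhaustive
  expect_length(intersect(rownames(sp$train$values),
                          rownames(sp$test$values)), 0)
  expect_setequal(c(rownames(sp$train$values), rownames(sp$test$values)),
                  rownames(sim$gem$values))

  tiny <- gem(matrix(1:8, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b"))),
              labels = c("x", "x", "y", "y"))
  sp2 <- split_train_test(tiny, 0.5, seed = 1)
  expect_equal(nrow(sp2$train$values), 2)
  expect_equal(nrow(sp2$test$values), 2)

  expect_identical(split_train_test(sim$gem, 0.67, seed = 9),
                   split_train_test(sim$gem, 0.67, seed = 9))
  one <- gem(matrix(1:6, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b"))),
             labels = c("x", "y", "y"))
  expect_error(split_train_test(one, 0.5, seed = 1), ">= 2 samples")
})

test_that("the preprocessing chain lands in [-1, 1] with both labels", {
  sim <- generate_two_state_gem(synthetic_spec(30, 12, 3, 2, seed = 8))
  pp <- preprocess_gem(sim$gem, 0.67, seed = 8)
  expect_true(all(abs(pp$train$values) <= 1))
  expect_true(all(abs(pp$test$values) <= 1))
  expect_length(unique(pp$train$labels), 2)
  expect_length(unique(pp$test$labels), 2)
})
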