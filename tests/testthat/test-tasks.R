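fake_result <- function(scores, subset = "s1") {
  structure(list(per_gene_score = scores, subset_name = subset),
            class = "perturbation_result")
}

test_that("core-gene calling uses a strict two-sided population-sd rule", {
  # mean 2, population sd 4: the 10 sits exactly at mean + 2 sd, and the
  # strict inequality leaves it unflagged
  r <- fake_result(c(a = 0, b = 0, c = 0, d = 0, e = 10))
  tab <- pool_scores(list(r), k_sd = 2)
  expect_false(any(tab$core))
  expect_equal(attr(tab, "score_mean"), 2)
  expect_equal(attr(tab, "score_sd"), 4)

  flat <- fake_result(c(a = 1, b = 1, c = 1))
  expect_false(any(pool_scores(list(flat), k_sd = 2)$core))

  sym <- fake_result(c(lo = -5, hi = 5))
  both <- pool_scores(list(sym), k_sd = 0)
  expect_true(all(both$core))

  dup <- list(fake_result(c(a = 1, b = 2)), fake_result(c(b = 3), "s2"))
  expect_error(pool_scores(dup, 2), "more than one subset")
})

test_that("scores pool across disjoint subsets with direction = sign", {
  rs <- list(fake_result(c(g1 = -0.8, g2 = 0.05), "s1"),
             fake_result(c(g3 = 0.1, g4 = -0.02), "s2"))
  tab <- pool_scores(rs, k_sd = 1)
  expect_setequal(tab$gene, c("g1", "g2", "g3", "g4"))
  expect_identical(tab$direction, sign(tab$score))
  expect_identical(tab$subset[tab$gene == "g3"], "s2")
  # sorted by decreasing |z|
  expect_true(all(diff(abs(tab$z)) <= 0))
})

test_that("perturbation-silhouette correlation matches closed forms", {
  expect_equal(correlate_perturbation_silhouette(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(correlate_perturbation_silhouette(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(correlate_perturbation_silhouette(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(round(correlate_perturbation_silhouette(c(1, 2, 3), c(1, 2, 4)), 4),
               0.982)
  expect_error(correlate_perturbation_silhouette(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(correlate_perturbation_silhouette(c(1, 2), c(1, 2)), "at least 3")
})

test_that("hypergeometric enrichment matches combinatorial identities", {
  bg <- paste0("g", 1:100)
  sets <- list(HIT = paste0("g", 1:10), MISS = paste0("g", 51:60))
  q10 <- paste0("g", 1:10)
  tab <- enrich(q10, sets["HIT"], bg)
  # query == set exactly: p = 1 / C(100, 10), and with one test q = p
  expect_equal(tab$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(tab$q, tab$p)

  tab2 <- enrich(q10, sets, bg)
  expect_equal(tab2$p[tab2$set == "MISS"], 1)
  expect_equal(tab2$overlap[tab2$set == "MISS"], 0)

  expect_error(enrich(c("g1", "not_in_bg"), sets, bg), "not in background")
  expect_error(enrich(q10, sets, character()), "non-empty")
})

test_that("BY-adjusted q values are monotone in rank and >= raw p", {
  set.seed(41)
  bg <- paste0("g", 1:200)
  sets <- lapply(1:12, function(i) sample(bg, sample(5:30, 1)))
  names(sets) <- paste0("set", 1:12)
  query <- sample(bg, 25)
  tab <- enrich(query, sets, bg)
  expect_true(all(tab$q >= tab$p))
  expect_true(all(diff(tab$q) >= -1e-15))  # sorted by p: q nondecreasing
  # explicit step-up oracle: q_(i) = min_{j >= i} p_(j) * m * H(m) / j
  m <- length(tab$p)
  cm <- sum(1 / seq_len(m))
  q_oracle <- rev(cummin(rev(tab$p * m * cm / seq_len(m))))
  expect_equal(tab$q, pmin(q_oracle, 1), tolerance = 1e-12)
})

test_that("augmentation emits labeled non-negative samples per request", {
  tt <- tiny_trained()
  syn <- augment(tt$checkpoint, c(normal = 5, tumor = 7), seed = 2)
  expect_equal(nrow(syn$values), 12)
  expect_equal(sum(syn$labels == "normal"), 5)
  expect_equal(sum(syn$labels == "tumor"), 7)
  expect_true(all(syn$values >= 0))
  expect_identical(colnames(syn$values), tt$checkpoint$gene_ids)
  expect_error(augment(tt$checkpoint, c(elephant = 3)), "unknown label")
  # seeded determinism
  expect_identical(augment(tt$checkpoint, c(normal = 3), seed = 9)$values,
                   augment(tt$checkpoint, c(normal = 3), seed = 9)$values)
})

test_that("perturbation keeps row pairing and validates genes and labels", {
  tt <- tiny_trained()
  res <- perturb(tt$checkpoint, tt$sim$gem, "tumor", "normal",
                 n_ode_steps = 25L)
  n_tumor <- sum(tt$sim$gem$labels == "tumor")
  expect_equal(nrow(res$perturbed), n_tumor)
  expect_identical(dim(res$original), dim(res$perturbed))
  expect_identical(rownames(res$original), rownames(res$perturbed))
  expect_identical(unname(res$per_gene_direction),
                   unname(sign(res$per_gene_score)))
  # same-condition bridging is near-identity (reconstruction regime)
  rec <- perturb(tt$checkpoint, tt$sim$gem, "tumor", "tumor",
                 n_ode_steps = 25L)
  expect_lt(mean(abs(rec$per_gene_score)), 0.1)
  expect_lt(mean(abs(rec$per_gene_score)), mean(abs(res$per_gene_score)))

  wrong <- gem_subset(tt$sim$gem, genes = tt$checkpoint$gene_ids[1:4])
  expect_error(perturb(tt$checkpoint, wrong, "tumor", "normal"), "gene set")
  expect_error(perturb(tt$checkpoint, tt$sim$gem, "elephant", "normal"),
               "unknown")
})

test_that("perturbation artifacts serialize to TSV", {
  tt <- tiny_trained()
  res <- perturb(tt$checkpoint, tt$sim$gem, "tumor", "normal",
                 n_ode_steps = 10L)
  dir <- withr::local_tempdir()
  paths <- write_perturbation(res, dir)
  expect_true(all(file.exists(paths)))
  scores <- read.delim(paths[3])
  expect_identical(scores$gene, tt$checkpoint$gene_ids)
  expect_equal(scores$score, unname(res$per_gene_score), tolerance = 1e-12)
})
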