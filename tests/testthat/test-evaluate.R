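test_that("stratified folds are disjoint, exhaustive and balanced per class", {
  corp <- sample_corpus(synthetic_spec(preset = "tiny", D = 80, seed = 12))
  for (seed in c(1, 99)) {
    folds <- stratified_kfold(corp, folds = 4, seed = seed)
    test_ids <- unlist(lapply(folds, `[[`, "test"))
    expect_setequal(test_ids, seq_len(n_docs(corp)))
    expect_equal(length(test_ids), n_docs(corp))   # no overlaps
    for (f in folds) {
      expect_length(intersect(f$train, f$test), 0)
      expect_setequal(union(f$train, f$test), seq_len(n_docs(corp)))
      per_class <- table(corp$docs$label[f$test])
      overall <- table(corp$docs$label) / 4
      expect_true(all(abs(per_class - overall[names(per_class)]) <= 1))
    }
  }
  expect_identical(stratified_kfold(corp, folds = 4, seed = 5),
                   stratified_kfold(corp, folds = 4, seed = 5))
  expect_error(stratified_kfold(corp, folds = 25, seed = 1), "class")
})

test_that("balanced corpora split into equal test folds", {
  # 1060 balanced documents over 4 classes -> five test folds of 212
  ids <- sprintf("d%04d", 1:1060)
  voc <- hslda_vocabulary("a-x", "a")
  corp <- hslda_corpus(
    tibble::tibble(doc_id = ids, feature = "a", value = "a-x"),
    docs = tibble::tibble(doc_id = ids,
                          label = rep(c("A", "B", "C", "D"), each = 265)),
    vocabulary = voc, class_names = c("A", "B", "C", "D"))
  folds <- stratified_kfold(corp, folds = 5, seed = 3)
  expect_equal(vapply(folds, function(f) length(f$test), numeric(1)),
               rep(212, 5))
})

test_that("macro metrics match the hand-computed confusion table", {
  m <- macro_metrics(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                     c("a", "b"))
  expect_equal(m$metrics$accuracy, 75)
  expect_equal(m$per_class$precision, c(100, 200 / 3), tolerance = 1e-10)
  expect_equal(m$per_class$recall, c(50, 100))
  expect_equal(m$metrics$macro_f1, mean(c(200 / 3, 80)), tolerance = 1e-10)
  expect_equal(as.numeric(m$confusion), c(1, 0, 1, 2))

  perfect <- macro_metrics(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(unlist(perfect$metrics), setNames(rep(100, 4),
               names(perfect$metrics)))
  expect_true(all(perfect$confusion == diag(1, 2)))

  # all-one-class predictor on balanced two-class data
  degen <- macro_metrics(rep(c("x", "y"), 5), rep("x", 10), c("x", "y"))
  expect_equal(degen$metrics$accuracy, 50)
  expect_equal(degen$metrics$macro_recall, 50)

  expect_error(macro_metrics("a", c("a", "b"), c("a", "b")), "equal length")
})

test_that("macro metrics are equivariant under class relabeling", {
  set.seed(14)
  truth <- sample(c("a", "b", "c"), 60, TRUE)
  pred <- sample(c("a", "b", "c"), 60, TRUE)
  m1 <- macro_metrics(truth, pred, c("a", "b", "c"))
  swap <- c(a = "b", b = "c", c = "a")
  m2 <- macro_metrics(swap[truth], swap[pred], c("a", "b", "c"))
  expect_equal(m1$metrics, m2$metrics, tolerance = 1e-12)
  expect_equal(sum(m1$confusion), 60)
  expect_equal(rowSums(m1$confusion), table(factor(truth, c("a", "b", "c"))) |>
                 as.numeric() |> setNames(c("a", "b", "c")))
})

test_that("cross-validation is reproducible and supports leave-one-out", {
  corp <- sample_corpus(synthetic_spec(preset = "tiny", D = 20,
                                       tokens_per_doc = c(4, 6), C = 2,
                                       seed = 61))
  corp$docs$label <- rep(c("C1", "C2"), 10)   # balanced for stratification
  cfg <- hslda_config(K = 2, em_max_iters = 3, e_step_max_iters = 10)
  cv <- suppressWarnings(cross_validate(corp, cfg, folds = 5, seed = 2))
  cv2 <- suppressWarnings(cross_validate(corp, cfg, folds = 5, seed = 2))
  expect_equal(cv$fold_metrics, cv2$fold_metrics, tolerance = 1e-12)
  expect_identical(cv$confusion, cv2$confusion)
  expect_equal(sum(cv$confusion), n_docs(corp))
  # leave-one-out boundary: folds = D gives singleton test folds
  loo_corp <- sample_corpus(synthetic_spec(preset = "tiny", D = 10,
                                           tokens_per_doc = c(4, 6), C = 1,
                                           seed = 62))
  loo <- suppressWarnings(cross_validate(loo_corp, cfg, folds = 10, seed = 2))
  expect_equal(nrow(loo$fold_metrics), 10)
  expect_true(all(vapply(loo$folds, function(f) length(f$test),
                         numeric(1)) == 1))
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})

test_that("risk tiers rank topics by class coefficients", {
  corp <- tiny_corpus(seed = 71, D = 12)
  fit <- suppressWarnings(fit_hslda(corp, config = hslda_config(
    K = 2, seed = 1, em_max_iters = 3)))
  fit$params$eta[1, ] <- c(5, -5)
  rt <- risk_factor_table(fit, top_topics = 1, top_pairs = 3)
  r1 <- rt[rt$class == fit$class_names[1], ]
  expect_true(all(r1$topic[r1$tier == "high"] == 1))
  expect_true(all(r1$topic[r1$tier == "low"] == 2))
  expect_error(risk_factor_table(fit, top_topics = 2), "top_topics")

  # a point-mass value in the high-tier topic ranks first
  fit$params$beta[1, ] <- 1e-9
  b1 <- which(fit$params$value_feature == 1)
  fit$params$beta[1, b1] <- 0; fit$params$beta[1, b1[1]] <- 1
  for (f in seq_len(ncol(fit$params$pi))) {
    b <- which(fit$params$value_feature == f)
    fit$params$beta[1, b] <- fit$params$beta[1, b] /
      sum(fit$params$beta[1, b])
  }
  fit$params$pi[1, ] <- c(0.97, 0.01, 0.01, 0.01)
  rt2 <- risk_factor_table(fit, top_topics = 1, top_pairs = 3)
  top_high <- rt2[rt2$class == fit$class_names[1] & rt2$tier == "high", ]
  expect_equal(top_high$value[1], fit$vocabulary$value[b1[1]])
  expect_s3_class(autoplot(rt2), "ggplot")
})

test_that("a planted class-discriminative value surfaces in its high tier", {
  hits <- 0
  for (seed in 1:10) {
    spec <- synthetic_spec(preset = "tiny", D = 40, seed = seed)
    params <- sample_params(spec)
    # plant: the topic with the largest coefficient for class 1 puts 95%
    # of its block-1 mass on value 1, and strongly prefers feature 1
    k_star <- which.max(params$eta[1, ])
    b1 <- which(params$value_feature == 1)
    params$beta[k_star, b1] <- 0.05 / (length(b1) - 1)
    params$beta[k_star, b1[1]] <- 0.95
    params$pi[k_star, ] <- 0.1 / (ncol(params$pi) - 1)
    params$pi[k_star, 1] <- 0.9
    corp <- sample_corpus(spec, params)
    model <- structure(list(
      params = params, vocabulary = corp$vocabulary,
      class_names = corp$class_names, elbo_trace = numeric(0),
      config = hslda_config(K = spec$K), variant = "hierarchical",
      iterations = 0L, converged = TRUE, n_train = n_docs(corp)),
      class = "hslda_model")
    rt <- risk_factor_table(model, top_topics = 1, top_pairs = 5)
    high1 <- rt[rt$class == "C1" & rt$tier == "high", ]
    if (corp$vocabulary$value[b1[1]] %in% high1$value) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("shuffled labels drive cross-validated accuracy to chance", {
  corp <- sample_corpus(synthetic_spec(preset = "separable", D = 150,
                                       seed = 81))
  withr::with_seed(17, {
    corp$docs$label <- sample(corp$docs$label)
  })
  cv <- suppressWarnings(cross_validate(
    corp, hslda_config(K = 3, alpha = 0.5, em_max_iters = 10,
                       e_step_max_iters = 30),
    folds = 3, seed = 81))
  expect_lt(abs(cv$mean_metrics$accuracy - 100 / 3), 10)
})
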