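test_that("class weights equalize the weighted class masses", {
  expect_equal(class_weights(rep(c(0, 1), each = 50)), c("0" = 1, "1" = 1))
  # the 76/31 negative/positive training-split counts
  w <- class_weights(c(rep(0, 76), rep(1, 31)))
  expect_equal(w[["0"]], 107 / 152, tolerance = 1e-12)
  expect_equal(w[["1"]], 107 / 62, tolerance = 1e-12)
  expect_equal(76 * w[["0"]], 31 * w[["1"]], tolerance = 1e-9)  # equal masses
  # scale invariance
  expect_equal(class_weights(c(rep(0, 152), rep(1, 62))), w)
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("weighted BCE matches its closed forms and a scalar oracle", {
  expect_equal(weighted_bce(0.5, 1), log(2), ignore_attr = TRUE)
  expect_lt(weighted_bce(1 - 1e-12, 1), 1e-6)
  set.seed(21)
  w <- c("0" = 0.7, "1" = 1.6)
  for (i in 1:50) {
    p <- runif(1, 0.01, 0.99); y <- rbinom(1, 1, 0.5)
    # independent scalar recomputation
    expected <- -(if (y == 1) w[["1"]] * log(p) else w[["0"]] * log(1 - p))
    expect_equal(weighted_bce(p, y, w), expected, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("metrics match hand-computed confusion matrices", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(perfect), c(macro_f1 = 1, uar = 1, accuracy = 1,
                                  macro_precision = 1))
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$uar, (0.5 + 1.0) / 2)
  expect_equal(m$accuracy, 0.75)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
  expect_error(compute_metrics(c(0, 1), c(1)), "length")
  # degenerate: a class absent from y_true contributes zero
  m1 <- compute_metrics(c(1, 1), c(1, 1))
  expect_equal(m1$uar, 0.5)
})

test_that("metrics agree with the brute-force per-class oracle on random draws", {
  set.seed(22)
  for (r in 1:200) {
    n <- sample(2:40, 1)
    yt <- rbinom(n, 1, runif(1, 0.1, 0.9))
    yp <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- compute_metrics(yt, yp)
    exp <- oracle_metrics(yt, yp)
    for (m in names(got)) {
      expect_equal(got[[m]], unname(exp[[m]]), tolerance = 1e-12)
    }
  }
})

small_split <- function(corp) {
  ids <- vapply(corp$transcripts, `[[`, "", "id")
  list(train = ids[1:12], dev = ids[13:16], test = ids[17:20])
}

test_that("seeded training runs are exactly reproducible", {
  corp <- fx_small_corpus()
  splits <- small_split(corp)
  cfg <- model_config("similarity_mv", hidden_dim = 8, n_heads = 2)
  tc <- train_config(max_epochs = 3, threshold_grid = 0.4, patience = 5)
  f1 <- train_model(corp, splits, cfg, tc, seed = 0, spec = encoder_spec(dim = 16))
  f2 <- train_model(corp, splits, cfg, tc, seed = 0, spec = encoder_spec(dim = 16))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # loss is finite and positive from the very first epoch
  expect_true(all(is.finite(f1$history$train_loss)))
  expect_gt(f1$history$train_loss[1], 0)
})

test_that("training loss trends downward on synthetic data for every variant", {
  corp <- fx_small_corpus()
  splits <- small_split(corp)
  for (variant in c("similarity_baseline", "similarity_mv",
                    "kcg_baseline", "kcg_mv")) {
    cfg <- model_config(variant, hidden_dim = 8, n_heads = 2)
    tc <- train_config(max_epochs = 6, threshold_grid = 0.4, patience = 10,
                       learning_rate = 5e-3)
    fit <- train_model(corp, splits, cfg, tc, seed = 0,
                       spec = encoder_spec(dim = 16), n_topics = 3)
    h <- fit$history$train_loss
    expect_lt(mean(tail(h, 2)), mean(head(h, 2)))
  }
})

test_that("the protocol reports per-seed rows and exact aggregates", {
  corp <- fx_small_corpus()
  splits <- small_split(corp)
  cfg <- model_config("similarity_mv", hidden_dim = 8, n_heads = 2)
  tc <- train_config(max_epochs = 2, seeds = c(0L, 1L), threshold_grid = 0.4,
                     patience = 5)
  rep <- run_protocol(corp, splits, cfg, tc, spec = encoder_spec(dim = 16))
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_seed), 4L)  # 2 seeds x dev/test
  # aggregate mean equals the arithmetic mean of per-seed values
  for (sp in c("dev", "test")) {
    rows <- rep$per_seed[rep$per_seed$split == sp, ]
    agg <- rep$aggregate[rep$aggregate$split == sp, ]
    expect_equal(agg$mean[agg$metric == "macro_f1"], mean(rows$macro_f1),
                 tolerance = 1e-12)
    expect_equal(agg$sd[agg$metric == "uar"], sd(rows$uar), tolerance = 1e-12)
  }
  # duplicated seed -> zero standard deviation everywhere
  tc2 <- train_config(max_epochs = 2, seeds = c(3L, 3L), threshold_grid = 0.4,
                      patience = 5)
  rep2 <- run_protocol(corp, splits, cfg, tc2, spec = encoder_spec(dim = 16))
  expect_true(all(rep2$aggregate$sd == 0))
})

test_that("dev/test transcripts never influence fitted artifacts", {
  corp <- fx_small_corpus()
  splits <- small_split(corp)
  cfg <- model_config("kcg_mv", hidden_dim = 8, n_heads = 2)
  spec <- encoder_spec(dim = 16)
  full <- prepare_corpus(corp, splits$train, cfg, spec = spec, n_topics = 3)
  train_only <- corp
  train_only$transcripts <- corp$transcripts[
    vapply(corp$transcripts, `[[`, "", "id") %in% splits$train]
  reduced <- prepare_corpus(train_only, splits$train, cfg, spec = spec,
                            n_topics = 3)
  expect_identical(reduced$models$therapist$topic_word,
                   full$models$therapist$topic_word)
  expect_identical(reduced$models$patient$topic_word,
                   full$models$patient$topic_word)
  for (id in splits$train) {
    expect_identical(reduced$items[[id]]$Ahat, full$items[[id]]$Ahat)
  }
})

test_that("the fitted model exposes the usual S3 surface", {
  corp <- fx_small_corpus()
  splits <- small_split(corp)
  cfg <- model_config("similarity_mv", hidden_dim = 8, n_heads = 2)
  tc <- train_config(max_epochs = 2, threshold_grid = 0.4, patience = 5)
  fit <- train_model(corp, splits, cfg, tc, seed = 0, spec = encoder_spec(dim = 16))
  expect_s3_class(fit, "dialograph_model")
  expect_output(print(fit), "similarity_mv")
  expect_output(summary(fit), "class weights")
  co <- coef(fit)
  expect_equal(dim(co$classifier_weights), c(8L, 1L))
  probs <- predict(fit, corp$transcripts[1:3])
  expect_length(probs, 3L)
  expect_true(all(probs >= 0 & probs <= 1))
  cls <- predict(fit, corp$transcripts[[1]], type = "class")
  expect_true(cls %in% c(0L, 1L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model_params(fit, path)
  back <- load_model_params(path)
  expect_equal(back$params$clf_w, unname(fit$params$clf_w), tolerance = 1e-12)
})
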