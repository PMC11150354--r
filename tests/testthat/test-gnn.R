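rand_params <- function(names, dims, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_along(names)) {
      out[[names[i]]] <- matrix(rnorm(prod(dims[[i]])), dims[[i]][1], dims[[i]][2])
    }
    out
  })
}

test_that("GCN layer matches the closed form on a single self-looped node", {
  # one node, no edges: Ahat = 1, so output = relu(x W + b)
  x <- matrix(c(0.5, -0.2), 1)
  params <- list(gcn1_W = diag(2), gcn1_b = matrix(c(0.1, 0.1), 1))
  out <- gcn_forward(x, NULL, params, n_layers = 1)
  expect_equal(out, pmax(x + 0.1, 0), tolerance = 1e-12)
})

test_that("GCN forward matches a dense D^-1/2 (A+I) D^-1/2 X W oracle", {
  set.seed(9)
  n <- 5; d <- 4; h <- 3
  X <- matrix(rnorm(n * d), n, d)
  edges <- data.frame(from = c(1, 1, 2, 4), to = c(2, 3, 5, 5),
                      weight = runif(4, 0.2, 1))
  params <- rand_params(c("gcn1_W", "gcn1_b"), list(c(d, h), c(1, h)))
  out <- gcn_forward(X, edges, params, n_layers = 1)
  # independent dense recomputation
  A <- matrix(0, n, n)
  for (r in 1:4) {
    A[edges$from[r], edges$to[r]] <- edges$weight[r]
    A[edges$to[r], edges$from[r]] <- edges$weight[r]
  }
  A <- A + diag(n)
  Dm <- diag(1 / sqrt(rowSums(A)))
  expected <- Dm %*% A %*% Dm %*% X %*% params$gcn1_W
  expected <- pmax(sweep(expected, 2, params$gcn1_b, "+"), 0)
  expect_equal(out, expected, tolerance = 1e-6)
})

test_that("GCN is permutation equivariant", {
  set.seed(10)
  n <- 6; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  edges <- data.frame(from = c(1, 2, 4), to = c(2, 3, 5), weight = c(0.9, 0.8, 0.7))
  params <- rand_params(c("gcn1_W", "gcn1_b"), list(c(d, d), c(1, d)))
  out <- gcn_forward(X, edges, params, 1)
  perm <- sample(n)
  inv <- match(seq_len(n), perm)
  pe <- data.frame(from = inv[edges$from], to = inv[edges$to],
                   weight = edges$weight)
  out_p <- gcn_forward(X[perm, ], pe, params, 1)
  expect_equal(out_p, out[perm, ], tolerance = 1e-9)
})

test_that("the node encoder is a permutation-invariant set function", {
  d <- 8; h <- 8
  params <- rand_params(c("ne_Wq", "ne_Wk", "ne_Wv", "ne_Wo"),
                        list(c(d, h), c(d, h), c(d, h), c(h, h)), seed = 3)
  set.seed(4)
  S <- matrix(rnorm(5 * d), 5, d)
  out <- node_encoder(S, params, n_heads = 2)
  expect_equal(dim(out), c(1L, h))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(node_encoder(S[perm, ], params, 2), out, tolerance = 1e-9)
  # duplicated singleton equals the singleton (attention over identical rows)
  x <- S[1, , drop = FALSE]
  expect_equal(node_encoder(rbind(x, x), params, 2),
               node_encoder(x, params, 2), tolerance = 1e-9)
  expect_error(node_encoder(S[0, , drop = FALSE], params, 2), "empty")
})

test_that("attention readout matches a dense attention oracle and is invariant", {
  h <- 8
  params <- rand_params(c("ro_Wq", "ro_Wk", "ro_Wv", "ro_Wo"),
                        list(c(h, h), c(h, h), c(h, h), c(h, h)), seed = 5)
  set.seed(6)
  H <- matrix(rnorm(4 * h), 4, h)
  out <- attention_readout(H, params, n_heads = 2)
  oracle <- colMeans(oracle_mha(H, H, params$ro_Wq, params$ro_Wk,
                                params$ro_Wv, params$ro_Wo, 2))
  expect_equal(as.numeric(out), oracle, tolerance = 1e-6)
  expect_equal(attention_readout(H[c(4, 2, 1, 3), ], params, 2), out,
               tolerance = 1e-9)
  # singleton: a fixed transform of that node
  one <- attention_readout(H[1, , drop = FALSE], params, 2)
  expect_equal(as.numeric(one),
               as.numeric(H[1, , drop = FALSE] %*% params$ro_Wv %*% params$ro_Wo),
               tolerance = 1e-9)
})

test_that("cross-attention fusion is symmetric for identical views and respects shapes", {
  h <- 8
  params <- rand_params(c("va_Wq", "va_Wk", "va_Wv", "va_Wo",
                          "ca_Wq", "ca_Wk", "ca_Wv", "ca_Wo"),
                        rep(list(c(h, h)), 8), seed = 7)
  set.seed(8)
  H <- matrix(rnorm(3 * h), 3, h)
  fused <- mv_inter_att_mean(H, H, params, n_heads = 2)
  expect_equal(dim(fused), c(1L, h))
  # identical views + shared weights: both directions coincide, so the mean
  # equals either direction's summary
  one_dir <- colMeans(oracle_mha(
    oracle_mha(H, H, params$va_Wq, params$va_Wk, params$va_Wv, params$va_Wo, 2),
    oracle_mha(H, H, params$va_Wq, params$va_Wk, params$va_Wv, params$va_Wo, 2),
    params$ca_Wq, params$ca_Wk, params$ca_Wv, params$ca_Wo, 2))
  expect_equal(as.numeric(fused), one_dir, tolerance = 1e-6)
  # an empty view degrades to half the surviving self-attended summary
  empty <- matrix(0, 0, h)
  surv <- mv_inter_att_mean(H, empty, params, n_heads = 2)
  self_sum <- colMeans(oracle_mha(H, H, params$va_Wq, params$va_Wk,
                                  params$va_Wv, params$va_Wo, 2))
  expect_equal(as.numeric(surv), 0.5 * self_sum, tolerance = 1e-6)
  expect_error(mv_inter_att_mean(empty, empty, params, 2), "both views empty")
})

test_that("the classification head is the logistic of an affine map", {
  expect_equal(classify(matrix(0, 1, 3), matrix(0, 3, 1), 0), 0.5)
  z <- matrix(c(1, -2, 0.5), 1)
  w <- matrix(c(0.3, 0.1, -0.4), 3)
  expect_equal(classify(z, w, 0.2),
               1 / (1 + exp(-(1 * 0.3 - 2 * 0.1 + 0.5 * -0.4 + 0.2))),
               tolerance = 1e-12)
  # monotone in the logit
  expect_true(classify(z, w, 1) > classify(z, w, 0))
})

test_that("analytic gradients match finite differences for every variant", {
  corp <- fx_small_corpus()
  splits <- list(train = vapply(corp$transcripts[1:8], `[[`, "", "id"))
  w <- c("0" = 1, "1" = 1.5)
  for (variant in c("similarity_baseline", "similarity_mv",
                    "kcg_baseline", "kcg_mv")) {
    cfg <- model_config(variant, hidden_dim = 8, n_heads = 2, dropout = 0)
    prep <- prepare_corpus(corp, splits$train, cfg,
                           spec = encoder_spec(dim = 12), n_topics = 3)
    store <- init_model_params(cfg, 12, seed = 0)
    item <- prep$items[[1]]
    fl <- dialograph:::forward_loss(store, item, 1L, w, cfg)
    dialograph:::ad_backward(fl$tape, fl$loss)
    g <- dialograph:::ad_param_grads(fl$tape)
    # every trainable tensor receives some gradient (no detached branches)
    for (nm in names(store$values)) {
      expect_false(is.null(g[[nm]]), info = paste(variant, nm))
      expect_gt(max(abs(g[[nm]])), 0)
    }
    lossfn <- function() {
      dialograph:::forward_loss(store, item, 1L, w, cfg)$loss$value[1, 1]
    }
    set.seed(11)
    for (nm in names(store$values)) {
      v <- store$values[[nm]]
      for (i in sample(length(v), min(2, length(v)))) {
        eps <- 1e-5
        store$values[[nm]][i] <- v[i] + eps; lp <- lossfn()
        store$values[[nm]][i] <- v[i] - eps; lm <- lossfn()
        store$values[[nm]][i] <- v[i]
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][i], num, tolerance = 1e-3,
                     info = paste(variant, nm))
      }
    }
  }
})

test_that("all four variants produce one probability per synthetic transcript", {
  corp <- memo("shape_corpus", function() {
    generate_corpus(gen_params(n_transcripts = 50L, seed = 13L,
                               n_topics_per_transcript = c(2L, 4L)))
  })
  ids <- vapply(corp$transcripts, `[[`, "", "id")
  for (variant in c("similarity_baseline", "similarity_mv",
                    "kcg_baseline", "kcg_mv")) {
    cfg <- model_config(variant, hidden_dim = 8, n_heads = 2, dropout = 0)
    prep <- prepare_corpus(corp, ids[1:30], cfg,
                           spec = encoder_spec(dim = 12), n_topics = 3)
    store <- init_model_params(cfg, 12, seed = 1)
    probs <- dialograph:::predict_items(store, prep$items, cfg)
    expect_length(probs, 50L)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_true(all(is.finite(probs)))
  }
})
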