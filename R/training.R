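# Training and evaluation: class-weighted binary cross entropy, Adam,
# dev-set macro-F1 model selection, the multi-seed protocol, and the
# four-metric evaluation suite for imbalanced binary classification.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param max_epochs Epoch cap.
#' @param batch_size Transcripts per gradient step (gradients averaged over
#'   the batch).
#' @param seeds Seeds for the multi-run protocol (default five runs).
#' @param threshold_grid Similarity-threshold search grid, tuned on mean dev
#'   macro-F1 (similarity variants only).
#' @param patience Early-stop patience on dev macro-F1.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, max_epochs = 100L,
                         batch_size = 8L, seeds = 0:4,
                         threshold_grid = c(0.3, 0.4, 0.5, 0.6, 0.7),
                         patience = 20L) {
  stopifnot(learning_rate > 0, length(seeds) >= 1L, max_epochs >= 1L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seeds = as.integer(seeds),
                 threshold_grid = threshold_grid,
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Per-class loss weights for imbalanced training
#'
#' `weight_c = N / (2 * N_c)`, so each class contributes equal total mass to
#' the weighted loss; a balanced set yields weights (1, 1).
#'
#' @param labels Binary training labels (0/1), both classes present.
#' @return Named numeric `c("0" = w0, "1" = w1)`.
#' @export
class_weights <- function(labels) {
  labels <- as.integer(labels)
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    stop("configuration error: both classes must be present in the training labels")
  }
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Class-weighted binary cross entropy
#'
#' `-w_y * (y log p + (1 - y) log(1 - p))` with the probability clamped away
#' from 0 and 1.
#'
#' @param prob Predicted probabilities in \[0, 1\].
#' @param label Binary labels (0/1), recycled against `prob`.
#' @param weights Per-class weights from [class_weights()] (default
#'   unweighted).
#' @param eps Clamping epsilon.
#' @return Non-negative loss values.
#' @export
weighted_bce <- function(prob, label, weights = c("0" = 1, "1" = 1),
                         eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  y <- as.numeric(label)
  w <- ifelse(y == 1, weights[["1"]], weights[["0"]])
  -w * (y * log(p) + (1 - y) * log(1 - p))
}

#' Evaluation metrics for imbalanced binary classification
#'
#' Macro-F1 (unweighted mean of per-class F1), UAR (unweighted average
#' recall, the mean of per-class recalls), accuracy, and macro precision.
#' A class absent from `y_true` (or an undefined precision) contributes 0 to
#' its per-class term.
#'
#' @param y_true,y_pred Equal-length binary vectors.
#' @return Named list `macro_f1`, `uar`, `accuracy`, `macro_precision`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("compute_metrics: empty inputs")
  if (length(y_true) != length(y_pred)) stop("compute_metrics: length mismatch")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("compute_metrics: labels must be binary 0/1")
  }
  prec <- rec <- f1 <- numeric(2L)
  for (c in c(0L, 1L)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    prec[c + 1L] <- if (tp + fp > 0L) tp / (tp + fp) else 0
    rec[c + 1L] <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1[c + 1L] <- if (prec[c + 1L] + rec[c + 1L] > 0) {
      2 * prec[c + 1L] * rec[c + 1L] / (prec[c + 1L] + rec[c + 1L])
    } else 0
  }
  list(macro_f1 = mean(f1), uar = mean(rec),
       accuracy = mean(y_true == y_pred), macro_precision = mean(prec))
}

## ---- corpus preparation ----------------------------------------------------

# Turn a corpus into per-transcript tensors for the chosen variant. All
# corpus-level artifacts (topic models) are fitted on the TRAIN split only.
# Returns list(items = named list of preps, input_dim, labels, models).
#' Prepare a corpus for training a graph classifier
#'
#' Encodes every utterance, fits any corpus-level artifacts (NMF topic
#' models for the keyword-graph variants) on the training split only, and
#' builds the per-transcript graph of the requested variant.
#'
#' @param corpus A corpus (list with `transcripts`).
#' @param train_ids Ids of the training split (topic models see only these).
#' @param config A [model_config()].
#' @param spec Sentence [encoder_spec()].
#' @param similarity_threshold Cosine threshold for similarity graphs.
#' @param kcg_threshold Edge threshold for keyword graphs.
#' @param k Keyword budget per graph.
#' @param n_topics Topics per NMF model.
#' @param topic_seed Seed for NMF fits.
#' @return A `prepared_corpus` list: `items` (per-id model inputs),
#'   `labels`, `input_dim`, fitted `models`, and the settings used.
#' @export
prepare_corpus <- function(corpus, train_ids, config,
                           spec = encoder_spec(dim = 64L),
                           similarity_threshold = 0.5, kcg_threshold = 0.0,
                           k = 50L, n_topics = 10L, topic_seed = 0L) {
  ids <- corpus_ids(corpus)
  stopifnot(all(train_ids %in% ids))
  embeddings <- lapply(corpus$transcripts, function(tr) {
    encode_sentences(tr$utterances$text, spec)
  })
  names(embeddings) <- ids
  models <- list()
  if (is_kcg_variant(config)) {
    train_tr <- corpus$transcripts[ids %in% train_ids]
    if (config$variant == "kcg_baseline") {
      sent <- unlist(lapply(train_tr, function(tr) tr$utterances$text))
      models$global <- fit_topic_model(sent, n_topics, topic_seed)
    } else {
      sent_t <- unlist(lapply(train_tr, function(tr) {
        tr$utterances$text[tr$utterances$speaker == "therapist"]
      }))
      sent_p <- unlist(lapply(train_tr, function(tr) {
        tr$utterances$text[tr$utterances$speaker == "patient"]
      }))
      models$therapist <- fit_topic_model(sent_t, n_topics, topic_seed)
      models$patient <- fit_topic_model(sent_p, n_topics, topic_seed + 1L)
    }
  }
  items <- lapply(seq_along(ids), function(i) {
    prepare_transcript(corpus$transcripts[[i]], embeddings[[i]], config,
                       models, spec, similarity_threshold, kcg_threshold, k)
  })
  names(items) <- ids
  structure(list(items = items, labels = corpus_labels(corpus),
                 input_dim = spec$dim, models = models, spec = spec,
                 config = config, similarity_threshold = similarity_threshold,
                 kcg_threshold = kcg_threshold, k = k),
            class = "prepared_corpus")
}

prepare_transcript <- function(transcript, emb, config, models, spec,
                               similarity_threshold, kcg_threshold, k) {
  u <- transcript$utterances
  row_of <- function(idx) match(idx, u$index)
  switch(config$variant,
    similarity_baseline = {
      g <- build_similarity_graph(emb, similarity_threshold)
      e <- g$edges
      e$from <- row_of(e$from); e$to <- row_of(e$to)
      list(Ahat = normalized_adjacency(nrow(u), e), X = emb, empty = nrow(u) == 0L)
    },
    similarity_mv = {
      mvg <- suppressWarnings(
        build_mv_similarity_graph(transcript, emb,
                                  threshold_t = similarity_threshold))
      order_ids <- c(mvg$therapist$node_ids, mvg$patient$node_ids)
      pos_of <- function(idx) match(idx, order_ids)
      et <- mvg$therapist$edges; ep <- mvg$patient$edges; ec <- mvg$cross_edges
      edges <- rbind(
        data.frame(from = pos_of(et$from), to = pos_of(et$to), weight = et$weight),
        data.frame(from = pos_of(ep$from), to = pos_of(ep$to), weight = ep$weight),
        data.frame(from = pos_of(ec$from), to = pos_of(ec$to), weight = ec$weight))
      nt <- length(mvg$therapist$node_ids); np <- length(mvg$patient$node_ids)
      list(Ahat = normalized_adjacency(nt + np, edges),
           X = emb[row_of(order_ids), , drop = FALSE],
           view_rows = list(therapist = seq_len(nt),
                            patient = if (np > 0L) nt + seq_len(np) else integer(0)),
           empty = nt + np == 0L)
    },
    kcg_baseline = {
      g <- build_kcg(transcript, models$global, emb, k, kcg_threshold, spec)
      m <- nrow(g$nodes)
      sets_emb <- lapply(g$sentence_sets, function(s) {
        emb[row_of(s), , drop = FALSE]
      })
      list(Ahat = if (m > 0L) normalized_adjacency(m, g$edges) else NULL,
           sets_emb = sets_emb, empty = m == 0L)
    },
    kcg_mv = {
      g <- build_kcg_mv(transcript, models$therapist, models$patient, emb,
                        k = k, kcg_threshold = kcg_threshold, spec = spec)
      mt <- nrow(g$therapist$nodes); mp <- nrow(g$patient$nodes)
      et <- g$therapist$edges; ep <- g$patient$edges; ec <- g$cross_edges
      edges <- rbind(
        et,
        data.frame(from = ep$from + mt, to = ep$to + mt, weight = ep$weight),
        data.frame(from = ec$from, to = ec$to + mt, weight = ec$weight))
      sets_emb <- c(
        lapply(g$therapist$sentence_sets, function(s) emb[row_of(s), , drop = FALSE]),
        lapply(g$patient$sentence_sets, function(s) emb[row_of(s), , drop = FALSE]))
      list(Ahat = if (mt + mp > 0L) normalized_adjacency(mt + mp, edges) else NULL,
           sets_emb = sets_emb,
           view_rows = list(therapist = seq_len(mt),
                            patient = if (mp > 0L) mt + seq_len(mp) else integer(0)),
           empty = mt + mp == 0L)
    },
    stop("unknown variant: ", config$variant))
}

## ---- forward / loss / prediction ------------------------------------------

store_getter <- function(tape, store) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    nd <- cache[[name]]
    if (is.null(nd)) {
      nd <- ad_param(tape, store, name)
      cache[[name]] <- nd
    }
    nd
  }
}

dropout_masks_for <- function(prep, config) {
  if (config$dropout <= 0) return(NULL)
  n <- if (is.null(prep$X)) length(prep$sets_emb) else nrow(prep$X)
  h <- config$hidden_dim
  lapply(seq_len(config$n_gcn_layers), function(l) {
    keep <- matrix(stats::rbinom(n * h, 1L, 1 - config$dropout), n, h)
    keep / (1 - config$dropout)
  })
}

# Forward + weighted BCE for one transcript; returns list(tape, prob, loss).
forward_loss <- function(store, prep, label, weights, config,
                         training = FALSE, eps = 1e-7) {
  tape <- ad_tape()
  getp <- store_getter(tape, store)
  masks <- if (training) dropout_masks_for(prep, config) else NULL
  prob <- tape_forward(tape, getp, prep, config, masks)
  w <- if (label == 1L) weights[["1"]] else weights[["0"]]
  term <- if (label == 1L) {
    ad_log(tape, ad_affine_const(tape, prob, add = eps))
  } else {
    ad_log(tape, ad_affine_const(tape, prob, mult = -1, add = 1 + eps))
  }
  loss <- ad_affine_const(tape, term, mult = -w)
  list(tape = tape, prob = prob$value[1L], loss = loss)
}

predict_items <- function(store, items, config) {
  vapply(items, function(prep) {
    if (isTRUE(prep$empty)) return(0.5)
    tape <- ad_tape()
    getp <- store_getter(tape, store)
    tape_forward(tape, getp, prep, config)$value[1L]
  }, numeric(1L))
}

eval_split <- function(store, prepared, ids, config, threshold = 0.5,
                       weights = c("0" = 1, "1" = 1)) {
  probs <- predict_items(store, prepared$items[ids], config)
  y <- prepared$labels[ids]
  out <- compute_metrics(y, as.integer(probs >= threshold))
  out$loss <- mean(weighted_bce(probs, y, weights))
  out
}

## ---- training --------------------------------------------------------------

#' Train a graph classifier on a prepared or raw corpus
#'
#' Optimizes the class-weighted binary cross entropy with Adam, evaluates
#' dev macro-F1 after each epoch, and restores the parameters of the best
#' dev epoch at the end (early stopping on patience). Decisions are made at
#' probability 0.5.
#'
#' @param corpus A corpus, or a `prepared_corpus` from [prepare_corpus()].
#' @param splits Named list `train`, `dev`, `test` of transcript ids
#'   (disjoint).
#' @param config A [model_config()].
#' @param tconfig A [train_config()] (its first seed is used).
#' @param seed Training seed (initialization, shuffling, dropout); defaults
#'   to the first entry of `tconfig$seeds`.
#' @param similarity_threshold,... Passed to [prepare_corpus()] when
#'   `corpus` is raw.
#' @return A `dialograph_model` fit: parameters, config, per-epoch history,
#'   dev/test metrics at the best epoch, and the preparation artifacts
#'   needed by `predict()`.
#' @export
train_model <- function(corpus, splits, config, tconfig = train_config(),
                        seed = tconfig$seeds[1L],
                        similarity_threshold = 0.5, ...) {
  prepared <- if (inherits(corpus, "prepared_corpus")) corpus else {
    prepare_corpus(corpus, splits$train, config,
                   similarity_threshold = similarity_threshold, ...)
  }
  stopifnot(length(intersect(splits$train, splits$dev)) == 0L,
            length(intersect(splits$train, splits$test)) == 0L,
            length(intersect(splits$dev, splits$test)) == 0L)
  labels <- prepared$labels
  weights <- class_weights(labels[splits$train])
  store <- init_model_params(config, prepared$input_dim, seed = seed)
  history <- data.frame()
  best <- list(macro_f1 = -Inf, loss = Inf, values = store$values, epoch = 0L)
  wait <- 0L
  withr::with_seed(as.integer(seed) + 1L, {
    for (epoch in seq_len(tconfig$max_epochs)) {
      order_ids <- sample(splits$train)
      epoch_loss <- 0
      batches <- split(order_ids,
                       ceiling(seq_along(order_ids) / tconfig$batch_size))
      for (batch in batches) {
        grads <- NULL
        for (id in batch) {
          prep <- prepared$items[[id]]
          if (isTRUE(prep$empty)) next
          fl <- forward_loss(store, prep, labels[[id]], weights, config,
                             training = TRUE)
          if (!is.finite(fl$loss$value[1L])) {
            stop("non-finite loss at epoch ", epoch, ", transcript ", id)
          }
          epoch_loss <- epoch_loss + fl$loss$value[1L]
          ad_backward(fl$tape, fl$loss)
          g <- ad_param_grads(fl$tape)
          grads <- if (is.null(grads)) g else {
            for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
            grads
          }
        }
        if (is.null(grads)) next
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(batch)
        adam_step(store, grads, lr = tconfig$learning_rate)
      }
      dev_m <- eval_split(store, prepared, splits$dev, config,
                          weights = weights)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / length(order_ids),
        dev_macro_f1 = dev_m$macro_f1, dev_loss = dev_m$loss,
        dev_uar = dev_m$uar, dev_accuracy = dev_m$accuracy,
        dev_macro_precision = dev_m$macro_precision))
      improved <- dev_m$macro_f1 > best$macro_f1 + 1e-12
      tied_better <- abs(dev_m$macro_f1 - best$macro_f1) <= 1e-12 &&
        dev_m$loss < best$loss - 1e-12
      if (improved || tied_better) {
        # dev macro-F1 selects the checkpoint; dev loss breaks ties, so a
        # barely-trained epoch that happens to hit the same small-dev score
        # as a converged one is not kept
        best <- list(macro_f1 = dev_m$macro_f1, loss = dev_m$loss,
                     values = store$values, epoch = epoch)
        if (improved) wait <- 0L else wait <- wait + 1L
      } else {
        wait <- wait + 1L
        if (wait >= tconfig$patience) break
      }
    }
  })
  store$values <- best$values
  fit <- structure(
    list(params = best$values, config = config, tconfig = tconfig,
         seed = seed, history = history, best_epoch = best$epoch,
         class_weights = weights,
         similarity_threshold = prepared$similarity_threshold,
         kcg_threshold = prepared$kcg_threshold, k = prepared$k,
         models = prepared$models, spec = prepared$spec,
         input_dim = prepared$input_dim, splits = splits,
         dev_metrics = eval_split(store, prepared, splits$dev, config)[
           c("macro_f1", "uar", "accuracy", "macro_precision")],
         test_metrics = eval_split(store, prepared, splits$test, config)[
           c("macro_f1", "uar", "accuracy", "macro_precision")]),
    class = "dialograph_model")
  fit
}

#' @export
print.dialograph_model <- function(x, ...) {
  cat(sprintf("<dialograph_model: %s, hidden %d, best dev epoch %d>\n",
              x$config$variant, x$config$hidden_dim, x$best_epoch))
  cat(sprintf("  dev  macro-F1 %.3f | UAR %.3f | acc %.3f | macro-P %.3f\n",
              x$dev_metrics$macro_f1, x$dev_metrics$uar,
              x$dev_metrics$accuracy, x$dev_metrics$macro_precision))
  cat(sprintf("  test macro-F1 %.3f | UAR %.3f | acc %.3f | macro-P %.3f\n",
              x$test_metrics$macro_f1, x$test_metrics$uar,
              x$test_metrics$accuracy, x$test_metrics$macro_precision))
  invisible(x)
}

#' @export
summary.dialograph_model <- function(object, ...) {
  cat("Graph-based depression classifier\n")
  cat("  variant:            ", object$config$variant, "\n")
  cat("  hidden dim / heads: ", object$config$hidden_dim, "/",
      object$config$n_heads, "\n")
  cat("  GCN layers:         ", object$config$n_gcn_layers, "\n")
  cat("  similarity thresh.: ", object$similarity_threshold, "\n")
  cat("  class weights:      ",
      sprintf("neg %.3f / pos %.3f", object$class_weights[["0"]],
              object$class_weights[["1"]]), "\n")
  cat("  epochs trained:     ", nrow(object$history),
      sprintf("(best dev epoch %d)", object$best_epoch), "\n")
  print(object)
  invisible(object)
}

#' @export
coef.dialograph_model <- function(object, ...) {
  list(classifier_weights = object$params$clf_w,
       classifier_bias = object$params$clf_b[1L, 1L])
}

#' Predict depression probabilities for transcripts
#'
#' Rebuilds each transcript's graph with the fit's stored artifacts (encoder
#' spec, thresholds, topic models) and runs the trained network.
#'
#' @param object A `dialograph_model`.
#' @param transcripts A list of `transcript`s, a single `transcript`, or a
#'   corpus.
#' @param type `"prob"` for probabilities, `"class"` for 0/1 decisions at
#'   0.5.
#' @param ... Unused.
#' @return Named numeric (or integer) vector, one entry per transcript.
#' @export
predict.dialograph_model <- function(object, transcripts,
                                     type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  if (!is.null(transcripts$transcripts)) transcripts <- transcripts$transcripts
  store <- param_store(object$params)
  probs <- vapply(transcripts, function(tr) {
    emb <- encode_sentences(tr$utterances$text, object$spec)
    prep <- prepare_transcript(tr, emb, object$config, object$models,
                               object$spec, object$similarity_threshold,
                               object$kcg_threshold, object$k)
    if (isTRUE(prep$empty)) return(0.5)
    predict_items(store, list(prep), object$config)
  }, numeric(1L))
  names(probs) <- vapply(transcripts, function(tr) tr$id, character(1L))
  if (type == "class") as.integer(probs >= 0.5) else probs
}

#' Plot the dev macro-F1 learning curve
#'
#' @param x A `dialograph_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dialograph_model <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$dev_macro_f1, type = "b",
                 xlab = "epoch", ylab = "dev macro-F1",
                 main = paste0(x$config$variant, " learning curve"), ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

## ---- multi-seed protocol ---------------------------------------------------

#' Multi-seed training and evaluation protocol
#'
#' Tunes the similarity threshold once on mean dev macro-F1 over the grid,
#' then trains one model per seed at the selected threshold and reports
#' per-seed and aggregated (mean and standard deviation) metrics on the dev
#' and test splits.
#'
#' @param corpus A corpus.
#' @param splits Named split id lists.
#' @param config A [model_config()].
#' @param tconfig A [train_config()]; `tconfig$seeds` drives the runs and
#'   `tconfig$threshold_grid` the tuning (a length-1 grid skips tuning).
#' @param ... Passed to [prepare_corpus()].
#' @return An `eval_report`: `per_seed` data frame, `aggregate` data frame
#'   (mean/sd per metric and split), `best_threshold`, `variant`, and the
#'   per-seed fitted models.
#' @export
run_protocol <- function(corpus, splits, config, tconfig = train_config(), ...) {
  grid <- if (is_kcg_variant(config)) tconfig$threshold_grid[1L] else
    tconfig$threshold_grid
  runs_by_threshold <- lapply(grid, function(th) {
    prepared <- prepare_corpus(corpus, splits$train, config,
                               similarity_threshold = th, ...)
    lapply(tconfig$seeds, function(s) {
      train_model(prepared, splits, config, tconfig, seed = s)
    })
  })
  mean_dev <- vapply(runs_by_threshold, function(runs) {
    mean(vapply(runs, function(f) f$dev_metrics$macro_f1, numeric(1L)))
  }, numeric(1L))
  sel <- which.max(mean_dev)
  fits <- runs_by_threshold[[sel]]
  per_seed <- do.call(rbind, lapply(fits, function(f) {
    rbind(
      data.frame(seed = f$seed, split = "dev", as.data.frame(f$dev_metrics)),
      data.frame(seed = f$seed, split = "test", as.data.frame(f$test_metrics)))
  }))
  metrics <- c("macro_f1", "uar", "accuracy", "macro_precision")
  aggregate <- do.call(rbind, lapply(c("dev", "test"), function(sp) {
    rows <- per_seed[per_seed$split == sp, ]
    data.frame(split = sp, metric = metrics,
               mean = vapply(metrics, function(m) mean(rows[[m]]), numeric(1L)),
               sd = vapply(metrics, function(m) stats::sd(rows[[m]]), numeric(1L)),
               row.names = NULL)
  }))
  aggregate$sd[is.na(aggregate$sd)] <- 0
  structure(list(per_seed = per_seed, aggregate = aggregate,
                 best_threshold = grid[sel], variant = config$variant,
                 fits = fits),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %s, %d seeds, threshold %.2f>\n",
              x$variant, length(unique(x$per_seed$seed)), x$best_threshold))
  agg <- x$aggregate
  for (sp in c("dev", "test")) {
    rows <- agg[agg$split == sp, ]
    cat(sprintf("  %-4s %s\n", sp, paste(
      sprintf("%s %.3f±%.3f", rows$metric, rows$mean, rows$sd),
      collapse = " | ")))
  }
  invisible(x)
}

#' Write an evaluation report to CSV and JSON
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_seed, file.path(dir, "per_seed.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregate, file.path(dir, "aggregate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(variant = report$variant, best_threshold = report$best_threshold,
         aggregate = report$aggregate),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
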