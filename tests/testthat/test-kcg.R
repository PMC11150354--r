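# Two disjoint 10-word vocabularies used to build separable topic corpora.
voc_a <- paste0("alpha", 1:10)
voc_b <- paste0("bravo", 1:10)

two_topic_corpus <- function(n_per = 20L, seed = 1L) {
  withr::with_seed(seed, {
    c(replicate(n_per, paste(sample(voc_a, 5, replace = TRUE), collapse = " ")),
      replicate(n_per, paste(sample(voc_b, 5, replace = TRUE), collapse = " ")))
  })
}

test_that("NMF recovers two disjoint-vocabulary topics", {
  sent <- two_topic_corpus()
  tm <- fit_topic_model(sent, n_topics = 2, seed = 0)
  rep <- topic_report(tm, n_words = 5)
  for (t in 0:1) {
    words <- rep$word[rep$topic == t]
    from_a <- mean(words %in% voc_a)
    expect_true(from_a == 1 || from_a == 0)  # each topic pure in one vocabulary
  }
  # the two topics cover different vocabularies
  top_a <- rep$word[rep$topic == 0][1] %in% voc_a
  top_b <- rep$word[rep$topic == 1][1] %in% voc_a
  expect_false(top_a == top_b)
})

test_that("NMF factors are non-negative and fits are deterministic", {
  sent <- two_topic_corpus()
  tm1 <- fit_topic_model(sent, n_topics = 3, seed = 4)
  tm2 <- fit_topic_model(sent, n_topics = 3, seed = 4)
  expect_true(all(tm1$topic_word >= 0))
  expect_identical(tm1$topic_word, tm2$topic_word)
  expect_error(fit_topic_model(c("xyz abc", "def ghi"), n_topics = 2),
               "vectorization error")
})

test_that("keyword scores are restricted to transcript words and respect the cap", {
  sent <- two_topic_corpus()
  tm <- fit_topic_model(sent, n_topics = 2, seed = 0)
  tr <- h_transcript(c("t", "p", "t", "p"),
                     c(paste(voc_a[1:5], collapse = " "),
                       paste(voc_a[3:8], collapse = " "),
                       paste(voc_a[c(1, 9)], collapse = " "),
                       paste(voc_a[10], voc_a[2])))
  kws <- score_keywords(tr, tm, k = 50)
  expect_true(all(kws$keyword %in% voc_a))  # topic-A transcript, topic-A words
  expect_equal(nrow(kws), 10L)  # fewer eligible words than k
  expect_true(all(diff(kws$score) <= 1e-12))  # ranked best-first
  # brute-force score recomputation: loading . topic_word column
  v <- dialograph:::transcript_term_vector(tr, tm)
  load <- pracma::lsqnonneg(t(tm$topic_word), v)$x
  for (i in seq_len(nrow(kws))) {
    col <- match(kws$keyword[i], tm$vocabulary)
    expect_equal(kws$score[i], sum(load * tm$topic_word[, col]),
                 tolerance = 1e-9)
  }
  # default keyword budget is the 50-node graph cap
  expect_equal(formals(score_keywords)$k, 50L)
  # disjoint transcript -> empty result with a warning
  trb <- h_transcript(c("t", "p"), c("zulu yankee", "xray whiskey"))
  expect_warning(out <- score_keywords(trb, tm), "no vocabulary")
  expect_equal(nrow(out), 0L)
})

test_that("sentence assignment is containment-first with embedding fallback", {
  tr <- h_transcript(c("t", "p", "p"),
                     c("alpha1 alpha3 extra", "alpha2 words here", "nothing shared"))
  kws <- data.frame(keyword = c("alpha1", "alpha2", "alpha3"),
                    score = c(3, 2, 1))
  spec <- encoder_spec(dim = 32)
  emb <- encode_sentences(tr$utterances$text, spec)
  sets <- assign_sentences(tr, kws, emb, spec)
  # utterance 0 contains ranks 1 and 3 -> goes to rank 1
  expect_true(0L %in% sets[["alpha1"]])
  expect_true(1L %in% sets[["alpha2"]])
  # utterance 2 contains no keyword: fallback must equal brute-force argmax
  kw_emb <- encode_sentences(kws$keyword, spec)
  sims <- vapply(1:3, function(j) oracle_cosine(emb[3, ], kw_emb[j, ]),
                 numeric(1))
  winner <- kws$keyword[which.max(sims)]
  expect_true(2L %in% sets[[winner]])
  # partition: every utterance in exactly one set
  expect_setequal(unlist(sets), tr$utterances$index)
  expect_equal(length(unlist(sets)), nrow(tr$utterances))
  # single keyword absorbs everything
  sets1 <- assign_sentences(tr, kws[1, ], emb, spec)
  expect_setequal(sets1[["alpha1"]], tr$utterances$index)
})

test_that("KCG edge weights are mean pairwise cosines between sentence sets", {
  sent <- two_topic_corpus()
  tm <- fit_topic_model(sent, n_topics = 2, seed = 0)
  spec <- encoder_spec(dim = 32)
  # two nodes, each holding one identical sentence -> weight 1
  tr <- h_transcript(c("t", "p"), c("alpha1 alpha1", "alpha2 alpha2"))
  emb <- rbind(deterministic_embed("same text", 32), deterministic_embed("same text", 32))
  g <- build_kcg(tr, tm, emb, spec = spec)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(g$edges$weight, 1, tolerance = 1e-9)
  # a threshold above 1 removes every edge
  g0 <- build_kcg(tr, tm, emb, kcg_threshold = 1.1, spec = spec)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("KCG edge weights match an independent double loop on sets of size 2 and 3", {
  sent <- two_topic_corpus()
  tm <- fit_topic_model(sent, n_topics = 2, seed = 0)
  spec <- encoder_spec(dim = 16)
  tr <- h_transcript(c("t", "p", "t", "p", "t"),
                     c("alpha1 left one", "alpha1 left two",
                       "alpha2 right one", "alpha2 right two", "alpha2 right three"))
  emb <- encode_sentences(tr$utterances$text, spec)
  g <- build_kcg(tr, tm, emb, spec = spec)
  expect_equal(sort(unname(vapply(g$sentence_sets, length, integer(1)))),
               c(2L, 3L))
  set_a <- g$sentence_sets[[1]]; set_b <- g$sentence_sets[[2]]
  acc <- 0
  for (s in set_a) for (t in set_b) {
    acc <- acc + oracle_cosine(emb[s + 1, ], emb[t + 1, ])
  }
  expect_equal(g$edges$weight, acc / (length(set_a) * length(set_b)),
               tolerance = 1e-9)
})

test_that("per-view KCGs with QA-presence cross edges match the exhaustive oracle", {
  corp <- fx_small_corpus()
  ids <- vapply(corp$transcripts, function(t) t$id, character(1))
  train_ids <- ids[1:12]
  spec <- encoder_spec(dim = 16)
  train_tr <- corp$transcripts[1:12]
  tm_t <- fit_topic_model(unlist(lapply(train_tr, function(t) {
    t$utterances$text[t$utterances$speaker == "therapist"]
  })), n_topics = 4, seed = 0)
  tm_p <- fit_topic_model(unlist(lapply(train_tr, function(t) {
    t$utterances$text[t$utterances$speaker == "patient"]
  })), n_topics = 4, seed = 1)
  for (tr in corp$transcripts[13:16]) {
    emb <- encode_sentences(tr$utterances$text, spec)
    qapairs <- pair_questions_answers(segment_turns(tr))
    g <- build_kcg_mv(tr, tm_t, tm_p, emb, k = 50, spec = spec)
    # oracle: enumerate (QAPair x node pair) combinations exhaustively
    expected <- list()
    for (p in qapairs) {
      for (q in p$question$utterance_indices) {
        for (a in p$answer$utterance_indices) {
          u <- which(vapply(g$therapist$sentence_sets,
                            function(s) q %in% s, logical(1)))
          v <- which(vapply(g$patient$sentence_sets,
                            function(s) a %in% s, logical(1)))
          if (length(u) == 1 && length(v) == 1) {
            expected[[paste(u, v)]] <- c(u, v)
          }
        }
      }
    }
    got <- paste(g$cross_edges$from, g$cross_edges$to)
    expect_setequal(got, names(expected))
    # per-view sentence sets partition the view utterances
    v <- split_views(tr)
    expect_setequal(unlist(g$therapist$sentence_sets), v$therapist)
    expect_setequal(unlist(g$patient$sentence_sets), v$patient)
    expect_lte(nrow(g$therapist$nodes), 50L)
    expect_lte(nrow(g$patient$nodes), 50L)
  }
})

test_that("removing the pairing removes all cross edges", {
  tr <- fx_small_corpus()$transcripts[[1]]
  spec <- encoder_spec(dim = 16)
  emb <- encode_sentences(tr$utterances$text, spec)
  train_tr <- fx_small_corpus()$transcripts[1:10]
  tm <- fit_topic_model(unlist(lapply(train_tr, function(t) t$utterances$text)),
                        n_topics = 4, seed = 0)
  g <- build_kcg_mv(tr, tm, tm, emb, qapairs = list(), spec = spec)
  expect_equal(nrow(g$cross_edges), 0L)
})

test_that("marker keywords rank among the top-50 keywords along class lines", {
  corp <- fx_default_corpus()
  labs <- vapply(corp$transcripts, `[[`, integer(1), "label")
  ids <- vapply(corp$transcripts, `[[`, "", "id")
  splits <- make_splits(corp, seed = 0)
  train_tr <- corp$transcripts[ids %in% splits$train]
  tm_p <- fit_topic_model(unlist(lapply(train_tr, function(t) {
    t$utterances$text[t$utterances$speaker == "patient"]
  })), n_topics = 10, seed = 0)
  markers <- corp$params$marker_keywords
  has_marker_kw <- vapply(corp$transcripts, function(tr) {
    sub <- dialograph:::subset_transcript(tr, split_views(tr)$patient)
    kws <- suppressWarnings(score_keywords(sub, tm_p, k = 50))
    any(markers %in% kws$keyword)
  }, logical(1))
  expect_gte(mean(has_marker_kw[labs == 1]), 0.9)
  expect_lte(mean(has_marker_kw[labs == 0]), 0.1)
})

test_that("topic models and keyword graphs serialize round trip", {
  sent <- two_topic_corpus()
  tm <- fit_topic_model(sent, n_topics = 2, seed = 0)
  path <- withr::local_tempfile(fileext = ".json")
  save_topic_model(tm, path)
  tm2 <- load_topic_model(path)
  expect_equal(tm2$topic_word, tm$topic_word, tolerance = 1e-12)
  expect_identical(tm2$vocabulary, tm$vocabulary)
})
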