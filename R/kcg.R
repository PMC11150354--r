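# Keyword correlation graphs: NMF topic models over sentence corpora,
# per-transcript keyword scoring, sentence-to-keyword assignment, and
# correlation-weighted keyword graphs in baseline and multi-view form.

#' Default English stop words
#'
#' Compact stop-word list used by the sentence-term vectorizer.
#' @return Character vector.
#' @export
default_stopwords <- function() {
  c("a", "about", "above", "after", "again", "all", "am", "an", "and", "any",
    "are", "as", "at", "be", "because", "been", "before", "being", "below",
    "between", "both", "but", "by", "can", "could", "did", "do", "does",
    "doing", "down", "during", "each", "few", "for", "from", "further", "had",
    "has", "have", "having", "he", "her", "here", "hers", "him", "his", "how",
    "i", "if", "in", "into", "is", "it", "its", "just", "me", "more", "most",
    "my", "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "out", "over", "own", "same", "she", "should",
    "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
    "then", "there", "these", "they", "this", "those", "through", "to", "too",
    "under", "until", "up", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with", "would",
    "you", "your", "yours")
}

tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9_']+")[[1L]]
  toks[nzchar(toks)]
}

# Sentence-term TF-IDF matrix with smooth idf (idf = log((1+n)/(1+df)) + 1)
# and L2-normalized rows. Stop words removed; words below min_df dropped.
vectorize_sentences <- function(sentences, stopwords = default_stopwords(),
                                min_df = 2L, vocabulary = NULL) {
  token_lists <- lapply(sentences, tokenize)
  token_lists <- lapply(token_lists, function(t) t[!t %in% stopwords])
  if (is.null(vocabulary)) {
    df_counts <- table(unlist(lapply(token_lists, unique)))
    vocabulary <- sort(names(df_counts)[df_counts >= min_df])
    if (length(vocabulary) == 0L) {
      stop("vectorization error: vocabulary empty after stop-word and ",
           "min_df filtering")
    }
    df <- as.numeric(df_counts[vocabulary])
  } else {
    df <- vapply(vocabulary, function(w) {
      sum(vapply(token_lists, function(t) w %in% t, logical(1L)))
    }, numeric(1L))
  }
  n <- length(sentences)
  X <- matrix(0, nrow = n, ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_len(n)) {
    tc <- table(token_lists[[i]][token_lists[[i]] %in% vocabulary])
    if (length(tc) > 0L) X[i, names(tc)] <- as.numeric(tc)
  }
  idf <- log((1 + n) / (1 + df)) + 1
  X <- sweep(X, 2L, idf, "*")
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm < 1e-12] <- 1
  list(X = X / nrm, vocabulary = vocabulary, df = df, idf = idf)
}

# Multiplicative-update NMF (Frobenius loss), deterministic given seed.
nmf_factorize <- function(X, k, seed, max_iter = 200L, tol = 1e-6) {
  n <- nrow(X); V <- ncol(X)
  scale <- sqrt(mean(X) / k)
  init <- withr::with_seed(as.integer(seed), {
    list(W = matrix(stats::runif(n * k), n, k) * scale,
         H = matrix(stats::runif(k * V), k, V) * scale)
  })
  W <- init$W; H <- init$H
  eps <- 1e-10
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      err <- sqrt(sum((X - W %*% H)^2))
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err_prev, 1e-12)) break
      err_prev <- err
    }
  }
  list(W = W, H = H)
}

#' Fit an NMF topic model over a sentence corpus
#'
#' Each sentence is treated as an individual document; the sentence-term
#' TF-IDF matrix is factorized with non-negative matrix factorization
#' (multiplicative updates), yielding a topic-by-word factor used downstream
#' to score keywords per transcript. Fit topic models on training-split
#' sentences only so that no dev/test information leaks into the
#' representation.
#'
#' @param sentences Character vector of training sentences.
#' @param n_topics Number of topics (>= 2).
#' @param seed Integer seed; fits are deterministic given the seed.
#' @param stopwords,min_df Vectorizer settings.
#' @param max_iter NMF iteration cap.
#' @return A `topic_model`: `vocabulary`, `topic_word` (n_topics x vocab,
#'   non-negative), `n_topics`, corpus document frequencies `df`, `idf`,
#'   and the vectorizer settings.
#' @export
fit_topic_model <- function(sentences, n_topics = 10L, seed = 0L,
                            stopwords = default_stopwords(), min_df = 2L,
                            max_iter = 200L) {
  stopifnot(n_topics >= 2L)
  vec <- vectorize_sentences(sentences, stopwords, min_df)
  if (nrow(vec$X) < n_topics) {
    stop("need at least n_topics sentences after vectorization (got ",
         nrow(vec$X), ")")
  }
  fac <- nmf_factorize(vec$X, n_topics, seed, max_iter)
  dimnames(fac$H) <- list(NULL, vec$vocabulary)
  structure(
    list(vocabulary = vec$vocabulary, topic_word = fac$H,
         n_topics = as.integer(n_topics), df = vec$df, idf = vec$idf,
         stopwords = stopwords, min_df = as.integer(min_df),
         seed = as.integer(seed)),
    class = "topic_model"
  )
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model: %d topics over %d words>\n",
              x$n_topics, length(x$vocabulary)))
  invisible(x)
}

#' Top words per topic
#'
#' @param model A `topic_model`.
#' @param n_words Words per topic.
#' @return Data frame `topic` (0-based), `rank`, `word`, `weight`.
#' @export
topic_report <- function(model, n_words = 10L) {
  do.call(rbind, lapply(seq_len(model$n_topics), function(t) {
    w <- model$topic_word[t, ]
    ord <- order(-w, model$vocabulary)[seq_len(min(n_words, length(w)))]
    data.frame(topic = t - 1L, rank = seq_along(ord),
               word = model$vocabulary[ord], weight = unname(w[ord]))
  }))
}

# Aggregated TF-IDF term vector of a transcript over the model vocabulary.
transcript_term_vector <- function(transcript, model) {
  toks <- unlist(lapply(transcript$utterances$text, tokenize))
  toks <- toks[toks %in% model$vocabulary]
  v <- numeric(length(model$vocabulary))
  names(v) <- model$vocabulary
  if (length(toks) > 0L) {
    tc <- table(toks)
    v[names(tc)] <- as.numeric(tc)
  }
  v * model$idf
}

#' Score a transcript's keywords under a topic model
#'
#' Word importance combines the transcript's topic loadings with the topic
#' model's word weights: the transcript's aggregated term vector is projected
#' non-negatively onto the fixed topic-word basis (non-negative least
#' squares), and each word occurring in the transcript scores the inner
#' product of that loading vector with its topic-word column. The top `k`
#' words by score become keyword-graph nodes; ties break by corpus document
#' frequency (higher first), then lexicographically.
#'
#' @param transcript A `transcript`.
#' @param model A fitted `topic_model`.
#' @param k Maximum number of keywords (default 50, the keyword-graph node
#'   budget).
#' @return Data frame `keyword`, `score`, ranked best-first; fewer than `k`
#'   rows when the transcript has fewer in-vocabulary words. Empty (with a
#'   warning) when the transcript shares no vocabulary with the model.
#' @export
score_keywords <- function(transcript, model, k = 50L) {
  v <- transcript_term_vector(transcript, model)
  present <- names(v)[v > 0]
  if (length(present) == 0L) {
    warning("transcript '", transcript$id,
            "' shares no vocabulary with the topic model")
    return(data.frame(keyword = character(0), score = numeric(0)))
  }
  H <- model$topic_word
  load <- pracma::lsqnonneg(t(H), v)$x  # topic loadings, >= 0
  score <- as.numeric(load %*% H[, present, drop = FALSE])
  df_present <- model$df[match(present, model$vocabulary)]
  ord <- order(-score, -df_present, present)
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(keyword = present[top], score = score[top])
}

#' Assign every utterance to exactly one keyword node
#'
#' Containment-first: an utterance containing one or more of the keywords is
#' assigned to the highest-scored contained keyword. Utterances containing
#' none are assigned to the keyword whose own embedding has maximal cosine
#' similarity to the utterance embedding (ties break by keyword rank). The
#' resulting sentence sets partition the utterances.
#'
#' @param transcript A `transcript`.
#' @param keywords Ranked keyword data frame from [score_keywords()].
#' @param embeddings Matrix, one row per utterance of `transcript`.
#' @param spec Encoder used to embed the keyword strings (must match the one
#'   that produced `embeddings`).
#' @return Named list: keyword -> integer vector of 0-based utterance
#'   indices (empty vectors possible).
#' @export
assign_sentences <- function(transcript, keywords, embeddings,
                             spec = encoder_spec(dim = ncol(embeddings))) {
  stopifnot(nrow(keywords) > 0L)
  u <- transcript$utterances
  stopifnot(nrow(embeddings) == nrow(u))
  kw <- keywords$keyword
  kw_emb <- encode_sentences(kw, spec)
  fallback_sim <- cosine_matrix(as.matrix(embeddings), kw_emb)
  sets <- stats::setNames(vector("list", length(kw)), kw)
  for (j in seq_along(kw)) sets[[j]] <- integer(0)
  for (i in seq_len(nrow(u))) {
    toks <- tokenize(u$text[i])
    contained <- which(kw %in% toks)
    j <- if (length(contained) > 0L) {
      min(contained)  # keywords are ranked best-first
    } else {
      sims <- fallback_sim[i, ]
      which(sims >= max(sims) - 1e-12)[1L]  # tie -> better rank
    }
    sets[[j]] <- c(sets[[j]], u$index[i])
  }
  sets
}

new_keyword_graph <- function(nodes, sentence_sets, edges, threshold,
                              speaker = NULL) {
  structure(
    list(nodes = nodes, sentence_sets = sentence_sets, edges = edges,
         threshold = threshold, speaker = speaker),
    class = "keyword_graph"
  )
}

#' @export
print.keyword_graph <- function(x, ...) {
  cat(sprintf("<keyword_graph: %d keyword nodes, %d edges, threshold %.3g>\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Build a keyword correlation graph for one transcript
#'
#' Nodes are the transcript's top-scoring keywords, each holding the set of
#' utterances assigned to it; keywords whose sentence set is empty are
#' dropped (their edge weights would be means over empty sets). Edge weight
#' between two nodes is the average pairwise cosine similarity between their
#' sentence-embedding sets; edges below `kcg_threshold` are discarded.
#'
#' @param transcript A `transcript`.
#' @param model A fitted `topic_model`.
#' @param embeddings Matrix, one row per utterance.
#' @param k Keyword budget (default 50).
#' @param kcg_threshold Edge threshold (default 0: keep all non-negative
#'   correlations).
#' @param spec Encoder for keyword strings, see [assign_sentences()].
#' @return A `keyword_graph`: `nodes` (`keyword`, `score`, `set_size`),
#'   `sentence_sets` (keyword -> utterance indices), `edges`
#'   (`from`, `to` 1-based node indices, `weight`), `threshold`.
#' @export
build_kcg <- function(transcript, model, embeddings, k = 50L,
                      kcg_threshold = 0.0,
                      spec = encoder_spec(dim = ncol(embeddings))) {
  kws <- score_keywords(transcript, model, k)
  if (nrow(kws) == 0L) {
    return(new_keyword_graph(
      data.frame(keyword = character(0), score = numeric(0), set_size = integer(0)),
      list(), data.frame(from = integer(0), to = integer(0), weight = numeric(0)),
      kcg_threshold))
  }
  sets <- assign_sentences(transcript, kws, embeddings, spec)
  keep <- vapply(sets, length, integer(1L)) > 0L
  kws <- kws[keep, , drop = FALSE]
  sets <- sets[keep]
  nodes <- data.frame(keyword = kws$keyword, score = kws$score,
                      set_size = vapply(sets, length, integer(1L)),
                      row.names = NULL)
  u <- transcript$utterances
  sim <- cosine_matrix(as.matrix(embeddings))
  m <- nrow(nodes)
  edges <- list()
  if (m >= 2L) {
    rows_of <- lapply(sets, function(s) match(s, u$index))
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        w <- mean(sim[rows_of[[i]], rows_of[[j]], drop = FALSE])
        if (w >= kcg_threshold) {
          edges[[length(edges) + 1L]] <- data.frame(from = i, to = j, weight = w)
        }
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  new_keyword_graph(nodes, sets, edges, kcg_threshold)
}

# Restrict a transcript to a subset of utterance indices (keeping original
# 0-based indices), used to build per-view graphs.
subset_transcript <- function(transcript, indices) {
  u <- transcript$utterances
  keep <- u$index %in% indices
  new_transcript(transcript$id, u[keep, , drop = FALSE],
                 phq8 = transcript$phq8, label = transcript$label)
}

#' Build a multi-view keyword correlation graph
#'
#' Therapist and patient views each get a keyword graph built from their own
#' utterances under their own view-specific topic model. Cross edges connect
#' a therapist node and a patient node whenever some question-answer pair has
#' a question utterance in the therapist node's sentence set and its paired
#' answer utterance in the patient node's sentence set.
#'
#' @param transcript A `transcript`.
#' @param model_t,model_p Topic models fitted on training-split therapist /
#'   patient sentences respectively.
#' @param embeddings Matrix, one row per utterance of the whole transcript.
#' @param qapairs QA pairs from [pair_questions_answers()].
#' @param k,kcg_threshold,spec As in [build_kcg()].
#' @return An `mv_keyword_graph`: `therapist` and `patient` `keyword_graph`s
#'   and `cross_edges` (`from` therapist node index, `to` patient node index,
#'   `weight = 1`).
#' @export
build_kcg_mv <- function(transcript, model_t, model_p, embeddings,
                         qapairs = pair_questions_answers(segment_turns(transcript)),
                         k = 50L, kcg_threshold = 0.0,
                         spec = encoder_spec(dim = ncol(embeddings))) {
  u <- transcript$utterances
  stopifnot(nrow(embeddings) == nrow(u))
  views <- split_views(transcript)
  build_view <- function(idx, model, speaker) {
    if (length(idx) == 0L) {
      g <- new_keyword_graph(
        data.frame(keyword = character(0), score = numeric(0), set_size = integer(0)),
        list(), data.frame(from = integer(0), to = integer(0), weight = numeric(0)),
        kcg_threshold, speaker)
      return(g)
    }
    sub <- subset_transcript(transcript, idx)
    emb <- embeddings[match(idx, u$index), , drop = FALSE]
    g <- build_kcg(sub, model, emb, k, kcg_threshold, spec)
    g$speaker <- speaker
    g
  }
  gt <- build_view(views$therapist, model_t, "therapist")
  gp <- build_view(views$patient, model_p, "patient")
  # node lookup: utterance index -> node id, per view
  node_of <- function(g) {
    if (length(g$sentence_sets) == 0L) return(integer(0))
    map <- integer(0)
    for (j in seq_along(g$sentence_sets)) map[as.character(g$sentence_sets[[j]])] <- j
    map
  }
  map_t <- node_of(gt); map_p <- node_of(gp)
  cross <- list()
  for (p in qapairs) {
    for (q in p$question$utterance_indices) {
      for (a in p$answer$utterance_indices) {
        ni <- map_t[as.character(q)]; nj <- map_p[as.character(a)]
        if (!is.na(ni) && !is.na(nj)) {
          cross[[length(cross) + 1L]] <- c(from = unname(ni), to = unname(nj))
        }
      }
    }
  }
  cross_edges <- if (length(cross) > 0L) {
    ce <- unique(as.data.frame(do.call(rbind, cross)))
    ce <- ce[order(ce$from, ce$to), , drop = FALSE]
    rownames(ce) <- NULL
    ce$weight <- 1.0
    ce
  } else data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  structure(list(therapist = gt, patient = gp, cross_edges = cross_edges),
            class = "mv_keyword_graph")
}

#' @export
print.mv_keyword_graph <- function(x, ...) {
  cat(sprintf(
    "<mv_keyword_graph: %d therapist + %d patient keyword nodes, %d cross edges>\n",
    nrow(x$therapist$nodes), nrow(x$patient$nodes), nrow(x$cross_edges)))
  invisible(x)
}

#' Save / load a topic model as portable JSON
#'
#' @param model A `topic_model`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `topic_model` (load).
#' @export
save_topic_model <- function(model, path) {
  obj <- list(vocabulary = model$vocabulary,
              topic_word = unname(as.matrix(model$topic_word)),
              n_topics = model$n_topics, df = model$df, idf = model$idf,
              stopwords = model$stopwords, min_df = model$min_df,
              seed = model$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_topic_model
#' @export
load_topic_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tw <- as.matrix(obj$topic_word)
  dimnames(tw) <- list(NULL, obj$vocabulary)
  structure(
    list(vocabulary = obj$vocabulary, topic_word = tw,
         n_topics = as.integer(obj$n_topics), df = as.numeric(obj$df),
         idf = as.numeric(obj$idf), stopwords = obj$stopwords,
         min_df = as.integer(obj$min_df), seed = as.integer(obj$seed)),
    class = "topic_model"
  )
}
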