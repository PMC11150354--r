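# Shared fixtures and independent oracles. Fixtures are built in code and
# memoized so expensive preparations run once per test session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Hand-built transcript from speaker codes ("t"/"p") and texts.
h_transcript <- function(speakers, texts = NULL, id = "tt", phq8 = NA_integer_) {
  if (is.null(texts)) {
    texts <- paste("utterance token", seq_along(speakers))
  }
  dialograph:::build_transcript_from_rows(
    id = id,
    speakers = ifelse(speakers == "t", "therapist", "patient"),
    texts = texts, phq8 = phq8)
}

fx_small_corpus <- function() {
  memo("small_corpus", function() generate_corpus(gen_params(n_transcripts = 20L, seed = 7L)))
}

fx_default_corpus <- function() {
  memo("default_corpus", function() generate_corpus(gen_params(seed = 0L)))
}

## ---- independent oracles ---------------------------------------------------

# Plain-loop cosine of two vectors.
oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# Brute-force similarity-graph edge list: double loop over all pairs.
oracle_similarity_edges <- function(emb, threshold) {
  n <- nrow(emb)
  out <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        w <- oracle_cosine(emb[i, ], emb[j, ])
        if (w >= threshold) {
          out[[length(out) + 1L]] <- data.frame(from = i - 1L, to = j - 1L,
                                                weight = w)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = integer(0), to = integer(0), weight = numeric(0)))
  }
  do.call(rbind, out)
}

# Per-class confusion-matrix metrics computed with explicit counting loops.
oracle_metrics <- function(y_true, y_pred) {
  per_class <- function(c) {
    tp <- fp <- fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == c && y_true[i] == c) tp <- tp + 1
      if (y_pred[i] == c && y_true[i] != c) fp <- fp + 1
      if (y_pred[i] != c && y_true[i] == c) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  }
  m0 <- per_class(0); m1 <- per_class(1)
  acc <- sum(y_true == y_pred) / length(y_true)
  list(macro_f1 = (m0["f"] + m1["f"]) / 2,
       uar = (m0["r"] + m1["r"]) / 2,
       accuracy = acc,
       macro_precision = (m0["p"] + m1["p"]) / 2)
}

# Union-find connected components over strong edges; returns membership
# vector indexed like `node_ids`.
oracle_union_find <- function(node_ids, edges_from, edges_to) {
  parent <- seq_along(node_ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_along(edges_from)) {
    i <- match(edges_from[k], node_ids)
    j <- match(edges_to[k], node_ids)
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  # path-compress into canonical roots
  vapply(seq_along(node_ids), function(i) find(i), integer(1L))
}

# Exhaustive QA cross-edge oracle at the utterance level: enumerate turns by
# scanning the speaker sequence directly, then all (q, a) utterance pairs.
oracle_cross_edges <- function(transcript) {
  u <- transcript$utterances
  n <- nrow(u)
  runs <- list(); cur <- c(1L)
  if (n > 1L) {
    for (i in 2:n) {
      if (u$speaker[i] == u$speaker[i - 1L]) cur <- c(cur, i)
      else { runs[[length(runs) + 1L]] <- cur; cur <- c(i) }
    }
  }
  runs[[length(runs) + 1L]] <- cur
  out <- list()
  if (length(runs) >= 2L) {
    for (r in 1:(length(runs) - 1L)) {
      if (u$speaker[runs[[r]][1L]] == "therapist" &&
          u$speaker[runs[[r + 1L]][1L]] == "patient") {
        for (q in runs[[r]]) {
          for (a in runs[[r + 1L]]) {
            out[[length(out) + 1L]] <- c(from = u$index[q], to = u$index[a])
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$from, df$to), , drop = FALSE]
}

# Dense single-block multi-head attention, written independently of the
# package's tape machinery.
oracle_mha <- function(X_q, X_kv, Wq, Wk, Wv, Wo, n_heads) {
  Q <- X_q %*% Wq; K <- X_kv %*% Wk; V <- X_kv %*% Wv
  h <- ncol(Q); dh <- h / n_heads
  heads <- NULL
  for (j in seq_len(n_heads)) {
    cols <- ((j - 1) * dh + 1):(j * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    heads <- cbind(heads, A %*% V[, cols, drop = FALSE])
  }
  heads %*% Wo
}
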