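# Sentence-similarity graphs: complete-thresholded baseline and the
# multi-view variant with per-view subgraphs plus question-answer cross edges.

new_similarity_graph <- function(node_ids, edges, threshold, speaker = NULL) {
  structure(
    list(node_ids = as.integer(node_ids), edges = edges,
         threshold = threshold, speaker = speaker),
    class = "similarity_graph"
  )
}

empty_edge_df <- function() {
  data.frame(from = integer(0), to = integer(0), weight = numeric(0))
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph: %d nodes, %d edges, threshold %.3g>\n",
              length(x$node_ids), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Build a sentence-similarity graph
#'
#' One node per sentence embedding; an undirected edge between every pair
#' whose cosine similarity reaches the threshold, weighted by that cosine.
#' The threshold introduces sparsity and is treated as a hyper-parameter
#' of the downstream model.
#'
#' @param embeddings Numeric matrix, one row per sentence.
#' @param threshold Cosine threshold in \[-1, 1\]; edges with
#'   `cosine >= threshold` are retained.
#' @param node_ids Node identifiers (default 0-based utterance indices
#'   `0..n-1`).
#' @return A `similarity_graph`: `node_ids`, an edge data frame
#'   (`from`, `to`, `weight`; `from < to`, each pair stored once), and the
#'   threshold.
#' @export
build_similarity_graph <- function(embeddings, threshold = 0.5,
                                   node_ids = seq_len(nrow(embeddings)) - 1L) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) == 0L) {
    return(new_similarity_graph(integer(0), empty_edge_df(), threshold))
  }
  stopifnot(threshold >= -1, threshold <= 1,
            length(node_ids) == nrow(embeddings))
  sim <- cosine_matrix(embeddings)
  n <- nrow(sim)
  if (n == 1L) {
    return(new_similarity_graph(node_ids, empty_edge_df(), threshold))
  }
  idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = as.integer(node_ids[idx[, 1L]]),
    to = as.integer(node_ids[idx[, 2L]]),
    weight = sim[idx]
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_similarity_graph(node_ids, edges, threshold)
}

# Expand turn-level QA correspondence to utterance-level cross edges:
# every utterance of the question turn connects to every utterance of the
# answer turn.
qa_cross_edges <- function(qapairs) {
  if (length(qapairs) == 0L) {
    return(data.frame(from = integer(0), to = integer(0), weight = numeric(0)))
  }
  parts <- lapply(qapairs, function(p) {
    expand.grid(from = p$question$utterance_indices,
                to = p$answer$utterance_indices,
                KEEP.OUT.ATTRS = FALSE)
  })
  cross <- do.call(rbind, parts)
  cross <- unique(cross)
  cross <- cross[order(cross$from, cross$to), , drop = FALSE]
  rownames(cross) <- NULL
  cross$weight <- 1.0
  cross$from <- as.integer(cross$from)
  cross$to <- as.integer(cross$to)
  cross
}

#' Build a multi-view sentence-similarity graph
#'
#' The transcript is split into therapist and patient views; each view gets
#' its own similarity graph over its utterances only, and the views are
#' joined by cross edges derived from question-answer turn pairs (every
#' utterance of a question turn connects to every utterance of its answer
#' turn). Cross edges encode discourse structure, not similarity, so they are
#' exempt from the thresholds and carry weight 1.
#'
#' @param transcript A `transcript`.
#' @param embeddings Matrix with one row per utterance, in utterance order.
#' @param qapairs Output of [pair_questions_answers()]; defaults to pairing
#'   the transcript's own turns.
#' @param threshold_t,threshold_p Per-view similarity thresholds (default
#'   equal).
#' @return An `mv_similarity_graph`: `therapist` and `patient`
#'   `similarity_graph`s (node ids are utterance indices) and a `cross_edges`
#'   data frame (`from` therapist utterance, `to` patient utterance,
#'   `weight = 1`).
#' @export
build_mv_similarity_graph <- function(transcript, embeddings,
                                      qapairs = pair_questions_answers(segment_turns(transcript)),
                                      threshold_t = 0.5,
                                      threshold_p = threshold_t) {
  u <- transcript$utterances
  stopifnot(nrow(embeddings) == nrow(u))
  views <- split_views(transcript)
  for (v in c("therapist", "patient")) {
    if (length(views[[v]]) == 0L) {
      warning("transcript '", transcript$id, "': empty ", v,
              " view; building a degenerate 0-node view graph")
    }
  }
  row_of <- match(views$therapist, u$index)
  gt <- build_similarity_graph(embeddings[row_of, , drop = FALSE],
                               threshold_t, node_ids = views$therapist)
  gt$speaker <- "therapist"
  row_of <- match(views$patient, u$index)
  gp <- build_similarity_graph(embeddings[row_of, , drop = FALSE],
                               threshold_p, node_ids = views$patient)
  gp$speaker <- "patient"
  structure(
    list(therapist = gt, patient = gp, cross_edges = qa_cross_edges(qapairs)),
    class = "mv_similarity_graph"
  )
}

#' @export
print.mv_similarity_graph <- function(x, ...) {
  cat(sprintf(
    "<mv_similarity_graph: %d therapist + %d patient nodes, %d + %d intra edges, %d cross edges>\n",
    length(x$therapist$node_ids), length(x$patient$node_ids),
    nrow(x$therapist$edges), nrow(x$patient$edges), nrow(x$cross_edges)))
  invisible(x)
}
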