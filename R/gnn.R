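# Graph neural models: GCN message passing, multi-head attention blocks
# (node encoder, attention-pool readout, multi-view cross-attention fusion)
# and the logistic classification head. A single tape-based forward pass
# serves both training (parameters tracked for gradients) and the exported
# inference-style operations (parameters as constants).

#' Model configuration
#'
#' @param variant One of `"similarity_baseline"`, `"similarity_mv"`,
#'   `"kcg_baseline"`, `"kcg_mv"`.
#' @param hidden_dim Hidden width (must be divisible by `n_heads`).
#' @param n_gcn_layers Number of GCN layers (>= 1), ReLU between layers.
#' @param n_heads Attention heads in every attention block.
#' @param dropout Dropout rate on node features between GCN layers during
#'   training.
#' @param readout `"attention_pool"` (multi-head self-attention then mean)
#'   or `"mean_pool"`.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("similarity_baseline", "similarity_mv",
                                     "kcg_baseline", "kcg_mv"),
                         hidden_dim = 128L, n_gcn_layers = 2L, n_heads = 4L,
                         dropout = 0.2,
                         readout = c("attention_pool", "mean_pool")) {
  variant <- match.arg(variant)
  readout <- match.arg(readout)
  stopifnot(n_gcn_layers >= 1L, hidden_dim %% n_heads == 0L,
            dropout >= 0, dropout < 1)
  structure(list(variant = variant, hidden_dim = as.integer(hidden_dim),
                 n_gcn_layers = as.integer(n_gcn_layers),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 readout = readout),
            class = "model_config")
}

is_mv_variant <- function(config) config$variant %in% c("similarity_mv", "kcg_mv")
is_kcg_variant <- function(config) config$variant %in% c("kcg_baseline", "kcg_mv")

#' Initialize model parameters
#'
#' Glorot-uniform initialization, deterministic given the seed.
#'
#' @param config A [model_config()].
#' @param input_dim Dimension of the input sentence embeddings.
#' @param seed Integer seed.
#' @return A parameter store (environment with `values`, Adam state).
#' @export
init_model_params <- function(config, input_dim, seed = 0L) {
  h <- config$hidden_dim
  withr::with_seed(as.integer(seed), {
    values <- list()
    gcn_in <- if (is_kcg_variant(config)) h else input_dim
    for (l in seq_len(config$n_gcn_layers)) {
      d_in <- if (l == 1L) gcn_in else h
      values[[paste0("gcn", l, "_W")]] <- glorot(d_in, h)
      values[[paste0("gcn", l, "_b")]] <- matrix(0, 1L, h)
    }
    if (is_kcg_variant(config)) {
      for (nm in c("ne_Wq", "ne_Wk", "ne_Wv")) values[[nm]] <- glorot(input_dim, h)
      values[["ne_Wo"]] <- glorot(h, h)
    }
    if (is_mv_variant(config)) {
      for (nm in c("va_Wq", "va_Wk", "va_Wv", "va_Wo",
                   "ca_Wq", "ca_Wk", "ca_Wv", "ca_Wo")) {
        values[[nm]] <- glorot(h, h)
      }
    } else if (config$readout == "attention_pool") {
      for (nm in c("ro_Wq", "ro_Wk", "ro_Wv", "ro_Wo")) values[[nm]] <- glorot(h, h)
    }
    values[["clf_w"]] <- glorot(h, 1L)
    values[["clf_b"]] <- matrix(0, 1L, 1L)
    param_store(values)
  })
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Builds the dense propagation matrix `D^{-1/2} (A + I) D^{-1/2}` from a
#' weighted edge list; edge weights become the adjacency entries.
#'
#' @param n_nodes Number of nodes.
#' @param edges Data frame with 1-based `from`, `to`, `weight`.
#' @return Dense `n_nodes` x `n_nodes` matrix.
#' @export
normalized_adjacency <- function(n_nodes, edges) {
  A <- diag(1, n_nodes)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges$from[r]; j <- edges$to[r]; w <- edges$weight[r]
      A[i, j] <- A[i, j] + w
      A[j, i] <- A[j, i] + w
    }
  }
  d <- rowSums(A)
  d[d < 1e-12] <- 1e-12
  dinv <- 1 / sqrt(d)
  A * outer(dinv, dinv)
}

## ---- tape builders (shared by training and exported operations) -----------

# Multi-head attention block: softmax(Q K^T / sqrt(d_h)) V per head, heads
# concatenated, output projection. `getp` maps a parameter name to a tape
# node; `prefix` selects the parameter group.
tape_mha <- function(tape, getp, prefix, q_in, kv_in, n_heads) {
  Q <- ad_matmul(tape, q_in, getp(paste0(prefix, "_Wq")))
  K <- ad_matmul(tape, kv_in, getp(paste0(prefix, "_Wk")))
  V <- ad_matmul(tape, kv_in, getp(paste0(prefix, "_Wv")))
  h <- ncol(Q$value)
  dh <- h %/% n_heads
  heads <- vector("list", n_heads)
  for (j in seq_len(n_heads)) {
    cols <- ((j - 1L) * dh + 1L):(j * dh)
    Qj <- ad_slice_cols(tape, Q, cols)
    Kj <- ad_slice_cols(tape, K, cols)
    Vj <- ad_slice_cols(tape, V, cols)
    scores <- ad_affine_const(tape, ad_matmul(tape, Qj, Kj, tb = TRUE),
                              mult = 1 / sqrt(dh))
    heads[[j]] <- ad_matmul(tape, ad_softmax_rows(tape, scores), Vj)
  }
  ad_matmul(tape, ad_cbind(tape, heads), getp(paste0(prefix, "_Wo")))
}

# Stacked GCN layers: H <- ReLU(Ahat H W + b), with optional dropout masks
# (list of constant matrices) applied after each nonlinearity.
tape_gcn <- function(tape, getp, Ahat_node, X, n_layers, dropout_masks = NULL) {
  H <- X
  for (l in seq_len(n_layers)) {
    H <- ad_matmul(tape, Ahat_node, H)
    H <- ad_matmul(tape, H, getp(paste0("gcn", l, "_W")))
    H <- ad_add_bias(tape, H, getp(paste0("gcn", l, "_b")))
    H <- ad_relu(tape, H)
    if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
      H <- ad_mul_constmat(tape, H, dropout_masks[[l]])
    }
  }
  H
}

# Attention-pool readout: self-attention over nodes, then column means.
tape_readout <- function(tape, getp, H, config) {
  if (config$readout == "mean_pool") return(ad_colmeans(tape, H))
  ad_colmeans(tape, tape_mha(tape, getp, "ro", H, H, config$n_heads))
}

# Node encoder: self-attention over one keyword node's sentence-embedding
# set, mean-pooled to a single feature row.
tape_node_encoder <- function(tape, getp, set_node, n_heads) {
  ad_colmeans(tape, tape_mha(tape, getp, "ne", set_node, set_node, n_heads))
}

# MV-Inter-Att (Mean) fusion: per-view self-attention, cross-attention in
# both directions (shared cross weights, views swapping query vs key/value
# roles), mean-pooled direction summaries combined by element-wise mean.
# An empty view contributes a zero summary; the surviving view contributes
# its self-attended mean.
tape_mv_fusion <- function(tape, getp, Ht, Hp, config) {
  h <- config$hidden_dim
  zero <- function() ad_const(tape, matrix(0, 1L, h))
  has_t <- !is.null(Ht) && nrow(Ht$value) > 0L
  has_p <- !is.null(Hp) && nrow(Hp$value) > 0L
  if (!has_t && !has_p) stop("both views empty: cannot fuse")
  if (has_t && has_p) {
    St <- tape_mha(tape, getp, "va", Ht, Ht, config$n_heads)
    Sp <- tape_mha(tape, getp, "va", Hp, Hp, config$n_heads)
    Ctp <- ad_colmeans(tape, tape_mha(tape, getp, "ca", St, Sp, config$n_heads))
    Cpt <- ad_colmeans(tape, tape_mha(tape, getp, "ca", Sp, St, config$n_heads))
    return(ad_affine_const(tape, ad_add(tape, Ctp, Cpt), mult = 0.5))
  }
  H <- if (has_t) Ht else Hp
  S <- ad_colmeans(tape, tape_mha(tape, getp, "va", H, H, config$n_heads))
  ad_affine_const(tape, ad_add(tape, S, zero()), mult = 0.5)
}

tape_classify <- function(tape, getp, z) {
  logit <- ad_add(tape, ad_matmul(tape, z, getp("clf_w")), getp("clf_b"))
  ad_sigmoid(tape, logit)
}

## ---- full forward over a prepared transcript -------------------------------

# prep: list(Ahat, X | sets_emb, view_rows = list(therapist=, patient=)).
# Returns the probability node (1 x 1).
tape_forward <- function(tape, getp, prep, config, dropout_masks = NULL) {
  if (is_kcg_variant(config)) {
    n_nodes <- length(prep$sets_emb)
    if (n_nodes == 0L) stop("empty graph: no keyword nodes")
    feats <- vector("list", n_nodes)
    for (i in seq_len(n_nodes)) {
      feats[[i]] <- tape_node_encoder(tape, getp,
                                      ad_const(tape, prep$sets_emb[[i]]),
                                      config$n_heads)
    }
    X <- ad_rbind(tape, feats)
  } else {
    if (nrow(prep$X) == 0L) stop("empty graph: no sentence nodes")
    X <- ad_const(tape, prep$X)
  }
  H <- tape_gcn(tape, getp, ad_const(tape, prep$Ahat), X,
                config$n_gcn_layers, dropout_masks)
  z <- if (is_mv_variant(config)) {
    rt <- prep$view_rows$therapist
    rp <- prep$view_rows$patient
    Ht <- if (length(rt) > 0L) ad_slice_rows(tape, H, rt) else NULL
    Hp <- if (length(rp) > 0L) ad_slice_rows(tape, H, rp) else NULL
    tape_mv_fusion(tape, getp, Ht, Hp, config)
  } else {
    tape_readout(tape, getp, H, config)
  }
  tape_classify(tape, getp, z)
}

## ---- exported inference-style operations -----------------------------------

const_getter <- function(tape, params) {
  function(name) {
    if (is.null(params[[name]])) stop("missing parameter: ", name)
    ad_const(tape, params[[name]])
  }
}

#' GCN forward pass
#'
#' Standard graph-convolution propagation: self-loops are added, the
#' adjacency (with edge weights as entries) is symmetrically degree
#' normalized, and `n_layers` rounds of `ReLU(Ahat H W_l + b_l)` are
#' applied.
#'
#' @param node_features Numeric matrix, one row per node.
#' @param edges Edge data frame (`from`, `to` 1-based, `weight`).
#' @param params Named list with `gcn<l>_W`, `gcn<l>_b` for each layer.
#' @param n_layers Number of layers.
#' @return Updated node-feature matrix.
#' @export
gcn_forward <- function(node_features, edges, params, n_layers = 1L) {
  node_features <- as.matrix(node_features)
  if (nrow(node_features) == 0L) stop("empty graph: no nodes")
  tape <- ad_tape()
  getp <- const_getter(tape, params)
  Ahat <- ad_const(tape, normalized_adjacency(nrow(node_features), edges))
  tape_gcn(tape, getp, Ahat, ad_const(tape, node_features), n_layers)$value
}

#' Node encoder: pool a sentence-embedding set into one node feature
#'
#' Multi-head self-attention over the set followed by mean pooling. The
#' output is permutation invariant in the set and, for a singleton set,
#' a fixed transform of that single embedding.
#'
#' @param sentence_embeddings Matrix, one row per sentence in the node's set
#'   (non-empty).
#' @param params Named list with `ne_Wq`, `ne_Wk`, `ne_Wv`, `ne_Wo`.
#' @param n_heads Attention heads.
#' @return 1 x hidden row vector.
#' @export
node_encoder <- function(sentence_embeddings, params, n_heads = 4L) {
  sentence_embeddings <- as.matrix(sentence_embeddings)
  if (nrow(sentence_embeddings) == 0L) {
    stop("node_encoder: empty sentence set (empty nodes must be dropped upstream)")
  }
  tape <- ad_tape()
  getp <- const_getter(tape, params)
  tape_node_encoder(tape, getp, ad_const(tape, sentence_embeddings), n_heads)$value
}

#' Attention-pool readout over node features
#'
#' Multi-head self-attention over the nodes, mean-pooled to a single graph
#' embedding.
#'
#' @param node_features Matrix, one row per node (>= 1).
#' @param params Named list with `ro_Wq`, `ro_Wk`, `ro_Wv`, `ro_Wo`.
#' @param n_heads Attention heads.
#' @return 1 x hidden graph-embedding row.
#' @export
attention_readout <- function(node_features, params, n_heads = 4L) {
  node_features <- as.matrix(node_features)
  if (nrow(node_features) == 0L) stop("attention_readout: empty graph")
  tape <- ad_tape()
  getp <- const_getter(tape, params)
  ad_colmeans(tape, tape_mha(tape, getp, "ro",
                             ad_const(tape, node_features),
                             ad_const(tape, node_features), n_heads))$value
}

#' Multi-view cross-attention fusion (mean combination)
#'
#' Each view's node features are self-attended; cross-attention then runs in
#' both directions with the views swapping query against key/value roles,
#' and the two mean-pooled direction summaries are combined by element-wise
#' mean. If one view is empty it contributes a zero summary and the fusion
#' degrades to half the surviving view's self-attended mean.
#'
#' @param view_t,view_p Node-feature matrices for the therapist and patient
#'   views (either may have zero rows, not both).
#' @param params Named list with `va_*` (self-attention) and `ca_*`
#'   (cross-attention) weight matrices.
#' @param n_heads Attention heads.
#' @return 1 x hidden fused embedding row.
#' @export
mv_inter_att_mean <- function(view_t, view_p, params, n_heads = 4L) {
  tape <- ad_tape()
  getp <- const_getter(tape, params)
  h <- ncol(params$va_Wq)
  cfg <- list(hidden_dim = h, n_heads = n_heads)
  Ht <- if (nrow(as.matrix(view_t)) > 0L) ad_const(tape, as.matrix(view_t)) else NULL
  Hp <- if (nrow(as.matrix(view_p)) > 0L) ad_const(tape, as.matrix(view_p)) else NULL
  tape_mv_fusion(tape, getp, Ht, Hp, cfg)$value
}

#' Logistic classification head
#'
#' @param embedding 1 x hidden graph embedding.
#' @param w,b Weight (hidden x 1) and bias (scalar).
#' @return Probability of the depressed class, in \[0, 1\].
#' @export
classify <- function(embedding, w, b = 0) {
  logit <- as.numeric(as.matrix(embedding) %*% as.matrix(w)) + as.numeric(b)
  1 / (1 + exp(-logit))
}
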