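# Clinician-readable graph summaries: DOT and GraphML writers with the
# weak/strong edge styling convention (dashed below the cutoff, solid at or
# above it, cross edges distinct), strong-edge cluster detection, and
# marker-keyword cluster reports.

#' Rendering specification
#'
#' @param weak_strong_cutoff Edge weight below which an edge is drawn
#'   dashed ("weak"); at or above, solid ("strong").
#' @param layout Layout hint recorded in DOT output (`"force_directed"` or
#'   `"circular"`); layout itself is cosmetic.
#' @param annotate_clusters Annotate strong-edge clusters in DOT output.
#' @param filler_vocabulary Words marking conversation-filler utterances.
#' @param output_format `"dot"`, `"graphml"`, `"png"` or `"svg"` (the last
#'   two require the external `dot` layout engine).
#' @return A `render_spec` list.
#' @export
render_spec <- function(weak_strong_cutoff = 0.5,
                        layout = c("force_directed", "circular"),
                        annotate_clusters = TRUE,
                        filler_vocabulary = default_fillers(),
                        output_format = c("dot", "graphml", "png", "svg")) {
  stopifnot(weak_strong_cutoff >= -1, weak_strong_cutoff <= 1)
  structure(list(weak_strong_cutoff = weak_strong_cutoff,
                 layout = match.arg(layout),
                 annotate_clusters = isTRUE(annotate_clusters),
                 filler_vocabulary = filler_vocabulary,
                 output_format = match.arg(output_format)),
            class = "render_spec")
}

# Canonical node/edge tables for any of the four graph classes.
# Nodes: id (int), label (chr), speaker (chr or NA). Edges: from, to (ids),
# weight, edge_type.
graph_tables <- function(graph) {
  if (inherits(graph, "similarity_graph")) {
    nodes <- data.frame(id = graph$node_ids,
                        label = as.character(graph$node_ids),
                        speaker = rep(if (is.null(graph$speaker)) NA_character_
                                      else graph$speaker,
                                      length(graph$node_ids)))
    e <- graph$edges
    edges <- data.frame(from = e$from, to = e$to, weight = e$weight,
                        edge_type = rep("intra", nrow(e)))
    return(list(nodes = nodes, edges = edges, kind = "similarity"))
  }
  if (inherits(graph, "keyword_graph")) {
    m <- nrow(graph$nodes)
    nodes <- data.frame(id = seq_len(m) - 1L, label = graph$nodes$keyword,
                        speaker = rep(if (is.null(graph$speaker)) NA_character_
                                      else graph$speaker, m),
                        score = graph$nodes$score,
                        set_size = graph$nodes$set_size)
    e <- graph$edges
    edges <- data.frame(from = e$from - 1L, to = e$to - 1L, weight = e$weight,
                        edge_type = rep("intra", nrow(e)))
    return(list(nodes = nodes, edges = edges, kind = "keyword"))
  }
  if (inherits(graph, "mv_similarity_graph")) {
    tt <- graph_tables(graph$therapist); pp <- graph_tables(graph$patient)
    tt$nodes$speaker <- "therapist"; pp$nodes$speaker <- "patient"
    tt$edges$edge_type <- rep("intra_t", nrow(tt$edges))
    pp$edges$edge_type <- rep("intra_p", nrow(pp$edges))
    cross <- data.frame(from = graph$cross_edges$from,
                        to = graph$cross_edges$to,
                        weight = graph$cross_edges$weight,
                        edge_type = rep("cross", nrow(graph$cross_edges)))
    return(list(nodes = rbind(tt$nodes, pp$nodes),
                edges = rbind(tt$edges, pp$edges, cross),
                kind = "similarity"))
  }
  if (inherits(graph, "mv_keyword_graph")) {
    mt <- nrow(graph$therapist$nodes)
    tt <- graph_tables(graph$therapist); pp <- graph_tables(graph$patient)
    tt$nodes$speaker <- "therapist"
    if (nrow(pp$nodes) > 0L) {
      pp$nodes$speaker <- "patient"
      pp$nodes$id <- pp$nodes$id + mt
      pp$edges$from <- pp$edges$from + mt
      pp$edges$to <- pp$edges$to + mt
    }
    tt$edges$edge_type <- rep("intra_t", nrow(tt$edges))
    pp$edges$edge_type <- rep("intra_p", nrow(pp$edges))
    cross <- data.frame(from = graph$cross_edges$from - 1L,
                        to = graph$cross_edges$to - 1L + mt,
                        weight = graph$cross_edges$weight,
                        edge_type = rep("cross", nrow(graph$cross_edges)))
    return(list(nodes = rbind(tt$nodes, pp$nodes),
                edges = rbind(tt$edges, pp$edges, cross),
                kind = "keyword"))
  }
  stop("unsupported graph class: ", paste(class(graph), collapse = "/"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a graph as DOT
#'
#' Deterministic output (nodes by id, edges lexicographic): edges with
#' weight below the weak/strong cutoff are dashed blue, at or above it solid
#' black; cross edges are orange. Strong-edge clusters can be annotated with
#' a filler/content tag derived from the member texts.
#'
#' @param graph Any supported graph object.
#' @param path Output path.
#' @param spec A [render_spec()].
#' @param texts Optional named character vector (node id -> text) used for
#'   filler annotation of similarity graphs.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path, spec = render_spec(), texts = NULL) {
  gt <- graph_tables(graph)
  if (nrow(gt$nodes) == 0L) stop("cannot render an empty graph")
  lines <- c("graph G {",
             sprintf("  // layout: %s", spec$layout),
             if (spec$layout == "circular") "  layout=circo;" else "  layout=fdp;")
  nodes <- gt$nodes[order(gt$nodes$id), , drop = FALSE]
  cluster_tag <- rep(NA_character_, nrow(nodes))
  if (spec$annotate_clusters) {
    cl <- detect_clusters(graph, cutoff = spec$weak_strong_cutoff,
                          texts = texts,
                          filler_vocabulary = spec$filler_vocabulary)
    for (c in cl) {
      cluster_tag[match(c$node_ids, nodes$id)] <-
        sprintf("%d:%s", c$cluster, c$annotation)
    }
  }
  for (r in seq_len(nrow(nodes))) {
    shade <- if (!is.na(nodes$speaker[r]) && nodes$speaker[r] == "patient")
      "lightblue" else "lightcoral"
    extra <- if (!is.na(cluster_tag[r]))
      sprintf(", comment=\"cluster %s\"", cluster_tag[r]) else ""
    lines <- c(lines, sprintf(
      "  n%d [label=\"%s\", fillcolor=%s, style=filled%s];",
      nodes$id[r], gsub("\"", "'", nodes$label[r]), shade, extra))
  }
  edges <- gt$edges
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    for (r in seq_len(nrow(edges))) {
      style <- if (edges$edge_type[r] == "cross") {
        "color=orange, style=solid"
      } else if (edges$weight[r] < spec$weak_strong_cutoff) {
        "color=blue, style=dashed"
      } else {
        "color=black, style=solid"
      }
      lines <- c(lines, sprintf(
        "  n%d -- n%d [weight_value=\"%.6f\", %s];",
        edges$from[r], edges$to[r], edges$weight[r], style))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a graph as GraphML
#'
#' Bit-stable given fixed ordering; node attributes carry the label,
#' speaker and (for keyword graphs) score and sentence-set size, edge
#' attributes the weight and edge type.
#'
#' @inheritParams write_dot
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, spec = render_spec()) {
  gt <- graph_tables(graph)
  keys <- c(
    '  <key id="d0" for="node" attr.name="label" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="speaker" attr.type="string"/>',
    '  <key id="d2" for="node" attr.name="score" attr.type="double"/>',
    '  <key id="d3" for="node" attr.name="set_size" attr.type="int"/>',
    '  <key id="d4" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="d5" for="edge" attr.name="edge_type" attr.type="string"/>')
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             keys, '  <graph id="G" edgedefault="undirected">')
  nodes <- gt$nodes[order(gt$nodes$id), , drop = FALSE]
  for (r in seq_len(nrow(nodes))) {
    data <- sprintf('<data key="d0">%s</data>', xml_escape(nodes$label[r]))
    if (!is.na(nodes$speaker[r])) {
      data <- paste0(data, sprintf('<data key="d1">%s</data>', nodes$speaker[r]))
    }
    if (!is.null(nodes$score)) {
      data <- paste0(data,
                     sprintf('<data key="d2">%.12g</data>', nodes$score[r]),
                     sprintf('<data key="d3">%d</data>', nodes$set_size[r]))
    }
    lines <- c(lines, sprintf('    <node id="n%d">%s</node>', nodes$id[r], data))
  }
  edges <- gt$edges
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    for (r in seq_len(nrow(edges))) {
      lines <- c(lines, sprintf(
        '    <edge source="n%d" target="n%d"><data key="d4">%.12g</data><data key="d5">%s</data></edge>',
        edges$from[r], edges$to[r], edges$weight[r], edges$edge_type[r]))
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GraphML file written by this package
#'
#' @param path GraphML path.
#' @return List with `nodes` (id, label, speaker, score, set_size) and
#'   `edges` (from, to, weight, edge_type) data frames.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_key <- function(el, key) {
    d <- xml2::xml_find_first(el, sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes <- data.frame(
    id = as.integer(sub("^n", "", xml2::xml_attr(node_els, "id"))),
    label = vapply(node_els, get_key, character(1L), key = "d0"),
    speaker = vapply(node_els, get_key, character(1L), key = "d1"),
    score = as.numeric(vapply(node_els, get_key, character(1L), key = "d2")),
    set_size = as.integer(vapply(node_els, get_key, character(1L), key = "d3")))
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- data.frame(
    from = as.integer(sub("^n", "", xml2::xml_attr(edge_els, "source"))),
    to = as.integer(sub("^n", "", xml2::xml_attr(edge_els, "target"))),
    weight = as.numeric(vapply(edge_els, get_key, character(1L), key = "d4")),
    edge_type = vapply(edge_els, get_key, character(1L), key = "d5"))
  list(nodes = nodes, edges = edges)
}

#' Render a graph to a file
#'
#' Dispatches on `spec$output_format`: DOT and GraphML are written directly;
#' PNG/SVG require the external `dot` layout engine on the PATH.
#'
#' @inheritParams write_dot
#' @return `path`, invisibly.
#' @export
render_graph <- function(graph, path, spec = render_spec(), texts = NULL) {
  fmt <- spec$output_format
  if (fmt == "dot") return(write_dot(graph, path, spec, texts))
  if (fmt == "graphml") return(write_graphml(graph, path, spec))
  if (Sys.which("dot") == "") {
    stop("rendering to ", fmt, " requires the external 'dot' layout engine; ",
         "use output_format = \"dot\" or \"graphml\" instead")
  }
  tmp <- tempfile(fileext = ".dot")
  write_dot(graph, tmp, spec, texts)
  status <- system2("dot", c(paste0("-T", fmt), tmp, "-o", path))
  if (status != 0L) stop("dot layout engine failed with status ", status)
  invisible(path)
}

#' Detect strong-edge clusters
#'
#' Clusters are the connected components of the subgraph keeping only edges
#' with weight at or above the cutoff (cross edges included). Each cluster
#' is annotated `"filler"` when at least half of its member texts are in the
#' filler vocabulary or (for similarity graphs) are single-token
#' back-channels, else `"content"`.
#'
#' @param graph Any supported graph object.
#' @param cutoff Strong-edge weight cutoff.
#' @param texts Named character vector (node id -> utterance text) for
#'   similarity graphs; keyword graphs use the keywords themselves.
#' @param filler_vocabulary Filler word list.
#' @return List of clusters: `cluster` (index), `node_ids`, `labels`,
#'   `annotation`.
#' @export
detect_clusters <- function(graph, cutoff = 0.5, texts = NULL,
                            filler_vocabulary = default_fillers()) {
  gt <- graph_tables(graph)
  if (nrow(gt$nodes) == 0L) return(list())
  strong <- gt$edges[gt$edges$weight >= cutoff, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(strong$from),
                   to = as.character(strong$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(gt$nodes$id)))
  comp <- igraph::components(ig)
  membership <- comp$membership[as.character(gt$nodes$id)]
  single_token_rule <- gt$kind == "similarity"
  node_text <- if (!is.null(texts)) {
    unname(texts[as.character(gt$nodes$id)])
  } else {
    gt$nodes$label
  }
  lapply(sort(unique(membership)), function(m) {
    rows <- which(membership == m)
    txts <- node_text[rows]
    is_filler <- vapply(txts, function(t) {
      toks <- strsplit(trimws(t), "\\s+")[[1L]]
      t %in% filler_vocabulary ||
        (single_token_rule && length(toks) == 1L) ||
        (length(toks) == 1L && toks %in% filler_vocabulary)
    }, logical(1L))
    list(cluster = as.integer(m), node_ids = gt$nodes$id[rows],
         labels = gt$nodes$label[rows],
         annotation = if (mean(is_filler) >= 0.5) "filler" else "content")
  })
}

#' Report marker-keyword clusters in a keyword graph
#'
#' Reports which marker keywords appear as nodes and whether they form a
#' cluster. In a keyword graph a node already is a cluster of sentences, so
#' a marker cluster is flagged when any of the following holds: a marker
#' node has gathered two or more utterances in its sentence set, two marker
#' nodes share a strong-edge component, or a marker node sits in a
#' strong-edge component of two or more nodes.
#'
#' @param kcg A `keyword_graph` (or `mv_keyword_graph`).
#' @param marker_keywords Marker words to look for.
#' @param cutoff Strong-edge cutoff.
#' @return List: `markers_present`, `marker_cluster` (flag as defined
#'   above), `markers_connected` (two markers share a strong component),
#'   `clusters` (the strong components containing markers).
#' @export
marker_cluster_report <- function(kcg, marker_keywords, cutoff = 0.5) {
  gt <- graph_tables(kcg)
  present <- intersect(marker_keywords, gt$nodes$label)
  if (length(present) == 0L) {
    return(list(markers_present = character(0), marker_cluster = FALSE,
                markers_connected = FALSE, clusters = list()))
  }
  cl <- detect_clusters(kcg, cutoff = cutoff)
  with_markers <- Filter(function(c) any(c$labels %in% present), cl)
  in_component <- any(vapply(with_markers, function(c) {
    length(c$node_ids) >= 2L
  }, logical(1L)))
  markers_connected <- any(vapply(with_markers, function(c) {
    sum(unique(c$labels) %in% present) >= 2L
  }, logical(1L)))
  marker_sets <- gt$nodes$set_size[gt$nodes$label %in% present]
  gathered <- length(marker_sets) > 0L && any(marker_sets >= 2L)
  list(markers_present = present,
       marker_cluster = gathered || markers_connected || in_component,
       markers_connected = markers_connected, clusters = with_markers)
}
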