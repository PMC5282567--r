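# ceRNA network assembly: the anticorrelation (opposite DE direction)
# filter, pairwise networks, tripartite integration with triad summaries,
# hub ranking, and Cytoscape-compatible export.

EDGE_COLUMNS <- c("regulator", "regulator_class", "regulator_direction",
                  "target", "target_class", "target_direction",
                  "evidence", "score")

empty_edges <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), 7), EDGE_COLUMNS[-8]),
                      stringsAsFactors = FALSE)
  df$score <- numeric(0)
  df
}

#' Filter predicted pairs to anticorrelated regulator-target edges
#'
#' Implements the "inverse correlation" selection: both endpoints of a
#' predicted pair must pass the chosen DE gate and have opposite DE
#' directions (an up-regulator may only repress a down-target and vice
#' versa).  Optionally, a sample-level correlation gate
#' (`r <= -require_r`) is applied on top when expression matrices are
#' supplied.
#'
#' @param pairs `InteractionPair` data frame (see [seed_pairs()],
#'   [cis_pairs()], [trans_pairs()], [load_interaction_table()]).
#' @param de_tables named list of [de_table()]s, one per feature class
#'   (`mirna`, `lncrna`, `mrna`); every pair endpoint must be present in
#'   its class's table.
#' @param gate `"de"` (default: >2-fold, q < 0.05 screen) or
#'   `"candidate"` (the stricter validation screen).
#' @param require_r optional non-negative threshold for the sample-level
#'   correlation gate.
#' @param expr named list of `expr_matrix` objects per class; required
#'   when `require_r` is set.
#' @return A `RegulatoryEdge` data frame.
#' @export
anticorrelation_filter <- function(pairs, de_tables, gate = c("de", "candidate"),
                                   require_r = NULL, expr = NULL) {
  gate <- match.arg(gate)
  stopifnot(all(PAIR_COLUMNS %in% names(pairs)))
  if (nrow(pairs) == 0) return(empty_edges())
  lookup <- function(ids, classes, what) {
    out <- data.frame(direction = character(length(ids)),
                      passes = logical(length(ids)), stringsAsFactors = FALSE)
    for (cl in unique(classes)) {
      det <- de_tables[[cl]]
      if (is.null(det)) stopf("no DE table supplied for class '%s'", cl)
      idx <- match(ids[classes == cl], det$feature)
      if (anyNA(idx))
        stopf("%s endpoint(s) missing from the %s DE table: %s", what, cl,
              paste(head(ids[classes == cl][is.na(idx)], 5), collapse = ", "))
      out$direction[classes == cl] <- det$direction[idx]
      out$passes[classes == cl] <-
        if (gate == "de") det$passes_de[idx] else det$passes_candidate[idx]
    }
    out
  }
  src <- lookup(pairs$source, pairs$source_class, "source")
  tgt <- lookup(pairs$target, pairs$target_class, "target")
  keep <- src$passes & tgt$passes &
    src$direction %in% c("up", "down") & tgt$direction %in% c("up", "down") &
    src$direction != tgt$direction
  edges <- data.frame(regulator = pairs$source[keep],
                      regulator_class = pairs$source_class[keep],
                      regulator_direction = src$direction[keep],
                      target = pairs$target[keep],
                      target_class = pairs$target_class[keep],
                      target_direction = tgt$direction[keep],
                      evidence = pairs$evidence[keep],
                      score = pairs$score[keep], stringsAsFactors = FALSE)
  if (!is.null(require_r)) {
    assert_scalar_number(require_r, "require_r", 0, 1)
    if (is.null(expr)) stopf("'expr' matrices required when 'require_r' is set")
    val <- function(cl, id) {
      em <- expr[[cl]]
      if (is.null(em) || !(id %in% rownames(em$values)))
        stopf("expression values missing for %s (%s)", id, cl)
      em$values[id, ]
    }
    r <- vapply(seq_len(nrow(edges)), function(i) {
      a <- val(edges$regulator_class[i], edges$regulator[i])
      b <- val(edges$target_class[i], edges$target[i])
      shared <- intersect(names(a), names(b))
      cor(a[shared], b[shared])
    }, numeric(1))
    edges <- edges[is.finite(r) & r <= -require_r, , drop = FALSE]
  }
  edges <- edges[!duplicated(edges[, c("regulator", "target", "evidence")]), ,
                 drop = FALSE]
  edges <- edges[order_c(edges$regulator, edges$target, edges$evidence), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

NETWORK_KINDS <- list(
  mirna_mrna = c("mirna", "mrna"),
  lncrna_mrna = c("lncrna", "mrna"),
  mirna_lncrna = c("mirna", "lncrna"),
  mirna_mrna_lncrna = c("mirna", "mrna", "lncrna"),
  lncrna_mirna_mrna = c("lncrna", "mirna", "mrna"))

new_network <- function(edges, kind) {
  ids <- c(edges$regulator, edges$target)
  classes <- c(edges$regulator_class, edges$target_class)
  dirs <- c(edges$regulator_direction, edges$target_direction)
  first <- !duplicated(ids)
  conflict <- tapply(paste(classes, dirs), ids, function(x) length(unique(x)))
  if (length(conflict) && any(conflict > 1))
    stopf("conflicting class/direction for node(s): %s",
          paste(names(conflict)[conflict > 1], collapse = ", "))
  nodes <- data.frame(id = ids[first], class = classes[first],
                      direction = dirs[first], stringsAsFactors = FALSE)
  deg <- table(c(edges$regulator, edges$target))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes <- nodes[order_c(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order_c(edges$regulator, edges$target, edges$evidence), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, kind = kind),
            class = "cerna_network")
}

#' Build a pairwise regulatory network
#'
#' Nodes are the edge endpoints (lexicographic order), with class, DE
#' direction and degree; duplicate (regulator, target, evidence) edges
#' collapse.  Edges whose endpoint classes do not match the declared kind
#' are rejected.
#'
#' @param edges `RegulatoryEdge` data frame from
#'   [anticorrelation_filter()].
#' @param kind `"mirna_mrna"`, `"lncrna_mrna"` or `"mirna_lncrna"`.
#' @return A `cerna_network` object.
#' @export
build_pair_network <- function(edges, kind = names(NETWORK_KINDS)[1:3]) {
  kind <- match.arg(kind)
  stopifnot(all(EDGE_COLUMNS %in% names(edges)))
  allowed <- NETWORK_KINDS[[kind]]
  ok <- edges$regulator_class == allowed[1] & edges$target_class == allowed[2]
  if (any(!ok))
    stopf("%d edge(s) have classes other than %s -> %s", sum(!ok),
          allowed[1], allowed[2])
  bad <- edges$regulator_direction == edges$target_direction
  if (any(bad)) stopf("%d edge(s) violate the opposite-direction constraint",
                      sum(bad))
  edges <- edges[!duplicated(edges[, c("regulator", "target", "evidence")]), ,
                 drop = FALSE]
  new_network(edges, kind)
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %s: %d nodes, %d edges\n", x$kind,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Integrate pairwise networks into tripartite ceRNA networks
#'
#' Builds the two tripartite views from the miRNA-mRNA, miRNA-lncRNA and
#' lncRNA-mRNA pairwise networks:
#' * the miRNA-centered network (`mirna_mrna_lncrna`): all edges incident
#'   to miRNAs that have at least one mRNA target *and* one lncRNA
#'   partner;
#' * the lncRNA-centered network (`lncrna_mirna_mrna`): the edges of every
#'   triad `(l, m, g)` with `edge(m -> l)` and `edge(m -> g)`, plus any
#'   lncRNA-mRNA edges between triad members.
#' In every triad the lncRNA and mRNA share a direction opposite to the
#' miRNA's (forced by the sign constraint).  Venn partitions compare, in
#' the miRNA-centered summary, mRNAs targeted by DE miRNAs vs mRNAs paired
#' with DE lncRNAs; in the lncRNA-centered summary, miRNAs pairing with
#' lncRNAs vs miRNAs targeting mRNAs.
#'
#' @param mirna_mrna,mirna_lncrna,lncrna_mrna `cerna_network` objects of
#'   the corresponding pairwise kinds.
#' @return A list with `mirna_centered` and `lncrna_centered`, each holding
#'   `network` (a `cerna_network`) and `summary` (triads, venn counts, and
#'   a per-node degree table).
#' @export
integrate_tripartite <- function(mirna_mrna, mirna_lncrna, lncrna_mrna) {
  stopifnot(inherits(mirna_mrna, "cerna_network"),
            inherits(mirna_lncrna, "cerna_network"),
            inherits(lncrna_mrna, "cerna_network"))
  if (mirna_mrna$kind != "mirna_mrna" || mirna_lncrna$kind != "mirna_lncrna" ||
      lncrna_mrna$kind != "lncrna_mrna")
    stopf("inputs must be the three pairwise network kinds")
  all_nodes <- rbind(mirna_mrna$nodes[, 1:3], mirna_lncrna$nodes[, 1:3],
                     lncrna_mrna$nodes[, 1:3])
  conflicts <- tapply(paste(all_nodes$class, all_nodes$direction),
                      all_nodes$id, function(x) length(unique(x)))
  if (length(conflicts) && any(conflicts > 1))
    stopf("node direction/class conflicts across input networks: %s",
          paste(names(conflicts)[conflicts > 1], collapse = ", "))

  mm <- mirna_mrna$edges; ml <- mirna_lncrna$edges; lm <- lncrna_mrna$edges
  focus_mirnas <- sort_c(intersect(unique(mm$regulator), unique(ml$regulator)))

  # miRNA-centered network
  keep_mm <- mm[mm$regulator %in% focus_mirnas, , drop = FALSE]
  keep_ml <- ml[ml$regulator %in% focus_mirnas, , drop = FALSE]
  mirna_net <- new_network(rbind(keep_mm, keep_ml), "mirna_mrna_lncrna")

  # triads: every (lncRNA, miRNA, mRNA) with edge(m->l) and edge(m->g)
  triads <- empty_triads()
  for (m in focus_mirnas) {
    ls <- sort_c(ml$target[ml$regulator == m])
    gs <- sort_c(mm$target[mm$regulator == m])
    if (length(ls) && length(gs)) {
      grid <- expand.grid(lncrna = ls, mrna = gs, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
      mdir <- ml$regulator_direction[match(m, ml$regulator)]
      triads <- rbind(triads, data.frame(
        lncrna = grid$lncrna, mirna = m, mrna = grid$mrna,
        mirna_direction = mdir,
        partner_direction = ifelse(mdir == "up", "down", "up"),
        stringsAsFactors = FALSE))
    }
  }
  triads <- triads[order_c(triads$lncrna, triads$mirna, triads$mrna), ,
                   drop = FALSE]
  rownames(triads) <- NULL

  lnc_edges <- rbind(
    ml[paste(ml$regulator, ml$target) %in% paste(triads$mirna, triads$lncrna), ,
       drop = FALSE],
    mm[paste(mm$regulator, mm$target) %in% paste(triads$mirna, triads$mrna), ,
       drop = FALSE],
    lm[paste(lm$regulator, lm$target) %in% paste(triads$lncrna, triads$mrna), ,
       drop = FALSE])
  lnc_net <- new_network(lnc_edges, "lncrna_mirna_mrna")

  venn <- function(a, b) {
    list(shared = length(intersect(a, b)),
         first_only = length(setdiff(a, b)),
         second_only = length(setdiff(b, a)),
         union = length(union(a, b)))
  }
  mirna_summary <- list(
    triads = triads,
    venn = venn(unique(mm$target), unique(lm$target)),
    degrees = mirna_net$nodes[, c("id", "class", "degree")])
  lncrna_summary <- list(
    triads = triads,
    venn = venn(unique(ml$regulator), unique(mm$regulator)),
    degrees = lnc_net$nodes[, c("id", "class", "degree")])

  list(mirna_centered = list(network = mirna_net, summary = mirna_summary),
       lncrna_centered = list(network = lnc_net, summary = lncrna_summary))
}

empty_triads <- function() {
  data.frame(lncrna = character(0), mirna = character(0), mrna = character(0),
             mirna_direction = character(0), partner_direction = character(0),
             stringsAsFactors = FALSE)
}

#' Rank hub nodes by degree
#'
#' @param network a `cerna_network`.
#' @param top_k how many nodes to return (all if fewer).
#' @return Node data frame ordered by descending degree, ties broken
#'   lexicographically by id.
#' @export
hub_nodes <- function(network, top_k = 10L) {
  stopifnot(inherits(network, "cerna_network"))
  top_k <- assert_count(top_k, "top_k")
  nodes <- network$nodes
  nodes <- nodes[order_c(-nodes$degree, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  head(nodes, top_k)
}

network_to_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("regulator", "target", "evidence", "score")],
    directed = TRUE,
    vertices = network$nodes[, c("id", "class", "direction", "degree")])
  g <- igraph::set_graph_attr(g, "kind", network$kind)
  g
}

#' Export a ceRNA network for Cytoscape
#'
#' GraphML carries node attributes (class, direction, degree) and edge
#' attributes (evidence, score) plus the network kind as a graph
#' attribute; reading our own GraphML back reproduces the network exactly.
#' SIF uses the relation token `represses`, one line per edge.
#'
#' @param network a `cerna_network`.
#' @param format `"graphml"` or `"sif"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, format = c("graphml", "sif"), path) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network_to_igraph(network), path, format = "graphml")
  } else {
    lines <- sprintf("%s\trepresses\t%s", network$edges$regulator,
                     network$edges$target)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a GraphML file written by [export_network()]
#'
#' @param path GraphML path.
#' @return A `cerna_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      class = igraph::vertex_attr(g, "class"),
                      direction = igraph::vertex_attr(g, "direction"),
                      degree = as.integer(igraph::vertex_attr(g, "degree")),
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(regulator = el[, 1],
                      regulator_class = nodes$class[match(el[, 1], nodes$id)],
                      regulator_direction = nodes$direction[match(el[, 1], nodes$id)],
                      target = el[, 2],
                      target_class = nodes$class[match(el[, 2], nodes$id)],
                      target_direction = nodes$direction[match(el[, 2], nodes$id)],
                      evidence = igraph::edge_attr(g, "evidence") %||% character(0),
                      score = igraph::edge_attr(g, "score") %||% numeric(0),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order_c(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order_c(edges$regulator, edges$target, edges$evidence), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 kind = igraph::graph_attr(g, "kind")),
            class = "cerna_network")
}
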