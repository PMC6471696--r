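#' Discount edge costs adjacent to context nodes
#'
#' The context algorithm biases the key-node search toward paths through
#' the products of up-regulated genes: every edge whose source or target
#' is a context node has its cost multiplied by `discount`. The input
#' graph is not modified.
#'
#' @param graph A [signaling_graph].
#' @param context_nodes Character vector of node ids (typically products
#'   of up-regulated genes).
#' @param discount Multiplier in (0, 1\]; 1 leaves the graph unchanged.
#' @return A new [signaling_graph] with modified costs.
#' @export
apply_context <- function(graph, context_nodes, discount = 0.5) {
  if (discount <= 0 || discount > 1) abort("`discount` must be in (0, 1].")
  unknown <- setdiff(context_nodes, graph$nodes$id)
  if (length(unknown) > 0) {
    warn(sprintf("%d context node(s) not in graph; ignored.",
                 length(unknown)))
    context_nodes <- setdiff(context_nodes, unknown)
  }
  e <- graph$edges
  hit <- e$from %in% context_nodes | e$to %in% context_nodes
  e$cost[hit] <- e$cost[hit] * discount
  signaling_graph(e, graph$nodes)
}

# Hop-bounded min-cost distances *to* a target node over the directed
# graph: truncated Bellman-Ford, one relaxation round per allowed step,
# which yields for every node the cheapest path to `target` using at most
# `radius` edges. Also records, per node, the successor on that path.
bounded_dist_to <- function(edges, node_ids, target, radius) {
  d <- setNames(rep(Inf, length(node_ids)), node_ids)
  nxt <- setNames(rep(NA_character_, length(node_ids)), node_ids)
  d[target] <- 0
  for (r in seq_len(radius)) {
    cand <- edges$cost + d[edges$to]
    improve <- cand < d[edges$from]
    if (!any(improve)) break
    # per source node, the best improving edge this round
    idx <- which(improve)
    best <- tapply(idx, edges$from[idx], function(ii) {
      ii[which.min(cand[ii])]
    })
    bi <- unlist(best)
    d[edges$from[bi]] <- cand[bi]
    nxt[edges$from[bi]] <- edges$to[bi]
  }
  list(dist = d, nxt = nxt)
}

#' Key-node (master-regulator) search
#'
#' Ranks every node of a weighted directed signalling network as a
#' candidate common regulator of a set of input transcription factors.
#' For a candidate k, min-cost paths of at most `radius` edges from k to
#' each input TF are found (truncated Bellman-Ford); the score is
#'
#' `score(k) = sum over reached inputs t of 1 / (1 + cost(k -> t))`
#' divided by the total number of nodes reachable from k within `radius`
#' steps — rewarding regulators that reach many inputs cheaply while
#' penalising promiscuous hubs. Nodes reaching no input are omitted.
#'
#' @param graph A [signaling_graph].
#' @param input_tfs Character vector of input TF node ids.
#' @param radius Maximum number of steps (edges) of the search
#'   (default 10).
#' @param max_path_cost Inputs costing more than this are not counted as
#'   reached (default Inf).
#' @return A tibble of class `keynode_result`: `node`, `score`,
#'   `n_reached`, `total_reachable`, `reached` (list-column of per-input
#'   costs), `paths` (list-column of path node sequences), sorted by
#'   descending score (ties: more reached inputs, then id).
#' @export
keynode_search <- function(graph, input_tfs, radius = 10,
                           max_path_cost = Inf) {
  if (radius < 1) abort("`radius` must be >= 1.")
  if (length(input_tfs) == 0) abort("`input_tfs` must be non-empty.")
  missing <- setdiff(input_tfs, graph$nodes$id)
  if (length(missing) > 0) {
    abort(paste0("Input TFs not in graph: ", paste(missing, collapse = ", ")))
  }
  ids <- graph$nodes$id
  e <- graph$edges
  # one hop-bounded backward search per input TF
  searches <- lapply(input_tfs, function(t) {
    bounded_dist_to(e, ids, t, radius)
  })
  names(searches) <- input_tfs
  # reachable-node counts within `radius` unweighted steps, self excluded
  g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                     vertices = ids, directed = TRUE)
  reach <- igraph::ego_size(g, order = radius, nodes = ids,
                            mode = "out", mindist = 1)
  names(reach) <- ids
  rows <- purrr::map(ids, function(k) {
    costs <- vapply(searches, function(s) s$dist[[k]], 0.0)
    ok <- is.finite(costs) & costs <= max_path_cost
    if (!any(ok) || reach[[k]] == 0) return(NULL)
    paths <- lapply(input_tfs[ok], function(t) {
      trace_path(searches[[t]]$nxt, k, t)
    })
    names(paths) <- input_tfs[ok]
    tibble(
      node = k,
      score = sum(1 / (1 + costs[ok])) / reach[[k]],
      n_reached = sum(ok),
      total_reachable = reach[[k]],
      reached = list(costs[ok]),
      paths = list(paths)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(node = character(), score = numeric(),
                  n_reached = integer(), total_reachable = integer(),
                  reached = list(), paths = list())
  } else {
    out <- dplyr::arrange(out, dplyr::desc(.data$score),
                          dplyr::desc(.data$n_reached), .data$node)
  }
  class(out) <- c("keynode_result", class(out))
  out
}

trace_path <- function(nxt, from, to) {
  path <- from
  cur <- from
  for (i in seq_len(length(nxt) + 1)) {
    if (identical(cur, to)) return(path)
    cur <- nxt[[cur]]
    if (is.na(cur)) break
    path <- c(path, cur)
  }
  path
}

#' @rdname keynode_search
#' @param x A `keynode_result`.
#' @param ... Unused.
#' @export
tidy.keynode_result <- function(x, ...) {
  tibble(node = x$node, score = x$score, n_reached = x$n_reached,
         total_reachable = x$total_reachable)
}

#' @rdname keynode_search
#' @param object A `keynode_result`.
#' @export
autoplot.keynode_result <- function(object, ...) {
  df <- tidy(object)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(utils::head(df, 25),
                  ggplot2::aes(x = .data$score, y = .data$node)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "key-node score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Enumerate feedback loops through a node
#'
#' Finds all simple cycles of length at most `max_len` edges passing
#' through `keynode` that traverse at least one regulatory (TF-to-gene)
#' edge — the closure by which a regulator can re-activate its own gene.
#' The sign product over the cycle marks positive (self-amplifying) loops.
#' Edges are regulatory when flagged in the edge table, or, failing that,
#' when their target node has kind `"gene"`.
#'
#' @param graph A [signaling_graph] whose gene nodes link back to their
#'   product nodes (gene-to-protein edges present).
#' @param keynode Node id the loops must pass through.
#' @param max_len Maximum cycle length in edges (>= 2).
#' @param context_nodes Optional node ids counted per loop.
#' @return Tibble with columns `nodes` (list-column; first node repeated
#'   last), `length`, `sign_product`, `positive`, `has_regulatory_edge`,
#'   `n_context_nodes`.
#' @export
find_feedback_loops <- function(graph, keynode, max_len = 8,
                                context_nodes = character()) {
  if (max_len < 2) abort("`max_len` must be >= 2.")
  if (!keynode %in% graph$nodes$id) abort("`keynode` not in graph.")
  e <- graph$edges
  reg_edge <- e$regulatory
  if (!any(reg_edge)) {
    kind <- setNames(graph$nodes$kind, graph$nodes$id)
    reg_edge <- kind[e$to] == "gene"
  }
  adj <- split(seq_len(nrow(e)), e$from)
  loops <- list()
  # bounded DFS over simple paths starting and ending at keynode
  walk <- function(node, path_nodes, path_edges) {
    out_edges <- adj[[node]]
    if (is.null(out_edges)) return()
    for (ei in out_edges) {
      nb <- e$to[ei]
      if (identical(nb, keynode)) {
        edges <- c(path_edges, ei)
        loops[[length(loops) + 1L]] <<- edges
      } else if (!(nb %in% path_nodes) && length(path_edges) + 1L < max_len) {
        walk(nb, c(path_nodes, nb), c(path_edges, ei))
      }
    }
  }
  walk(keynode, keynode, integer(0))
  rows <- purrr::map(loops, function(edges) {
    if (!any(reg_edge[edges])) return(NULL)
    nodes <- c(e$from[edges], keynode)
    tibble(
      nodes = list(nodes),
      length = length(edges),
      sign_product = prod(e$sign[edges]),
      positive = prod(e$sign[edges]) == 1,
      has_regulatory_edge = TRUE,
      n_context_nodes = length(intersect(unique(nodes), context_nodes))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(nodes = list(), length = integer(),
                  sign_product = integer(), positive = logical(),
                  has_regulatory_edge = logical(), n_context_nodes = integer())
  }
  out
}

#' Prioritise master-regulator candidates by omics evidence
#'
#' Aggregates key-node scores to genes (the best-scoring isoform wins),
#' joins differential expression and differential methylation statistics,
#' and keeps genes whose absolute expression and methylation log fold
#' changes pass the thresholds, ordered by key-node score.
#'
#' @param results A [keynode_search()] result.
#' @param expression Differential-expression tibble ([diff_stats()]
#'   columns) keyed by `feature`.
#' @param methylation Differential-methylation tibble keyed by `feature`.
#' @param gene_of Named character vector mapping node ids to gene ids;
#'   nodes without a mapping use their own id.
#' @param lfc_expression,lfc_methylation Minimum absolute log2 fold
#'   changes (defaults 1.0 and 0.585, i.e. fold change 1.5).
#' @return Tibble: `gene`, `node`, `score`, `n_reached`,
#'   `expression_logFC`, `methylation_logFC`, ordered by score.
#' @export
prioritize_regulators <- function(results, expression, methylation,
                                  gene_of = NULL,
                                  lfc_expression = 1.0,
                                  lfc_methylation = log2(1.5)) {
  df <- tidy(results)
  df$gene <- if (is.null(gene_of)) df$node else {
    g <- gene_of[df$node]
    ifelse(is.na(g), df$node, g)
  }
  # best isoform per gene
  df <- df |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  ex <- setNames(expression$logFC, expression$feature)
  me <- setNames(methylation$logFC, methylation$feature)
  df$expression_logFC <- unname(ex[df$gene])
  df$methylation_logFC <- unname(me[df$gene])
  dropped <- is.na(df$expression_logFC) | is.na(df$methylation_logFC)
  if (any(dropped)) {
    warn(sprintf("%d candidate(s) without omics statistics dropped.",
                 sum(dropped)))
    df <- df[!dropped, ]
  }
  df <- df[abs(df$expression_logFC) >= lfc_expression &
             abs(df$methylation_logFC) >= lfc_methylation, ]
  dplyr::select(
    dplyr::arrange(df, dplyr::desc(.data$score)),
    "gene", "node", "score", "n_reached",
    "expression_logFC", "methylation_logFC"
  )
}
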