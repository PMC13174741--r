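#' Read a STRING-style edge list into a simple undirected graph
#'
#' Expects a TSV with two protein-identifier columns and a combined score on
#' the 0-1000 scale (columns `protein1`, `protein2`, `combined_score`, or the
#' first three columns). Edges below `min_score` are dropped, pairs are
#' canonicalized (unordered), self-loops and duplicates removed. Nodes from
#' an optional node list are retained even when isolated.
#'
#' @param path TSV path.
#' @param min_score confidence cutoff; 700 is the conventional
#'   "high confidence" level.
#' @param nodes optional character vector of node ids to retain as degree-0
#'   vertices if absent from the edge list.
#' @return an undirected simple `igraph` with edge attribute
#'   `combined_score`.
#' @export
read_string_edges <- function(path, min_score = 700, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L && ncol(df) < 3L) {
    df <- data.frame(protein1 = character(0), protein2 = character(0),
                     combined_score = numeric(0))
  }
  cols <- c("protein1", "protein2", "combined_score")
  if (!all(cols %in% names(df))) {
    if (ncol(df) < 3L) stop("edge list needs 3 columns")
    df <- df[, 1:3]
    names(df) <- cols
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- which(is.na(score) & !is.na(df$combined_score))
  if (length(bad))
    stop(sprintf("unparsable combined_score at line %d", bad[1L] + 1L))
  df$combined_score <- score
  df <- df[df$combined_score >= min_score, , drop = FALSE]
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  dup <- duplicated(paste(a, b, sep = "\r"))
  df <- data.frame(from = a[!dup], to = b[!dup],
                   combined_score = df$combined_score[!dup],
                   stringsAsFactors = FALSE)
  verts <- unique(c(df$from, df$to, nodes))
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = verts))
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Degree, betweenness and closeness centrality
#'
#' Unweighted classical centralities: degree; betweenness normalized by
#' `(n-1)(n-2)/2` so values read as the fraction of shortest paths passing
#' through the node; and Wasserman-Faust closeness
#' `((r-1)/sum d) * ((r-1)/(n-1))` over the `r` reachable nodes, which
#' handles disconnected graphs (isolated nodes score 0).
#'
#' @param g an igraph.
#' @return data frame with columns `node`, `DC`, `BC`, `CC`.
#' @export
classical_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  dc <- igraph::degree(g)
  bc <- if (n > 2L) igraph::betweenness(g, directed = FALSE,
                                        normalized = TRUE)
        else rep(0, n)
  d <- igraph::distances(g)
  cc <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    r <- length(dv) + 1L
    if (r < 2L || n < 2L) return(0)
    ((r - 1) / sum(dv)) * ((r - 1) / (n - 1))
  }, numeric(1))
  data.frame(node = igraph::V(g)$name %||% as.character(seq_len(n)),
             DC = as.numeric(dc), BC = as.numeric(bc), CC = cc,
             stringsAsFactors = FALSE)
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v)` is the sum over all maximal cliques containing `v` of
#' `(|C| - 1)!`. For a node whose neighborhood induces no edges this reduces
#' to its degree (each edge is a maximal 2-clique); isolated nodes score 0.
#' Maximal cliques are enumerated by Bron-Kerbosch with pivoting.
#'
#' @param g an igraph.
#' @param clique_cap abort if the graph has more maximal cliques than this
#'   (pathological inputs should be decomposed first).
#' @return named numeric vector of MCC scores.
#' @export
mcc_centrality <- function(g, clique_cap = 1e6) {
  n <- igraph::vcount(g)
  nms <- igraph::V(g)$name %||% as.character(seq_len(n))
  out <- stats::setNames(numeric(n), nms)
  if (igraph::ecount(g) == 0L) return(out)
  cl <- igraph::max_cliques(g, min = 2L)
  if (length(cl) > clique_cap)
    stop("more than ", clique_cap,
         " maximal cliques; decompose the graph first")
  for (C in cl) {
    w <- factorial(length(C) - 1L)
    out[as.integer(C)] <- out[as.integer(C)] + w
  }
  out
}

#' Density of the maximum neighborhood component (DMNC)
#'
#' `DMNC(v) = E / V^eps` (eps = 1.7) of the largest connected component of
#' the subgraph induced by `v`'s neighbors (excluding `v` itself). Nodes
#' whose neighborhood induces no edges score 0. Component-size ties are
#' broken by larger edge count, then by the lexicographically smallest
#' member.
#'
#' @param g an igraph.
#' @param eps the density exponent.
#' @return named numeric vector of DMNC scores.
#' @export
dmnc_centrality <- function(g, eps = 1.7) {
  n <- igraph::vcount(g)
  nms <- igraph::V(g)$name %||% as.character(seq_len(n))
  vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    nb <- setdiff(nb, v)
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0L) return(0)
    comp <- igraph::components(sub)
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    if (length(cand) > 1L) {
      ec <- vapply(cand, function(ci)
        igraph::ecount(igraph::induced_subgraph(sub,
                                                which(comp$membership == ci))),
        numeric(1))
      cand <- cand[ec == max(ec)]
      if (length(cand) > 1L) {
        first_member <- vapply(cand, function(ci)
          min(igraph::V(sub)$name[comp$membership == ci]), character(1))
        cand <- cand[order(first_member)][1L]
      }
    }
    ci <- cand[1L]
    mem <- which(comp$membership == ci)
    e <- igraph::ecount(igraph::induced_subgraph(sub, mem))
    e / length(mem)^eps
  }, numeric(1)) -> out
  stats::setNames(out, nms)
}

#' Five-centrality consensus ranking of network nodes
#'
#' Computes DC, BC, CC (classical), MCC and DMNC, min-max normalizes each
#' metric across nodes to `[0, 1]` (a constant metric maps to all zeros and
#' is flagged), averages the five normalized values into a consensus score,
#' and ranks nodes by descending consensus with ties broken by node id.
#'
#' @param g an igraph.
#' @param top_k number of candidates to return (all nodes, with a warning,
#'   when the graph is smaller).
#' @return list with `table` (per-node raw + normalized metrics, `consensus`,
#'   `rank`), `top` (character vector of the top-`top_k` node ids), and
#'   `degenerate_metrics` (names of constant metrics).
#' @export
consensus_rank <- function(g, top_k = 20L) {
  tab <- classical_centralities(g)
  tab$MCC <- as.numeric(mcc_centrality(g)[tab$node])
  tab$DMNC <- as.numeric(dmnc_centrality(g)[tab$node])
  metrics <- c("DC", "BC", "CC", "MCC", "DMNC")
  degenerate <- character(0)
  for (mc in metrics) {
    v <- tab[[mc]]
    rng <- range(v)
    if (diff(rng) <= .Machine$double.eps) {
      tab[[paste0(mc, "_norm")]] <- rep(0, length(v))
      degenerate <- c(degenerate, mc)
    } else {
      tab[[paste0(mc, "_norm")]] <- (v - rng[1L]) / diff(rng)
    }
  }
  tab$consensus <- rowMeans(tab[, paste0(metrics, "_norm")])
  ord <- order(-tab$consensus, tab$node)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) < top_k)
    warning("graph has fewer than top_k nodes; returning all")
  list(table = tab, top = utils::head(tab$node, top_k),
       degenerate_metrics = degenerate)
}

#' Closeness-centered subnetwork
#'
#' Extracts the subnetwork spanned by the `top_k` nodes ranked by closeness
#' centrality, their first-degree neighbors, and every node lying on at least
#' one shortest path between a pair of top nodes. Node roles are tagged
#' `hub` > `interactor` > `path` (a node keeps the highest-precedence role it
#' qualifies for).
#'
#' @param g an igraph.
#' @param top_k number of closeness hubs to seed the subnetwork with.
#' @return the induced `igraph` subgraph with vertex attribute `role`.
#' @export
cc_subnetwork <- function(g, top_k = 20L) {
  cent <- classical_centralities(g)
  ord <- order(-cent$CC, cent$node)
  hubs <- cent$node[utils::head(ord, top_k)]
  nbrs <- unique(unlist(lapply(hubs, function(h)
    igraph::V(g)$name[as.integer(igraph::neighbors(g, h))])))
  path_nodes <- character(0)
  if (length(hubs) > 1L) {
    for (i in seq_len(length(hubs) - 1L)) {
      sp <- igraph::all_shortest_paths(g, from = hubs[i],
                                       to = hubs[(i + 1L):length(hubs)])
      path_nodes <- c(path_nodes,
                      unlist(lapply(sp$res, function(p) igraph::V(g)$name[as.integer(p)])))
    }
    path_nodes <- unique(path_nodes)
  }
  keep <- unique(c(hubs, nbrs, path_nodes))
  sub <- igraph::induced_subgraph(g, keep)
  role <- rep("path", igraph::vcount(sub))
  nm <- igraph::V(sub)$name
  role[nm %in% nbrs] <- "interactor"
  role[nm %in% hubs] <- "hub"
  igraph::V(sub)$role <- role
  sub
}

#' Write a centrality table and subnetwork edge list to TSV
#'
#' @param ranking result of [consensus_rank()].
#' @param sub optional subnetwork from [cc_subnetwork()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_netrank <- function(ranking, sub = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "centrality_table.tsv")
  utils::write.table(ranking$table, paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  top_path <- file.path(dir, "top_candidates.tsv")
  utils::write.table(data.frame(node = ranking$top), top_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, top_path)
  if (!is.null(sub)) {
    el <- igraph::as_data_frame(sub, what = "edges")
    roles <- stats::setNames(igraph::V(sub)$role, igraph::V(sub)$name)
    el$from_role <- roles[el$from]
    el$to_role <- roles[el$to]
    sub_path <- file.path(dir, "cc_subnetwork_edges.tsv")
    utils::write.table(el, sub_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, sub_path)
  }
  invisible(paths)
}
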