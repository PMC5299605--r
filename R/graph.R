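#' Weighted directed graph for boundary search
#'
#' A light container for the graphs used by the CSI search: nodes carry
#' image coordinates, edges carry non-negative weights and run left to
#' right (ascending x). Two virtual endpoint nodes (`x = -Inf` / `+Inf`)
#' make the start/end choice cost-neutral: the virtual start has only
#' outgoing zero-weight edges to the first occupied column, the virtual
#' end only incoming ones from the last.
#'
#' @param nodes Tibble with columns `id` (1..n), `x`, `z` and logical
#'   `virtual`.
#' @param edges Tibble with columns `from`, `to` (node ids) and `w`
#'   (weight, `>= 0`).
#' @return A list of class `graph_spec`.
#' @export
graph_spec <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (nrow(edges) > 0 && any(edges$w < 0)) abort("edge weights must be non-negative")
  if (nrow(edges) > 0) {
    vstart <- nodes$id[nodes$virtual & nodes$x == -Inf]
    vend <- nodes$id[nodes$virtual & nodes$x == Inf]
    if (length(vstart) && any(edges$to %in% vstart)) {
      abort("virtual start node cannot have incoming edges")
    }
    if (length(vend) && any(edges$from %in% vend)) {
      abort("virtual end node cannot have outgoing edges")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "graph_spec")
}

#' Dijkstra shortest path with a deterministic tie-break
#'
#' Finds a minimum-total-weight path from `source` to `target`. Among
#' equal-weight paths the lexicographically smallest node-id sequence is
#' returned, which makes the search fully deterministic.
#'
#' @param g A [graph_spec()].
#' @param source,target Node ids.
#' @return Integer vector of node ids along the path (including both
#'   endpoints), or `NULL` if `target` is unreachable.
#' @export
shortest_path <- function(g, source, target) {
  n <- nrow(g$nodes)
  ids <- g$nodes$id
  to_idx <- match(g$edges$to, ids)
  adj_from <- split(seq_len(nrow(g$edges)), g$edges$from)
  dist <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  si <- match(source, ids); ti <- match(target, ids)
  if (is.na(si) || is.na(ti)) abort("source/target not in graph")
  dist[si] <- 0

  path_to <- function(i) {
    p <- integer(0)
    while (!is.na(i)) {
      p <- c(ids[i], p)
      i <- parent[i]
    }
    p
  }
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (j in seq_len(k)) {
      if (a[j] < b[j]) return(TRUE)
      if (a[j] > b[j]) return(FALSE)
    }
    length(a) < length(b)
  }

  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[order(dist[cand], ids[cand])][1]
    if (u == ti) break
    done[u] <- TRUE
    ekeys <- adj_from[[as.character(ids[u])]]
    if (is.null(ekeys)) next
    for (e in ekeys) {
      v <- to_idx[e]
      nd <- dist[u] + g$edges$w[e]
      if (nd < dist[v]) {
        dist[v] <- nd
        parent[v] <- u
      } else if (nd == dist[v] && !is.na(parent[v])) {
        old <- parent[v]
        newp <- c(path_to(u), ids[v])
        oldp <- c(path_to(old), ids[v])
        if (lex_less(newp, oldp)) parent[v] <- u
      }
    }
  }
  if (!is.finite(dist[ti])) return(NULL)
  path_to(ti)
}

# Total weight of a node-id path in g (tests and scoring helper).
path_weight <- function(g, path) {
  if (length(path) < 2) return(0)
  w <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which(g$edges$from == path[k] & g$edges$to == path[k + 1])
    if (length(e) == 0) return(Inf)
    w <- w + min(g$edges$w[e])
  }
  w
}

#' Decompose a graph into weakly connected fragments
#'
#' Partitions the non-virtual nodes into weakly connected components
#' (edge direction ignored) and returns each as a fresh [graph_spec()]
#' with its own virtual endpoints attached by zero-weight edges to the
#' nodes of its leftmost and rightmost occupied columns. Fragments are
#' ordered by their leftmost column.
#'
#' @param g A [graph_spec()] (virtual nodes, if present, are dropped).
#' @return List of `graph_spec` fragments (empty list for an empty graph).
#' @export
graph_fragments <- function(g) {
  real <- g$nodes[!g$nodes$virtual, , drop = FALSE]
  if (nrow(real) == 0) return(list())
  e <- g$edges[g$edges$from %in% real$id & g$edges$to %in% real$id, , drop = FALSE]
  comp <- setNames(rep(NA_integer_, nrow(real)), real$id)
  nbr <- split(c(e$to, e$from), c(e$from, e$to))
  cid <- 0L
  for (start in real$id) {
    if (!is.na(comp[as.character(start)])) next
    cid <- cid + 1L
    queue <- start
    comp[as.character(start)] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      vs <- nbr[[as.character(u)]]
      vs <- vs[is.na(comp[as.character(vs)])]
      if (length(vs)) {
        comp[as.character(vs)] <- cid
        queue <- c(queue, unique(vs))
      }
    }
  }
  frags <- lapply(seq_len(cid), function(k) {
    ids <- as.integer(names(comp)[comp == k])
    nd <- real[real$id %in% ids, , drop = FALSE]
    ed <- e[e$from %in% ids & e$to %in% ids, , drop = FALSE]
    attach_virtual_endpoints(nd, ed)
  })
  left <- vapply(frags, function(f) min(f$nodes$x[!f$nodes$virtual]), numeric(1))
  frags[order(left)]
}

# Add virtual start/end nodes wired with zero weight to the nodes of the
# first / last occupied column.
attach_virtual_endpoints <- function(nodes, edges) {
  vs <- max(nodes$id, 0L) + 1L
  ve <- vs + 1L
  first_x <- min(nodes$x)
  last_x <- max(nodes$x)
  nodes2 <- dplyr::bind_rows(
    nodes,
    tibble(id = c(vs, ve), x = c(-Inf, Inf), z = c(NA_real_, NA_real_),
           virtual = TRUE)
  )
  nodes2$virtual[is.na(nodes2$virtual)] <- FALSE
  e_start <- tibble(from = vs, to = nodes$id[nodes$x == first_x], w = 0)
  e_end <- tibble(from = nodes$id[nodes$x == last_x], to = ve, w = 0)
  graph_spec(nodes2, dplyr::bind_rows(edges, e_start, e_end))
}
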