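#' @name empc
#' @title Extended minimum path cover on a splice graph
#'
#' @description
#' The assembly problem per back-splice event: given the splice graph (a
#' DAG with one source and one sink, the two back-spliced exons) and the
#' family of read-witnessed subpaths, find a minimum number k of
#' source-to-sink paths such that (a) every node, (b) every edge and
#' (c) every subpath is covered, each path (d) running from source to sink.
#' Each returned path is one candidate full-length circular isoform.
#'
#' The solver casts conditions (a), (b) and (d) as a minimum-flow problem
#' with lower bounds: every node is split into an in/out arc with lower
#' bound 1, every edge becomes an arc with lower bound 1, and the minimum
#' source-to-sink flow is found by a feasible-flow construction followed by
#' flow-cancelling augmentation (two Edmonds-Karp style passes). Subpath
#' constraints (c) enter the same network as "token" arcs with lower bound
#' 1 that jump from the first to the last node of the subpath; elements
#' covered by a token lose their own lower bound, and tokens are expanded
#' back into their full node runs during path decomposition. The token
#' relaxation is exact unless one solution path would have to chain two
#' overlapping subpath constraints, so on small graphs the flow answer is
#' verified (and if necessary replaced) by a branch-and-bound set-cover
#' search over all source-to-sink paths, bounded below by the token-free
#' minimum flow. Tie-breaks everywhere prefer the smallest node index, so
#' the solution is deterministic.
NULL

# ---- arc-list flow network -------------------------------------------------

.INF <- 1e9L

# BFS augmenting-path max-flow between s and t on an arc list with lower
# bounds: forward residual cap - f, backward residual f - lb.
.flow_augment <- function(net, s, t, limit = Inf) {
  pushed <- 0L
  repeat {
    if (pushed >= limit) break
    # BFS
    prev_arc <- rep(NA_integer_, net$n_nodes)
    prev_dir <- rep(0L, net$n_nodes)
    visited <- rep(FALSE, net$n_nodes)
    visited[s] <- TRUE
    queue <- s
    while (length(queue) && !visited[t]) {
      u <- queue[1L]; queue <- queue[-1L]
      fw <- which(net$from == u & net$f < net$cap)
      for (a in fw[order(net$to[fw])]) {
        v <- net$to[a]
        if (!visited[v]) {
          visited[v] <- TRUE; prev_arc[v] <- a; prev_dir[v] <- 1L
          queue <- c(queue, v)
        }
      }
      bw <- which(net$to == u & net$f > net$lb)
      for (a in bw[order(net$from[bw])]) {
        v <- net$from[a]
        if (!visited[v]) {
          visited[v] <- TRUE; prev_arc[v] <- a; prev_dir[v] <- -1L
          queue <- c(queue, v)
        }
      }
    }
    if (!visited[t]) break
    # bottleneck
    delta <- limit - pushed
    v <- t
    while (v != s) {
      a <- prev_arc[v]
      delta <- min(delta, if (prev_dir[v] > 0L) net$cap[a] - net$f[a]
                          else net$f[a] - net$lb[a])
      v <- if (prev_dir[v] > 0L) net$from[a] else net$to[a]
    }
    v <- t
    while (v != s) {
      a <- prev_arc[v]
      net$f[a] <- net$f[a] + prev_dir[v] * delta
      v <- if (prev_dir[v] > 0L) net$from[a] else net$to[a]
    }
    pushed <- pushed + delta
  }
  list(net = net, pushed = pushed)
}

# Build the split-node lower-bound network. Token arcs are added for
# subpaths; node/edge arcs covered by some subpath get lower bound 0.
# Node i -> in node i, out node n+i; src entry is in_src, exit out_snk.
.empc_network <- function(n, edges, src, snk, subpaths) {
  covered_node <- rep(FALSE, n)
  edge_key <- function(u, v) paste0(u, ">", v)
  covered_edge <- character(0)
  for (sp in subpaths) {
    covered_node[sp] <- TRUE
    if (length(sp) > 1L)
      covered_edge <- c(covered_edge, edge_key(sp[-length(sp)], sp[-1L]))
  }
  from <- integer(0); to <- integer(0); lb <- integer(0)
  kind <- character(0); ref <- integer(0)
  # split arcs
  from <- c(from, seq_len(n)); to <- c(to, n + seq_len(n))
  lb <- c(lb, ifelse(covered_node, 0L, 1L))
  kind <- c(kind, rep("node", n)); ref <- c(ref, seq_len(n))
  # edge arcs
  if (nrow(edges)) {
    from <- c(from, n + edges[, 1L]); to <- c(to, edges[, 2L])
    lb <- c(lb, ifelse(edge_key(edges[, 1L], edges[, 2L]) %in% covered_edge,
                       0L, 1L))
    kind <- c(kind, rep("edge", nrow(edges))); ref <- c(ref, seq_len(nrow(edges)))
  }
  # token arcs
  for (j in seq_along(subpaths)) {
    sp <- subpaths[[j]]
    from <- c(from, sp[1L]); to <- c(to, n + sp[length(sp)])
    lb <- c(lb, 1L); kind <- c(kind, "token"); ref <- c(ref, j)
  }
  list(n_nodes = 2L * n, from = from, to = to, lb = lb,
       cap = rep(.INF, length(from)), f = rep(0L, length(from)),
       kind = kind, ref = ref, src = src, snk = snk, n = n,
       subpaths = subpaths)
}

# route one unit from in_src through arc a to out_snk (all caps infinite,
# graph pruned to source->sink nodes, so a route always exists)
.empc_feasible <- function(net) {
  n2 <- net$n_nodes
  # BFS tree from in_src and reverse BFS from out_snk over all arcs
  reach_path <- function(start, forward) {
    par <- rep(NA_integer_, n2); par_arc <- rep(NA_integer_, n2)
    seen <- rep(FALSE, n2); seen[start] <- TRUE; queue <- start
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      arcs <- if (forward) which(net$from == u) else which(net$to == u)
      for (a in arcs) {
        v <- if (forward) net$to[a] else net$from[a]
        if (!seen[v]) {
          seen[v] <- TRUE; par[v] <- u; par_arc[v] <- a; queue <- c(queue, v)
        }
      }
    }
    list(par = par, par_arc = par_arc, seen = seen)
  }
  fwd <- reach_path(net$src, TRUE)          # paths from in_src
  bwd <- reach_path(net$n + net$snk, FALSE) # paths to out_snk
  add_route <- function(node, tree, forward) {
    v <- node
    while (!is.na(tree$par_arc[v])) {
      a <- tree$par_arc[v]
      net$f[a] <<- net$f[a] + 1L
      v <- tree$par[v]
    }
  }
  total <- 0L
  for (a in which(net$lb > 0L)) {
    add_route(net$from[a], fwd, TRUE)
    net$f[a] <- net$f[a] + 1L
    add_route(net$to[a], bwd, FALSE)
    total <- total + 1L
  }
  list(net = net, value = total)
}

# minimum s-t flow with lower bounds; returns value and saturated network
.empc_minflow <- function(net) {
  fs <- .empc_feasible(net)
  net <- fs$net; value <- fs$value
  # cancel circulating flow: augment from out_snk to in_src in the residual
  res <- .flow_augment(net, net$n + net$snk, net$src, limit = value - 1L)
  list(net = res$net, value = value - res$pushed)
}

# decompose integer flow into source->sink node paths (token arcs expanded)
.empc_decompose <- function(net) {
  n <- net$n
  paths <- list()
  out_snk <- n + net$snk
  repeat {
    # start a new path if flow leaves in_src
    starts <- which(net$from == net$src & net$f > 0L)
    if (length(starts) == 0L) break
    path <- integer(0)
    v <- net$src
    while (TRUE) {
      arcs <- which(net$from == v & net$f > 0L)
      if (length(arcs) == 0L) break
      # prefer the plain split/edge arc with smallest next node, tokens last
      ord <- order(net$kind[arcs] == "token", net$to[arcs])
      a <- arcs[ord[1L]]
      net$f[a] <- net$f[a] - 1L
      if (net$kind[a] == "token") {
        sp <- net$subpaths[[net$ref[a]]]
        path <- c(path, sp)     # token covers sp entirely; lands at out end
      } else if (net$kind[a] == "node") {
        path <- c(path, net$ref[a])
      }
      v <- net$to[a]
      if (v == out_snk) break
    }
    paths[[length(paths) + 1L]] <- path
  }
  paths[order(vapply(paths, function(p) paste(sprintf("%06d", p), collapse = ","),
                     character(1)))]
}

# ---- public solver ---------------------------------------------------------

#' Solve the extended minimum path cover for one splice graph
#'
#' @param graph a `splice_graph` (see [build_splice_graph()]).
#' @param subpaths subpath evidence as returned by [extract_subpaths()]
#'   (or `NULL`).
#' @param exact_limit maximum node count for which the flow answer is
#'   verified by exhaustive-path branch and bound (default 12).
#' @param max_paths cap on enumerated source-to-sink paths for the exact
#'   search.
#' @return list of class `path_cover`: `paths` (list of integer node-index
#'   chains, each from source to sink), `k` (path count), `exact` (logical:
#'   solution proven minimal), `dropped_subpaths` (count of evidence runs
#'   discarded because they were not walks in the graph).
#' @export
solve_empc <- function(graph, subpaths = NULL, exact_limit = 12L,
                       max_paths = 2000L) {
  n <- nrow(graph$nodes)
  edges <- graph$edges
  runs <- if (is.null(subpaths)) list() else subpaths$runs
  mult <- if (is.null(subpaths)) integer(0) else subpaths$multiplicity

  if (graph$source == graph$sink) {
    return(structure(list(paths = list(graph$source), k = 1L, exact = TRUE,
                          dropped_subpaths = 0L), class = "path_cover"))
  }
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) adj[edges] <- TRUE
  is_walk <- vapply(runs, function(r)
    length(r) >= 2L && all(adj[cbind(r[-length(r)], r[-1L])]), logical(1))
  dropped <- sum(!is_walk)
  if (dropped > 0L)
    warning(dropped, " subpath(s) not walks in the graph; dropped")
  runs <- runs[is_walk]
  mult <- mult[is_walk]
  runs <- runs[lengths(runs) >= 3L]  # length-2 runs are just edges

  # lower bound: min flow without subpath constraints
  base <- .empc_minflow(.empc_network(n, edges, graph$source, graph$sink,
                                      list()))
  k_lower <- base$value
  sol_flow <- .empc_minflow(.empc_network(n, edges, graph$source, graph$sink,
                                          runs))
  paths <- .empc_decompose(sol_flow$net)
  k <- length(paths)
  exact <- (k == k_lower) || length(runs) == 0L
  if (n <= exact_limit) {
    # even when k is proven minimal, several minimum covers may exist; the
    # search also applies the longest-isoform-first tie-break among them
    allp <- .enumerate_st_paths(n, edges, graph$source, graph$sink, max_paths)
    if (!is.null(allp)) {
      bb <- .cover_branch_bound(allp, n, edges, runs, k_lower, k, paths)
      paths <- bb$paths
      k <- bb$k
      exact <- bb$exact || exact
    }
  }
  structure(list(paths = paths, k = k, exact = exact,
                 dropped_subpaths = dropped), class = "path_cover")
}

#' @export
print.path_cover <- function(x, ...) {
  cat("path_cover: k =", x$k, if (x$exact) "(proven minimal)" else "(heuristic)", "\n")
  for (p in x$paths) cat(" ", paste(p, collapse = " -> "), "\n")
  invisible(x)
}

# all source->sink paths in lexicographic order; NULL if more than cap
.enumerate_st_paths <- function(n, edges, src, snk, cap = 2000L) {
  nxt <- vector("list", n)
  if (nrow(edges)) for (i in seq_len(nrow(edges)))
    nxt[[edges[i, 1L]]] <- c(nxt[[edges[i, 1L]]], edges[i, 2L])
  nxt <- lapply(nxt, sort)
  out <- list()
  stack <- list(src)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- p[length(p)]
    if (v == snk) {
      out[[length(out) + 1L]] <- p
      if (length(out) > cap) return(NULL)
      next
    }
    for (w in rev(nxt[[v]])) stack[[length(stack) + 1L]] <- c(p, w)
  }
  out
}

# does path contain run as a contiguous slice?
.contains_run <- function(path, run) {
  m <- length(run); np <- length(path)
  if (m > np) return(FALSE)
  starts <- which(path == run[1L])
  for (s in starts) {
    if (s + m - 1L <= np && all(path[s:(s + m - 1L)] == run)) return(TRUE)
  }
  FALSE
}

# preference among equal-size covers: longest isoforms first (the all-exon
# chain is a priori the most common isoform), then lexicographic node order
.cover_pref <- function(paths) {
  lens <- sort(lengths(paths), decreasing = TRUE)
  key <- vapply(paths, function(p) paste(sprintf("%03d", p), collapse = ""),
                character(1))
  list(lens = lens, key = paste(sort(key), collapse = "|"))
}

.pref_better <- function(a, b) {
  la <- a$lens; lb <- b$lens
  m <- max(length(la), length(lb))
  la <- c(la, rep(-1L, m - length(la)))
  lb <- c(lb, rep(-1L, m - length(lb)))
  d <- la - lb
  nz <- which(d != 0L)
  if (length(nz)) return(d[nz[1L]] > 0L)
  a$key < b$key
}

# minimal set cover over enumerated paths by branch and bound, seeded with
# the flow solution as incumbent; among minimum covers the longest-first
# preference decides
.cover_branch_bound <- function(allp, n, edges, runs, k_lower, k_best,
                                paths_best) {
  ne <- nrow(edges)
  # element universe: nodes 1..n, edges n+1..n+ne, runs n+ne+1..
  n_elem <- n + ne + length(runs)
  covers <- lapply(allp, function(p) {
    el <- p
    if (ne) {
      pe <- cbind(p[-length(p)], p[-1L])
      idx <- match(paste(pe[, 1L], pe[, 2L]), paste(edges[, 1L], edges[, 2L]))
      el <- c(el, n + idx[!is.na(idx)])
    }
    for (j in seq_along(runs))
      if (.contains_run(p, runs[[j]])) el <- c(el, n + ne + j)
    el
  })
  cover_mat <- matrix(FALSE, length(allp), n_elem)
  for (i in seq_along(allp)) cover_mat[i, covers[[i]]] <- TRUE
  need <- which(colSums(cover_mat) > 0L)   # elements coverable at all
  best <- list(k = k_best, paths = paths_best, exact = FALSE,
               pref = .cover_pref(paths_best))
  # DFS over element-driven branching: pick uncovered element with fewest
  # covering paths, branch on those paths in lex order
  rec <- function(chosen, covered) {
    k_cur <- length(chosen)
    unc <- setdiff(need, covered)
    if (length(unc) == 0L) {
      cand <- allp[sort(chosen)]
      pref <- .cover_pref(cand)
      if (k_cur < best$k ||
          (k_cur == best$k && .pref_better(pref, best$pref)))
        best <<- list(k = k_cur, paths = cand, exact = TRUE, pref = pref)
      return()
    }
    if (k_cur + 1L > best$k) return()   # cannot reach a cover of size <= best
    per_elem <- vapply(unc, function(e) sum(cover_mat[, e]), integer(1))
    e <- unc[which.min(per_elem)]
    for (i in which(cover_mat[, e])) {
      if (i %in% chosen) next
      rec(c(chosen, i), union(covered, covers[[i]]))
    }
  }
  rec(integer(0), integer(0))
  if (best$k == k_lower) best$exact <- TRUE
  best[c("k", "paths", "exact")]
}

#' Brute-force extended-minimum-path-cover oracle
#'
#' Exhaustively enumerates all source-to-sink paths and all path subsets in
#' increasing size, returning a provably minimum feasible cover. A test
#' oracle for [solve_empc()]; refuses graphs with more than `max_nodes`
#' nodes.
#'
#' @param graph a `splice_graph`.
#' @param subpaths subpath evidence ([extract_subpaths()] result) or `NULL`.
#' @param max_nodes hard node-count limit (default 10).
#' @param max_subsets refuse after examining this many path subsets.
#' @return a `path_cover` (always `exact = TRUE`).
#' @export
enumerate_all_covers_bruteforce <- function(graph, subpaths = NULL,
                                            max_nodes = 10L,
                                            max_subsets = 2e5) {
  n <- nrow(graph$nodes)
  if (n > max_nodes) stop("graph too large for brute force (", n, " nodes)")
  if (graph$source == graph$sink) {
    return(structure(list(paths = list(graph$source), k = 1L, exact = TRUE,
                          dropped_subpaths = 0L), class = "path_cover"))
  }
  edges <- graph$edges
  runs <- if (is.null(subpaths)) list() else subpaths$runs
  adj <- matrix(FALSE, n, n)
  if (nrow(edges)) adj[edges] <- TRUE
  runs <- runs[vapply(runs, function(r)
    length(r) >= 3L && all(adj[cbind(r[-length(r)], r[-1L])]), logical(1))]
  allp <- .enumerate_st_paths(n, edges, graph$source, graph$sink, cap = 100000L)
  if (length(allp) == 0L) stop("sink unreachable from source")
  feasible <- function(sel) {
    ps <- allp[sel]
    nodes_cov <- sort(unique(unlist(ps)))
    if (!all(seq_len(n) %in% nodes_cov)) {
      # only nodes on some path need covering; all graph nodes are by
      # construction, so require full coverage
      return(FALSE)
    }
    if (nrow(edges)) {
      ecov <- unique(do.call(rbind, lapply(ps, function(p)
        cbind(p[-length(p)], p[-1L]))))
      if (!all(paste(edges[, 1L], edges[, 2L]) %in%
               paste(ecov[, 1L], ecov[, 2L]))) return(FALSE)
    }
    for (r in runs)
      if (!any(vapply(ps, .contains_run, logical(1), run = r))) return(FALSE)
    TRUE
  }
  n_checked <- 0L
  for (k in seq_len(length(allp))) {
    if (choose(length(allp), k) + n_checked > max_subsets)
      stop("brute force refuses: subset budget exceeded")
    cmb <- utils::combn(length(allp), k)
    n_checked <- n_checked + ncol(cmb)
    for (j in seq_len(ncol(cmb))) {
      if (feasible(cmb[, j])) {
        return(structure(list(paths = allp[cmb[, j]], k = k, exact = TRUE,
                              dropped_subpaths = 0L), class = "path_cover"))
      }
    }
  }
  stop("no feasible cover found")  # unreachable for pruned graphs
}

#' Assemble all circular transcripts of one gene locus
#'
#' Runs [solve_empc()] on every splice graph of the locus and converts the
#' resulting paths to transcript records. Transcript ids follow the pattern
#' `circ<gene>-<bsj ordinal>-<isoform ordinal>`.
#'
#' @param graphs list of `splice_graph` objects for the locus, in reporting
#'   order (sorted by BSJ coordinates).
#' @param subpath_families list parallel to `graphs` of
#'   [extract_subpaths()] results (or `NULL`s).
#' @return list of transcript records; each holds `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `bsj_start`, `bsj_end`, `support`,
#'   `chain` (exon interval matrix), `length`, `path` (node indices),
#'   `graph_idx`.
#' @export
assemble_locus <- function(graphs, subpath_families = NULL) {
  out <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (is.null(g)) next
    sp <- if (is.null(subpath_families)) NULL else subpath_families[[gi]]
    sol <- solve_empc(g, sp)
    for (pi in seq_along(sol$paths)) {
      p <- sol$paths[[pi]]
      chain <- g$nodes[p, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        transcript_id = sprintf("circ%s-%d-%d", g$gene_id, gi, pi),
        gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        bsj_start = g$bsj_start, bsj_end = g$bsj_end, support = g$support,
        chain = chain, length = sum(chain[, 2L] - chain[, 1L]),
        path = p, graph_idx = gi)
    }
  }
  out
}
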