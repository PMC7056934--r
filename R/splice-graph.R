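#' Assign back-splice junctions to annotated gene loci
#'
#' A BSJ belongs to a locus when both of its coordinates coincide with
#' annotated exon boundaries of that locus (left boundary of the acceptor
#' exon, right boundary of the donor exon) on the same chromosome. A BSJ
#' matching exon boundaries in two overlapping genes is assigned to both.
#'
#' @param bsjs BSJ table ([read_bsj_list()]).
#' @param annotation a `gene_annotation`.
#' @param tolerance maximum absolute boundary mismatch in bp (default 0 =
#'   exact). When a match within tolerance is found, the BSJ coordinates
#'   are snapped to the annotated boundary.
#' @return list with `assigned` (data.table: `bsj_idx`, `gene_id`, snapped
#'   `start`/`end`) and `unassigned` (integer row indices into `bsjs`).
#' @export
assign_bsjs_to_loci <- function(bsjs, annotation, tolerance = 0L) {
  res <- list()
  hit_any <- rep(FALSE, nrow(bsjs))
  for (l in annotation$loci) {
    on_chr <- which(bsjs$chrom == l$chrom &
                    bsjs$start >= min(l$exons[, 1L]) - tolerance &
                    bsjs$end <= max(l$exons[, 2L]) + tolerance)
    if (length(on_chr) == 0L) next
    for (i in on_chr) {
      ds <- abs(l$exons[, 1L] - bsjs$start[i])
      de <- abs(l$exons[, 2L] - bsjs$end[i])
      if (min(ds) <= tolerance && min(de) <= tolerance) {
        res[[length(res) + 1L]] <- data.table(
          bsj_idx = i, gene_id = l$gene_id,
          start = l$exons[which.min(ds), 1L],
          end = l$exons[which.min(de), 2L])
        hit_any[i] <- TRUE
      }
    }
  }
  assigned <- if (length(res)) rbindlist(res) else
    data.table(bsj_idx = integer(), gene_id = character(),
               start = integer(), end = integer())
  multi <- assigned[, .N, by = bsj_idx][N > 1L]
  if (nrow(multi) > 0L)
    warning(nrow(multi), " BSJ(s) matched exon boundaries in more than one gene")
  list(assigned = assigned, unassigned = which(!hit_any))
}

#' Build the splice graph of one back-splice event
#'
#' Nodes are the annotated exon intervals of the locus lying entirely inside
#' the back-spliced span; exons only partially overlapping the span are
#' excluded. The exon starting at the BSJ left boundary is the source and
#' the exon ending at the right boundary is the sink. A directed edge (u,v)
#' is added when one alignment record spans the junction from exon u's
#' right boundary to exon v's left boundary (a CIGAR N gap); the circular
#' sink-to-source junction itself is never an edge. Nodes on no
#' source-to-sink path are dropped. Fragments are attached to the graph
#' when all their segments lie within the span (fragments in regions where
#' back-spliced circles overlap are thereby shared between graphs).
#'
#' @param locus one element of `gene_annotation$loci`.
#' @param bsj_start,bsj_end snapped BSJ coordinates (0-based half-open).
#' @param segments data.table of alignment blocks for the locus region
#'   (columns as in [read_alignments()]`$segments`).
#' @param support BSJ supporting-read count (carried through).
#' @return a `splice_graph` object, or `NULL` when no source/sink exon
#'   matches or the sink is unreachable (the BSJ is unassemblable). Fields:
#'   `nodes` (exon matrix in genomic order), `edges` (2-column matrix of
#'   node indices), `source`, `sink`, `frag_ids`, `n_inconsistent`.
#' @export
build_splice_graph <- function(locus, bsj_start, bsj_end, segments,
                               support = 0L) {
  ex <- locus$exons
  inside <- ex[, 1L] >= bsj_start & ex[, 2L] <= bsj_end
  nodes <- ex[inside, , drop = FALSE]
  if (nrow(nodes) == 0L) return(NULL)
  src_cand <- which(nodes[, 1L] == bsj_start)
  snk_cand <- which(nodes[, 2L] == bsj_end)
  if (length(src_cand) == 0L || length(snk_cand) == 0L) return(NULL)

  seg <- segments[segments$start >= bsj_start & segments$end <= bsj_end, ]
  # fragments wholly inside the span
  all_in <- setdiff(unique(segments$frag_id), unique(segments$frag_id[
    segments$start < bsj_start | segments$end > bsj_end]))
  seg <- seg[seg$frag_id %in% all_in, ]

  edges <- matrix(integer(0), ncol = 2L)
  if (nrow(seg) > 0L) {
    setorder(seg, frag_id, mate, record, start)
    ns <- nrow(seg)
    same <- if (ns > 1L)
      seg$frag_id[-1L] == seg$frag_id[-ns] & seg$mate[-1L] == seg$mate[-ns] &
      seg$record[-1L] == seg$record[-ns] else logical(0)
    if (any(same)) {
      ee <- unique(data.table(don = seg$end[-ns][same],
                              acc = seg$start[-1L][same]))
      el <- list()
      for (j in seq_len(nrow(ee))) {
        us <- which(nodes[, 2L] == ee$don[j])
        vs <- which(nodes[, 1L] == ee$acc[j])
        if (length(us) && length(vs)) {
          cmb <- expand.grid(u = us, v = vs)
          cmb <- cmb[cmb$u < cmb$v, , drop = FALSE]
          if (nrow(cmb)) el[[length(el) + 1L]] <- as.matrix(cmb)
        }
      }
      if (length(el)) edges <- unique(do.call(rbind, el))
    }
  }

  pick <- function(cand) {
    if (length(cand) == 1L) return(cand)
    deg <- vapply(cand, function(n) sum(edges == n), integer(1))
    len <- nodes[cand, 2L] - nodes[cand, 1L]
    cand[order(-deg, -len)][1L]
  }
  src <- pick(src_cand); snk <- pick(snk_cand)

  if (src == snk) {
    g <- list(gene_id = locus$gene_id, chrom = locus$chrom,
              strand = locus$strand, bsj_start = bsj_start,
              bsj_end = bsj_end, support = support,
              nodes = nodes[src, , drop = FALSE], source = 1L, sink = 1L,
              edges = matrix(integer(0), ncol = 2L),
              frag_ids = all_in, n_inconsistent = 0L)
    class(g) <- "splice_graph"
    return(g)
  }
  # single-exon fallback: an exon spanning the whole BSJ
  whole <- which(nodes[, 1L] == bsj_start & nodes[, 2L] == bsj_end)

  keep <- .on_st_path(nrow(nodes), edges, src, snk)
  if (!keep[snk] || !keep[src]) {
    if (length(whole)) {
      return(build_splice_graph(
        list(gene_id = locus$gene_id, chrom = locus$chrom,
             strand = locus$strand,
             exons = nodes[whole[1L], , drop = FALSE]),
        bsj_start, bsj_end, segments, support))
    }
    return(NULL)
  }
  remap <- cumsum(keep)
  nodes2 <- nodes[keep, , drop = FALSE]
  edges2 <- edges[keep[edges[, 1L]] & keep[edges[, 2L]], , drop = FALSE]
  if (nrow(edges2)) edges2 <- cbind(remap[edges2[, 1L]], remap[edges2[, 2L]])
  g <- list(gene_id = locus$gene_id, chrom = locus$chrom,
            strand = locus$strand, bsj_start = bsj_start, bsj_end = bsj_end,
            support = support, nodes = nodes2, source = remap[src],
            sink = remap[snk], edges = edges2, frag_ids = all_in,
            n_inconsistent = 0L)
  class(g) <- "splice_graph"
  g
}

# nodes lying on at least one source->sink walk
.on_st_path <- function(n, edges, src, snk) {
  fwd <- rep(FALSE, n); fwd[src] <- TRUE
  bwd <- rep(FALSE, n); bwd[snk] <- TRUE
  if (nrow(edges)) {
    repeat {
      new <- fwd[edges[, 1L]] & !fwd[edges[, 2L]]
      if (!any(new)) break
      fwd[edges[new, 2L]] <- TRUE
    }
    repeat {
      new <- bwd[edges[, 2L]] & !bwd[edges[, 1L]]
      if (!any(new)) break
      bwd[edges[new, 1L]] <- TRUE
    }
  }
  fwd & bwd
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph %s %s:%d-%d(%s): %d nodes, %d edges, %d fragments\n",
              x$gene_id, x$chrom, x$bsj_start, x$bsj_end, x$strand,
              nrow(x$nodes), nrow(x$edges), length(x$frag_ids)))
  invisible(x)
}

#' Extract subpath evidence from fragments on a splice graph
#'
#' For every fragment attached to the graph, the set of nodes touched by
#' its combined mate segments is computed. A fragment whose touched nodes
#' form one edge-connected run of three or more nodes contributes that run
#' as subpath evidence (a run that must appear contiguously in some
#' assembled isoform). BSJ-spanning fragments wrap across the circular
#' junction, so their touched nodes are split into maximal edge-connected
#' runs and each run of length >= 3 is emitted. Non-spanning fragments
#' whose touched nodes do not form a single connected run are counted as
#' inconsistent evidence. Identical runs are merged with multiplicity.
#'
#' @param graph a `splice_graph`.
#' @param segments locus alignment blocks (same table passed to
#'   [build_splice_graph()]).
#' @param frag_info data.table with `frag_id` and `bsj_spanning` columns
#'   ([read_alignments()]`$frags`).
#' @return list with `runs` (list of integer node-index vectors),
#'   `multiplicity` (integer vector) and `n_inconsistent`.
#' @export
extract_subpaths <- function(graph, segments, frag_info) {
  out <- list(runs = list(), multiplicity = integer(0), n_inconsistent = 0L)
  if (is.null(graph) || length(graph$frag_ids) == 0L || nrow(graph$nodes) < 3L)
    return(out)
  seg <- segments[segments$frag_id %in% graph$frag_ids, ]
  nodes <- graph$nodes
  n <- nrow(nodes)
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$edges)) adj[graph$edges] <- TRUE
  spanning <- frag_info$frag_id[frag_info$bsj_spanning]

  # touched = >=1 bp overlap between any segment and the node interval.
  # Non-spanning fragments join both mates into one candidate run; fragments
  # wrapping the BSJ are split at the junction by taking each alignment
  # record separately (a record never crosses the circular junction).
  m <- outer(seg$start, nodes[, 2L], "<") & outer(seg$end, nodes[, 1L], ">")
  is_span_row <- seg$frag_id %in% spanning
  grp <- ifelse(is_span_row,
                paste0("s", seg$frag_id, ".", seg$mate, ".", seg$record),
                paste0("f", seg$frag_id))
  tm <- rowsum(m * 1L, grp) > 0L
  joined_frag <- startsWith(rownames(tm), "f")

  runs_acc <- new.env(parent = emptyenv())
  n_inc <- 0L
  for (i in seq_len(nrow(tm))) {
    tn <- which(tm[i, ])
    if (length(tn) < 3L) next
    ok <- adj[cbind(tn[-length(tn)], tn[-1L])]
    pieces <- split(tn, cumsum(c(TRUE, !ok)))
    if (length(pieces) > 1L) {
      if (joined_frag[i]) n_inc <- n_inc + 1L
      next
    }
    for (p in pieces) {
      if (length(p) >= 3L) {
        key <- paste(p, collapse = ",")
        runs_acc[[key]] <- (if (is.null(runs_acc[[key]])) 0L else runs_acc[[key]]) + 1L
      }
    }
  }
  keys <- ls(runs_acc)
  out$runs <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1L]]))
  out$multiplicity <- vapply(keys, function(k) runs_acc[[k]], integer(1),
                             USE.NAMES = FALSE)
  out$n_inconsistent <- n_inc
  out
}
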