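# in-code fixtures shared across test files

# write a small GTF; exons = list(transcript_id -> matrix of 1-based
# (start, end) rows), one gene
write_tiny_gtf <- function(path, gene_id = "GENE1", chrom = "chr1",
                           strand = "+", exons) {
  lines <- unlist(lapply(names(exons), function(tx) {
    e <- exons[[tx]]
    sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            chrom, e[, 1L], e[, 2L], strand, gene_id, tx)
  }))
  writeLines(lines, path)
  path
}

# write a SAM file from a record data.frame (qname, flag, rname, pos, cigar)
write_tiny_sam <- function(path, records, chroms = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  body <- sprintf("%s\t%d\t%s\t%d\t50\t%s\t=\t1\t0\t*\t*",
                  records$qname, records$flag, records$rname, records$pos,
                  records$cigar)
  writeLines(c(hdr, body), path)
  path
}

# minimal splice_graph for solver tests: n nodes (spaced intervals),
# edges as 2-column matrix of node indices
make_graph <- function(n, edges, src = 1L, snk = n) {
  starts <- (seq_len(n) - 1L) * 200L
  g <- list(gene_id = "T", chrom = "chr1", strand = "+",
            bsj_start = starts[1L], bsj_end = starts[n] + 100L, support = 0L,
            nodes = cbind(start = starts, end = starts + 100L),
            source = src, sink = snk,
            edges = if (is.null(edges)) matrix(integer(0), ncol = 2L) else
              matrix(as.integer(edges), ncol = 2L),
            frag_ids = integer(0), n_inconsistent = 0L)
  class(g) <- "splice_graph"
  g
}

subpaths_of <- function(...) {
  runs <- list(...)
  list(runs = runs, multiplicity = rep(1L, length(runs)), n_inconsistent = 0L)
}

# random solvable DAG instance for property tests: nodes pruned to
# source->sink paths, subpaths sampled as random walks
random_dag_instance <- function(seed, n_max = 8L, p_edge = 0.35,
                                n_subpaths = 2L) {
  set.seed(seed)
  n <- sample(4:n_max, 1L)
  edges <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(edges)) < p_edge
  edges <- edges[keep, , drop = FALSE]
  # ensure a backbone path so sink is reachable
  bb <- cbind(seq_len(n - 1L), 2:n)
  take <- runif(n - 1L) < 0.6
  edges <- unique(rbind(edges, bb[take, , drop = FALSE]))
  g <- make_graph(n, edges)
  keepn <- circflow:::.on_st_path(n, g$edges, g$source, g$sink)
  if (sum(keepn) < 2L) return(NULL)
  remap <- cumsum(keepn)
  e2 <- g$edges[keepn[g$edges[, 1L]] & keepn[g$edges[, 2L]], , drop = FALSE]
  e2 <- cbind(remap[e2[, 1L]], remap[e2[, 2L]])
  g <- make_graph(sum(keepn), e2, src = remap[g$source], snk = remap[g$sink])
  # subpaths: random walks of length 3-4
  runs <- list()
  if (nrow(g$edges)) {
    nxt <- split(g$edges[, 2L], g$edges[, 1L])
    for (i in seq_len(n_subpaths)) {
      v <- sample(nrow(g$nodes), 1L)
      run <- v
      for (step in 1:3) {
        ch <- nxt[[as.character(run[length(run)])]]
        if (is.null(ch)) break
        run <- c(run, ch[sample.int(length(ch), 1L)])
      }
      if (length(run) >= 3L) runs[[length(runs) + 1L]] <- run
    }
  }
  list(graph = g,
       subpaths = if (length(runs))
         list(runs = runs, multiplicity = rep(1L, length(runs)),
              n_inconsistent = 0L) else NULL)
}

# literal check of EMPC conditions (a)-(d)
check_empc_conditions <- function(graph, subpaths, solution) {
  paths <- solution$paths
  ok_ends <- all(vapply(paths, function(p)
    p[1L] == graph$source && p[length(p)] == graph$sink, logical(1)))
  nodes_cov <- all(seq_len(nrow(graph$nodes)) %in% unlist(paths))
  edges_cov <- TRUE
  if (nrow(graph$edges)) {
    pe <- unique(do.call(rbind, lapply(paths, function(p)
      if (length(p) > 1L) cbind(p[-length(p)], p[-1L]) else NULL)))
    edges_cov <- all(paste(graph$edges[, 1L], graph$edges[, 2L]) %in%
                     paste(pe[, 1L], pe[, 2L]))
  }
  sp_cov <- TRUE
  if (!is.null(subpaths)) {
    for (r in subpaths$runs) {
      if (!any(vapply(paths, circflow:::.contains_run, logical(1), run = r)))
        sp_cov <- FALSE
    }
  }
  ok_ends && nodes_cov && edges_cov && sp_cov
}

# transcript record for quantifier tests; chain = 0-based (start,end) matrix
make_tx <- function(chain, strand = "+", id = "tx1", gene = "G1",
                    chrom = "chr1") {
  chain <- matrix(as.integer(chain), ncol = 2L)
  list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
       bsj_start = chain[1L, 1L], bsj_end = chain[nrow(chain), 2L],
       support = 0L, chain = chain,
       length = sum(chain[, 2L] - chain[, 1L]), path = seq_len(nrow(chain)),
       graph_idx = 1L)
}

# fragment as segment table; each row (mate, record, start, end)
make_frag <- function(...) {
  rows <- list(...)
  data.table::data.table(
    frag_id = 1L,
    mate = vapply(rows, `[[`, numeric(1), 1L),
    record = vapply(rows, `[[`, numeric(1), 2L),
    chrom = "chr1",
    start = vapply(rows, `[[`, numeric(1), 3L),
    end = vapply(rows, `[[`, numeric(1), 4L))
}
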