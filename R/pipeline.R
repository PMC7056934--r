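#' Assemble and quantify circular RNA isoforms
#'
#' End-to-end pipeline: read inputs, filter BSJs by support, assign BSJs to
#' annotated loci, build one splice graph per back-splice event, extract
#' subpath evidence, solve the extended minimum path cover, estimate
#' isoform abundances by EM, apply the per-mille abundance filter, compute
#' FPKM/TPM/read counts and the relation index, and optionally write the
#' output GTF and expression table.
#'
#' @param annotation GTF path or a `gene_annotation`.
#' @param alignments SAM path or a `fragment_alignments`.
#' @param bsjs BSJ-list path or a BSJ data.table.
#' @param dialect BSJ dialect when `bsjs` is a path (see [read_bsj_list()]).
#' @param min_support minimum BSJ supporting-read count (default 10).
#' @param tolerance exon-boundary matching tolerance in bp (default 0).
#' @param fragment_mean,fragment_sd fragment-length model override; when
#'   `NA` (default) the model is estimated from fragments of
#'   single-isoform loci (fallback: mean 250, sd 25).
#' @param quant a [quant_config()].
#' @param out_prefix when non-`NULL`, outputs are written via
#'   [write_outputs()].
#' @param verbose print per-stage progress.
#' @return object of class `circ_result`: list with
#'   \describe{
#'     \item{transcripts}{data.table of expression records (one row per
#'       assembled isoform, with `RI` column).}
#'     \item{unassembled}{data.table of BSJs for which no transcript could
#'       be assembled, with a `reason` column.}
#'     \item{stats}{per-stage counts.}
#'     \item{flm}{the fragment-length model used.}
#'   }
#' @export
run_assemble_quantify <- function(annotation, alignments, bsjs,
                                  dialect = "circexplorer2",
                                  min_support = 10L, tolerance = 0L,
                                  fragment_mean = NA, fragment_sd = NA,
                                  quant = quant_config(),
                                  out_prefix = NULL, verbose = FALSE) {
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (is.character(bsjs)) bsjs <- read_bsj_list(bsjs, dialect)
  bsjs <- as.data.table(bsjs)
  stats <- list(bsjs_in = nrow(bsjs))
  bsjs <- filter_bsj_by_support(bsjs, min_support)
  bsjs <- resolve_bsj_strand(bsjs, annotation)
  stats$bsjs_after_support <- nrow(bsjs)
  .msg(verbose, stats$bsjs_in, " BSJs read, ", nrow(bsjs),
       " after support filter (>=", min_support, ")")

  asg <- assign_bsjs_to_loci(bsjs, annotation, tolerance)
  stats$bsjs_assigned <- length(unique(asg$assigned$bsj_idx))
  stats$bsjs_unassigned <- length(asg$unassigned)
  .msg(verbose, stats$bsjs_assigned, " BSJs assigned to loci, ",
       stats$bsjs_unassigned, " unmatched")

  seg <- alignments$segments
  frag_info <- alignments$frags
  # fragments per locus: any segment overlapping the locus span
  loci_used <- unique(asg$assigned$gene_id)
  seg_by_locus <- list()
  if (nrow(seg) > 0L && length(loci_used) > 0L) {
    idx <- annotation$index[annotation$index$gene_id %in% loci_used, ]
    segGR <- GenomicRanges::GRanges(seg$chrom,
      IRanges::IRanges(seg$start + 1L, seg$end))
    locGR <- GenomicRanges::GRanges(idx$chrom,
      IRanges::IRanges(idx$span_start + 1L, idx$span_end))
    ov <- GenomicRanges::findOverlaps(segGR, locGR)
    hits <- data.table(row = S4Vectors::queryHits(ov),
                       locus = idx$gene_id[S4Vectors::subjectHits(ov)])
    hits[, frag_id := seg$frag_id[row]]
    fl <- unique(hits[, list(frag_id, locus)])
    setkey(seg, frag_id)
    seg_by_locus <- lapply(split(fl$frag_id, fl$locus), function(ids)
      seg[list(unique(ids))])
  }

  transcripts <- list()
  unassembled <- list()
  graphs_by_locus <- list()
  for (g in loci_used) {
    locus <- annotation$loci[[g]]
    a <- asg$assigned[asg$assigned$gene_id == g, ]
    a <- a[order(a$start, a$end), ]
    lseg <- seg_by_locus[[g]]
    if (is.null(lseg)) lseg <- seg[0L]
    graphs <- list(); families <- list()
    for (bi in seq_len(nrow(a))) {
      gr <- build_splice_graph(locus, a$start[bi], a$end[bi], lseg,
                               support = bsjs$support[a$bsj_idx[bi]])
      if (is.null(gr)) {
        unassembled[[length(unassembled) + 1L]] <- data.table(
          gene_id = g, chrom = locus$chrom, bsj_start = a$start[bi],
          bsj_end = a$end[bi], reason = "no source/sink exon or sink unreachable")
        graphs[bi] <- list(NULL)
        families[bi] <- list(NULL)
        next
      }
      graphs[[bi]] <- gr
      families[[bi]] <- extract_subpaths(gr, lseg, frag_info)
    }
    txs <- assemble_locus(graphs, families)
    if (length(txs)) {
      transcripts <- c(transcripts, txs)
      graphs_by_locus[[g]] <- graphs
    }
  }
  stats$bsjs_unassembled <- length(unassembled)
  stats$transcripts_assembled <- length(transcripts)
  .msg(verbose, length(transcripts), " transcripts assembled; ",
       length(unassembled), " BSJs unassemblable")

  # fragment-length model
  flm <- if (!is.na(fragment_mean) && !is.na(fragment_sd))
    fragment_length_model(fragment_mean, fragment_sd)
  else fit_fragment_length(transcripts, alignments, quant)
  .msg(verbose, sprintf("fragment length model: mean %.1f sd %.1f",
                        flm$mean, flm$sd))

  # EM per locus, then per-mille filter and a final EM pass on survivors
  kept <- list()
  em_stats <- list(n_excluded = 0L)
  for (g in unique(vapply(transcripts, `[[`, character(1), "gene_id"))) {
    txs <- transcripts[vapply(transcripts, function(t)
      t$gene_id == g, logical(1))]
    lseg <- seg_by_locus[[g]]
    fid_keep <- unique(unlist(lapply(graphs_by_locus[[g]], function(x)
      if (!is.null(x)) x$frag_ids)))
    lseg <- lseg[lseg$frag_id %in% fid_keep, ]
    if (is.null(lseg) || nrow(lseg) == 0L) {
      for (i in seq_along(txs)) {
        txs[[i]]$theta <- 1 / length(txs)
        txs[[i]]$expected_count <- 0
      }
      kept <- c(kept, txs)
      next
    }
    cd <- .compat_density(txs, lseg, flm, quant)
    fit <- .em_run(cd$G, cd$l, quant)
    em_stats$n_excluded <- em_stats$n_excluded + fit$n_excluded
    for (i in seq_along(txs)) {
      txs[[i]]$theta <- fit$theta[i]
      txs[[i]]$expected_count <- fit$expected_count[i]
    }
    surv <- filter_low_abundance(txs, quant)
    if (length(surv) < length(txs)) {
      keep_id <- vapply(surv, `[[`, character(1), "transcript_id")
      sel <- vapply(txs, function(t) t$transcript_id %in% keep_id, logical(1))
      refit <- .em_run(cd$G[, sel, drop = FALSE], cd$l[sel],
                       quant_config(quant$k_effective, quant$filter_ratio,
                                    max_em_iters = 1L,
                                    loglik_tol = quant$loglik_tol),
                       w_init = fit$w[sel])
      txs <- txs[sel]
      for (i in seq_along(txs)) {
        txs[[i]]$theta <- refit$theta[i]
        txs[[i]]$expected_count <- refit$expected_count[i]
      }
    }
    kept <- c(kept, txs)
  }
  stats$transcripts_reported <- length(kept)
  stats$fragments_total <- alignments$n_fragments
  stats$fragments_unexplained <- em_stats$n_excluded

  total <- max(alignments$n_fragments, 1L)
  expr <- compute_expression_metrics(kept, total)

  # relation index over the analyzed BSJ set
  ri <- compute_relation_index(bsjs)
  bkey <- paste(bsjs$chrom, bsjs$start, bsjs$end)
  # match transcripts to (possibly snapped) BSJ coordinates
  snap <- asg$assigned
  skey <- paste(snap$gene_id, snap$start, snap$end)
  tx_bkey <- paste(expr$chrom, expr$bsj_start, expr$bsj_end)
  snap_orig <- bkey[snap$bsj_idx]
  names(snap_orig) <- paste(snap$gene_id, snap$start, snap$end)
  expr$RI <- ri[match(snap_orig[paste(expr$gene_id, expr$bsj_start,
                                      expr$bsj_end)], bkey)]

  res <- structure(list(
    transcripts = expr,
    unassembled = if (length(unassembled)) rbindlist(unassembled) else
      data.table(gene_id = character(), chrom = character(),
                 bsj_start = integer(), bsj_end = integer(),
                 reason = character()),
    stats = stats, flm = flm, quant = quant), class = "circ_result")
  if (!is.null(out_prefix)) write_outputs(res$transcripts, out_prefix)
  res
}

#' @export
print.circ_result <- function(x, ...) {
  cat("circ_result:", nrow(x$transcripts), "circular transcripts from",
      length(unique(paste(x$transcripts$chrom, x$transcripts$bsj_start,
                          x$transcripts$bsj_end))), "back-splice junctions\n")
  cat(sprintf("  fragment length model: mean %.1f, sd %.1f\n",
              x$flm$mean, x$flm$sd))
  cat("  unassembled BSJs:", nrow(x$unassembled), "\n")
  invisible(x)
}

#' @export
summary.circ_result <- function(object, ...) {
  tx <- object$transcripts
  iso_per_bsj <- if (nrow(tx)) table(table(paste(tx$chrom, tx$bsj_start,
                                                 tx$bsj_end))) else table(integer(0))
  out <- list(n_transcripts = nrow(tx),
              n_bsjs = length(unique(paste(tx$chrom, tx$bsj_start, tx$bsj_end))),
              isoforms_per_bsj = iso_per_bsj,
              stats = object$stats)
  class(out) <- "summary.circ_result"
  out
}

#' @export
print.summary.circ_result <- function(x, ...) {
  cat("circular transcripts:", x$n_transcripts, "from", x$n_bsjs, "BSJs\n")
  cat("isoform-count distribution per BSJ:\n")
  print(x$isoforms_per_bsj)
  cat("pipeline stages:\n")
  for (n in names(x$stats)) cat(sprintf("  %-24s %s\n", n, x$stats[[n]]))
  invisible(x)
}

#' Evaluate predictions against a simulated truth
#'
#' @param truth_path truth TSV written by [run_simulate()].
#' @param predictions_path expression TSV written by [write_outputs()], or
#'   a `circ_result`.
#' @return list with the `assembly` score, `quantification` correlations
#'   (absolute mode; `NULL` if fewer than 3 matched pairs) and the
#'   RI-stratified table when RI values are present.
#' @export
run_evaluate <- function(truth_path, predictions_path) {
  truth <- fread(truth_path, sep = "\t")
  pred <- if (inherits(predictions_path, "circ_result"))
    predictions_path$transcripts else fread(predictions_path, sep = "\t")
  assembly <- score_assembly(truth, pred)
  quantification <- tryCatch(score_quantification(truth, pred),
                             error = function(e) NULL)
  ri_tab <- NULL
  if ("RI" %in% names(pred) && nrow(pred)) {
    ri_map <- unique(as.data.table(pred)[, list(chrom, bsj_start, bsj_end, RI)])
    ri_tab <- stratify_by_ri(truth, pred, ri_map)
  }
  list(assembly = assembly, quantification = quantification,
       ri_stratified = ri_tab)
}
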