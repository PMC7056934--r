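#' Score assembled transcripts against a simulated truth
#'
#' A predicted transcript is a true positive when its full exon chain
#' exactly matches a truth transcript of the same back-splice junction
#' (same chromosome and BSJ coordinates). Sensitivity = TP/(TP+FN) over
#' truth transcripts, precision = TP/(TP+FP) over predictions, F1 their
#' harmonic mean. Truth transcripts are those with at least one emitted
#' fragment (`frag_count_true >= 1`) unless `all_truth = TRUE`.
#'
#' @param truth truth table from [simulate_truth()]/[simulate_reads()]
#'   (columns `chrom`, `bsj_start`, `bsj_end`, `exon_chain`,
#'   `frag_count_true`).
#' @param predicted data.frame of predictions with `chrom`, `bsj_start`,
#'   `bsj_end`, `exon_chain` (0-based half-open, `start-end,start-end`).
#' @param all_truth count truth transcripts without emitted fragments too.
#' @return list of class `assembly_score`: `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `f1`, plus the matched key tables.
#' @export
score_assembly <- function(truth, predicted, all_truth = FALSE) {
  truth <- as.data.table(truth)
  if (!all_truth && "frag_count_true" %in% names(truth))
    truth <- truth[truth$frag_count_true >= 1L, ]
  tkey <- truth[, paste(chrom, bsj_start, bsj_end, exon_chain)]
  pkey <- if (is.null(predicted) || nrow(predicted) == 0L) character(0) else
    as.data.table(predicted)[, paste(chrom, bsj_start, bsj_end, exon_chain)]
  tp <- sum(pkey %in% tkey)
  fp <- length(pkey) - tp
  fn <- length(tkey) - sum(tkey %in% pkey)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = sens,
                 precision = prec, f1 = f1, truth_keys = tkey,
                 predicted_keys = pkey), class = "assembly_score")
}

#' @export
print.assembly_score <- function(x, ...) {
  cat(sprintf("assembly_score: TP=%d FP=%d FN=%d  sens=%.4f prec=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$f1))
  invisible(x)
}

#' Correlation between true and estimated abundances
#'
#' Pearson and Spearman correlations over matched (truth, estimate) pairs.
#' In `absolute` mode fragment counts are compared across all matched
#' transcripts. In `relative-per-locus` mode the comparison is restricted
#' to loci with two or more matched isoforms and uses within-locus
#' abundance proportions.
#'
#' @param truth truth table (needs `frag_count_true`, `theta_true`,
#'   `gene_id`).
#' @param predicted expression records (needs `read_count`, `theta`,
#'   `gene_id`, and matching keys as in [score_assembly()]).
#' @param mode `"absolute"` or `"relative-per-locus"`.
#' @return list with `pcc`, `scc`, `n` (matched pairs) and the matched
#'   table.
#' @export
score_quantification <- function(truth, predicted,
                                 mode = c("absolute", "relative-per-locus")) {
  mode <- match.arg(mode)
  truth <- as.data.table(truth)
  predicted <- as.data.table(predicted)
  tt <- truth[, list(key = paste(chrom, bsj_start, bsj_end, exon_chain),
                     gene_id, frag_count_true,
                     theta_true = if ("theta_true" %in% names(truth))
                       theta_true else NA_real_)]
  pp <- predicted[, list(key = paste(chrom, bsj_start, bsj_end, exon_chain),
                         read_count,
                         theta = if ("theta" %in% names(predicted))
                           theta else NA_real_)]
  m <- merge(tt, pp, by = "key")
  if (nrow(m) < 3L) stop("fewer than 3 matched transcript pairs")
  if (mode == "absolute") {
    x <- m$frag_count_true; y <- m$read_count
  } else {
    m <- m[, n_iso := .N, by = "gene_id"][n_iso >= 2L]
    if (nrow(m) < 3L) stop("fewer than 3 matched pairs in multi-isoform loci")
    m[, p_t := frag_count_true / sum(frag_count_true), by = "gene_id"]
    m[, p_p := read_count / sum(read_count), by = "gene_id"]
    x <- m$p_t; y <- m$p_p
  }
  list(pcc = cor(x, y, method = "pearson"),
       scc = cor(x, y, method = "spearman"),
       n = nrow(m), matched = m)
}

#' Stratify assembly scores by relation index
#'
#' Recomputes sensitivity/precision/F1 within RI bins 1, 2, 3, 4 and >4.
#' Both truth and predicted transcripts are binned by the RI of their BSJ.
#'
#' @param truth,predicted as in [score_assembly()].
#' @param ri_map data.frame mapping BSJs to RI: columns `chrom`,
#'   `bsj_start`, `bsj_end`, `RI`.
#' @param all_truth see [score_assembly()].
#' @return data.table with one row per non-empty bin: `ri_bin`, `tp`,
#'   `fp`, `fn`, `sensitivity`, `precision`, `f1`.
#' @export
stratify_by_ri <- function(truth, predicted, ri_map, all_truth = FALSE) {
  ri_map <- as.data.table(ri_map)
  ri_map[, bkey := paste(chrom, bsj_start, bsj_end)]
  binof <- function(ri) ifelse(ri > 4L, ">4", as.character(ri))
  truth <- as.data.table(truth)
  predicted <- as.data.table(predicted)
  truth[, bkey := paste(chrom, bsj_start, bsj_end)]
  predicted[, bkey := paste(chrom, bsj_start, bsj_end)]
  truth[, ri_bin := binof(ri_map$RI[match(bkey, ri_map$bkey)])]
  predicted[, ri_bin := binof(ri_map$RI[match(bkey, ri_map$bkey)])]
  bins <- intersect(c("1", "2", "3", "4", ">4"),
                    union(truth$ri_bin, predicted$ri_bin))
  out <- lapply(bins, function(b) {
    sc <- score_assembly(truth[ri_bin == b], predicted[ri_bin == b],
                         all_truth = all_truth)
    data.table(ri_bin = b, tp = sc$tp, fp = sc$fp, fn = sc$fn,
               sensitivity = sc$sensitivity, precision = sc$precision,
               f1 = sc$f1)
  })
  rbindlist(out)
}

#' Per-isoform correlation of relative abundance across conditions
#'
#' For a series of runs of the same simulated loci under different
#' expression conditions, computes for every truth isoform the Pearson
#' correlation between its true and estimated within-locus abundance
#' proportions across the conditions. Isoforms never assembled get a zero
#' estimate in every condition where they are missing.
#'
#' @param truths list of truth tables (one per condition).
#' @param predictions list of expression-record tables (parallel).
#' @return data.table with `transcript_id` (truth id), `n_conditions`,
#'   `pcc`.
#' @export
relative_abundance_series <- function(truths, predictions) {
  stopifnot(length(truths) == length(predictions), length(truths) >= 3L)
  per_cond <- lapply(seq_along(truths), function(i) {
    tt <- as.data.table(truths[[i]])
    pp <- as.data.table(predictions[[i]])
    tt[, key := paste(chrom, bsj_start, bsj_end, exon_chain)]
    pp[, key := paste(chrom, bsj_start, bsj_end, exon_chain)]
    est <- pp$theta[match(tt$key, pp$key)]
    est[is.na(est)] <- 0
    data.table(transcript_id = tt$transcript_id, cond = i,
               truth = tt$theta_true, est = est)
  })
  long <- rbindlist(per_cond)
  long[, list(n_conditions = .N,
              pcc = if (stats::sd(truth) > 0 && stats::sd(est) > 0)
                cor(truth, est) else NA_real_),
       by = transcript_id]
}
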