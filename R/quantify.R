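#' Quantification configuration
#'
#' @param k_effective effective-mapping threshold in bp: a read end
#'   overlapping an exon by fewer than `k_effective` bases is ignored when
#'   testing fragment-transcript compatibility, and the per-fragment
#'   selection probability of a transcript of length `l` is
#'   `1/(l - 2*k_effective + 2)`. Default 3.
#' @param filter_ratio low-abundance filter: within a locus, isoforms with
#'   relative abundance below `filter_ratio` times the most abundant
#'   isoform are discarded. Default 0.001 (1 per mille).
#' @param max_em_iters,loglik_tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below `loglik_tol` (default 1e-6) or after
#'   `max_em_iters` iterations (default 1000).
#' @return list of class `quant_config`.
#' @export
quant_config <- function(k_effective = 3L, filter_ratio = 0.001,
                         max_em_iters = 1000L, loglik_tol = 1e-6) {
  stopifnot(k_effective >= 1L, filter_ratio >= 0, filter_ratio < 1)
  structure(list(k_effective = as.integer(k_effective),
                 filter_ratio = filter_ratio,
                 max_em_iters = as.integer(max_em_iters),
                 loglik_tol = loglik_tol), class = "quant_config")
}

#' Normal fragment-length model
#'
#' @param mean,sd fragment length mean and standard deviation in bp.
#' @return list of class `fragment_length_model`.
#' @export
fragment_length_model <- function(mean, sd) {
  stopifnot(sd > 0)
  structure(list(mean = mean, sd = sd), class = "fragment_length_model")
}

# ---- fragment-to-transcript mapping ---------------------------------------

# Map one alignment record (>=1 genomic blocks, ascending) onto the
# transcript; returns c(off_start, off_end) in the genomic-ascending
# linearization of the chain, or NULL if incompatible.
# trim: 2-vector, whether the (left, right) outer ends are read termini
# subject to the k_effective trim.
.map_record <- function(starts, ends, chain, cum, k, trim = c(TRUE, TRUE)) {
  m <- length(starts)
  if (trim[1L] && m > 1L && (ends[1L] - starts[1L]) < k) {
    starts <- starts[-1L]; ends <- ends[-1L]; m <- m - 1L
  }
  if (trim[2L] && m > 1L && (ends[m] - starts[m]) < k) {
    starts <- starts[-m]; ends <- ends[-m]; m <- m - 1L
  }
  idx <- integer(m)
  for (i in seq_len(m)) {
    j <- which(chain[, 1L] <= starts[i] & ends[i] <= chain[, 2L])
    if (length(j) == 0L) return(NULL)
    idx[i] <- j[1L]
  }
  if (m > 1L) {
    if (any(diff(idx) != 1L)) return(NULL)
    if (any(ends[-m] != chain[idx[-m], 2L])) return(NULL)
    if (any(starts[-1L] != chain[idx[-1L], 1L])) return(NULL)
  }
  c(cum[idx[1L]] + (starts[1L] - chain[idx[1L], 1L]),
    cum[idx[m]] + (ends[m] - chain[idx[m], 1L]))
}

# Per-transcript model: chain ascending, cumulative offsets, length, strand
.tx_model <- function(transcript) {
  chain <- transcript$chain
  lens <- chain[, 2L] - chain[, 1L]
  list(chain = chain, cum = cumsum(c(0L, lens))[seq_len(nrow(chain))],
       l = sum(lens), strand = transcript$strand)
}

# Map one fragment (its segment rows: $mate, $record, $start, $end as
# parallel vectors) onto a transcript model.
# Returns implied length lt, or NA if incompatible.
.map_fragment <- function(seg, tx, k) {
  l <- tx$l
  flip <- identical(tx$strand, "-")
  v_mate <- seg$mate; v_rec <- seg$record
  v_start <- seg$start; v_end <- seg$end
  mates <- list()
  for (mt in unique(v_mate)) {
    in_mate <- v_mate == mt
    recs <- unique(v_rec[in_mate])
    ivs <- vector("list", length(recs))
    for (ri in seq_along(recs)) {
      rows <- in_mate & v_rec == recs[ri]
      r <- .map_record(v_start[rows], v_end[rows], tx$chain, tx$cum, k,
                       trim = if (length(recs) == 1L) c(TRUE, TRUE)
                              else c(FALSE, FALSE))
      if (is.null(r)) return(NA_real_)
      if (flip) r <- c(l - r[2L], l - r[1L])
      ivs[[ri]] <- r
    }
    if (length(ivs) == 1L) {
      mates[[as.character(mt)]] <- ivs[[1L]]
    } else if (length(ivs) == 2L) {
      # a BSJ-split mate must be {[a, l), [0, b)} in transcript orientation
      a <- ivs[[which(vapply(ivs, function(x) x[2L] == l, logical(1)))[1L]]]
      b <- ivs[[which(vapply(ivs, function(x) x[1L] == 0, logical(1)))[1L]]]
      if (is.null(a) || is.null(b) || length(a) == 0L || length(b) == 0L)
        return(NA_real_)
      mates[[as.character(mt)]] <- c(a[1L], l + b[2L])
    } else {
      return(NA_real_)  # more than one wrap is not representable
    }
  }
  if (length(mates) == 0L) return(NA_real_)
  m1 <- mates[["1"]]; m2 <- mates[["2"]]
  if (is.null(m1)) m1 <- m2
  if (is.null(m2)) m2 <- m1
  s1 <- m1[1L]
  s2 <- m2[1L]; e2 <- m2[2L]
  if (s2 < s1) { s2 <- s2 + l; e2 <- e2 + l }  # mate2 upstream: wraps the BSJ
  lt <- e2 - s1
  if (lt <= 0) lt <- lt + l
  lt
}

#' Test whether a fragment is compatible with a circular transcript
#'
#' A fragment is compatible when every aligned segment lies inside the
#' transcript's exon chain and every splice implied by a CIGAR gap joins
#' two consecutive exons of the chain, allowing the mate pair (or a split
#' mate) to wrap across the back-splice junction. Read ends overlapping an
#' exon by fewer than `k_effective` bp are ignored.
#'
#' @param fragment data.table of the fragment's segment rows (columns
#'   `mate`, `record`, `start`, `end`; see [read_alignments()]).
#' @param transcript a transcript record ([assemble_locus()]).
#' @param k_effective effective-mapping threshold (bp).
#' @return logical.
#' @export
fragment_compatibility <- function(fragment, transcript, k_effective = 3L) {
  !is.na(.map_fragment(fragment, .tx_model(transcript), k_effective))
}

#' Implied length of a fragment on a circular transcript
#'
#' The distance from mate1's 5'-most transcript coordinate to mate2's
#' 3'-most transcript coordinate along the circle. When the footprints
#' imply that the fragment runs past the back-splice junction (a split
#' mate, or mate2 upstream of mate1 on the linearized circle), one full
#' transcript length is added.
#'
#' @inheritParams fragment_compatibility
#' @return implied length in bp, or `NA` if the fragment is incompatible.
#' @export
implied_fragment_length <- function(fragment, transcript, k_effective = 3L) {
  .map_fragment(fragment, .tx_model(transcript), k_effective)
}

# ---- EM -------------------------------------------------------------------

# density matrix G[f, t] = F(lt(f)) / (l(t) - 2k + 2), 0 when incompatible
.compat_density <- function(transcripts, segments, flm, cfg) {
  txm <- lapply(transcripts, .tx_model)
  l <- vapply(txm, function(x) x$l, numeric(1))
  ord <- order(segments$frag_id)
  v_fid <- segments$frag_id[ord]
  v_mate <- segments$mate[ord]; v_rec <- segments$record[ord]
  v_start <- segments$start[ord]; v_end <- segments$end[ord]
  seg_idx <- split(seq_along(v_fid), v_fid)
  fids <- as.integer(names(seg_idx))
  frag_segs <- lapply(seg_idx, function(i)
    list(mate = v_mate[i], record = v_rec[i],
         start = v_start[i], end = v_end[i]))
  G <- matrix(0, nrow = length(fids), ncol = length(transcripts))
  LT <- matrix(NA_real_, nrow = length(fids), ncol = length(transcripts))
  for (ti in seq_along(txm)) {
    tx <- txm[[ti]]
    denom <- max(l[ti] - 2 * cfg$k_effective + 2, 1)
    for (fi in seq_along(fids)) {
      lt <- .map_fragment(frag_segs[[fi]], tx, cfg$k_effective)
      if (!is.na(lt)) {
        LT[fi, ti] <- lt
        G[fi, ti] <- max(dnorm(lt, flm$mean, flm$sd), 1e-12) / denom
      }
    }
  }
  rownames(G) <- as.character(fids)
  list(G = G, LT = LT, l = l, frag_ids = fids)
}

# EM in mixture-weight space: w_t = (theta_t/l_t)/sum(theta/l).
# Returns w, theta, expected counts, log-likelihood trace.
.em_run <- function(G, l, cfg, w_init = NULL) {
  n <- nrow(G); Tn <- ncol(G)
  keep <- rowSums(G) > 0
  G <- G[keep, , drop = FALSE]
  N <- nrow(G)
  if (N == 0L || Tn == 0L)
    return(list(w = rep(1 / max(Tn, 1), Tn), theta = rep(1 / max(Tn, 1), Tn),
                expected_count = rep(0, Tn), loglik = -Inf, trace = numeric(0),
                converged = TRUE, n_used = 0L, n_excluded = n))
  w <- if (is.null(w_init)) rep(1 / Tn, Tn) else w_init / sum(w_init)
  trace <- numeric(0)
  converged <- FALSE
  gamma <- NULL
  for (it in seq_len(cfg$max_em_iters)) {
    P <- sweep(G, 2L, w, "*")
    rs <- rowSums(P)
    ll <- sum(log(rs))
    gamma <- P / rs
    w_new <- colSums(gamma) / N
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) <=
          cfg$loglik_tol * (abs(trace[it - 1L]) + 1e-12)) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  theta <- w * l
  theta <- theta / sum(theta)
  list(w = w, theta = theta, expected_count = colSums(gamma),
       loglik = trace[length(trace)], trace = trace, converged = converged,
       n_used = N, n_excluded = n - N)
}

#' Estimate isoform abundances by EM on the circular-transcript likelihood
#'
#' Maximizes the likelihood in which a fragment f is drawn from transcript
#' t with probability proportional to `theta_t/l(t)` (normalized over the
#' transcript set) times `F[lt(f)]/(l(t) - 2k + 2)`, where `F` is a normal
#' fragment-length density, `lt(f)` the implied (wrap-aware) fragment
#' length and `k` the effective-mapping threshold. The log-likelihood is
#' concave, so EM from a uniform start attains the global maximum.
#'
#' @param transcripts list of transcript records of one locus
#'   ([assemble_locus()]).
#' @param fragments a `fragment_alignments` object, or a data.table of
#'   segment rows restricted to the locus.
#' @param flm a [fragment_length_model()].
#' @param cfg a [quant_config()].
#' @return the transcript list with `theta` and `expected_count` filled in;
#'   attributes `loglik`, `loglik_trace`, `converged`, `n_used`,
#'   `n_excluded`.
#' @export
em_estimate <- function(transcripts, fragments, flm, cfg = quant_config()) {
  segments <- if (inherits(fragments, "fragment_alignments"))
    fragments$segments else fragments
  cd <- .compat_density(transcripts, segments, flm, cfg)
  if (all(cd$G == 0))
    stop("no fragment is compatible with any transcript")
  fit <- .em_run(cd$G, cd$l, cfg)
  if (!fit$converged)
    warning("EM did not converge within ", cfg$max_em_iters, " iterations")
  for (i in seq_along(transcripts)) {
    transcripts[[i]]$theta <- fit$theta[i]
    transcripts[[i]]$expected_count <- fit$expected_count[i]
  }
  attr(transcripts, "loglik") <- fit$loglik
  attr(transcripts, "loglik_trace") <- fit$trace
  attr(transcripts, "converged") <- fit$converged
  attr(transcripts, "n_used") <- fit$n_used
  attr(transcripts, "n_excluded") <- fit$n_excluded
  transcripts
}

#' Drop isoforms below the per-mille abundance filter
#'
#' Within each gene locus, transcripts whose relative abundance is below
#' `filter_ratio` times the most abundant isoform of the locus are
#' discarded; the remaining abundances are re-normalized.
#'
#' @param transcripts list of transcript records with `theta` set.
#' @param cfg a [quant_config()].
#' @return filtered transcript list (thetas re-normalized per locus).
#' @export
filter_low_abundance <- function(transcripts, cfg = quant_config()) {
  if (length(transcripts) == 0L) return(transcripts)
  gene <- vapply(transcripts, function(t) t$gene_id, character(1))
  theta <- vapply(transcripts, function(t) t$theta, numeric(1))
  keep <- rep(TRUE, length(transcripts))
  for (g in unique(gene)) {
    i <- which(gene == g)
    keep[i] <- theta[i] >= cfg$filter_ratio * max(theta[i])
  }
  out <- transcripts[keep]
  gene <- gene[keep]; theta <- theta[keep]
  for (g in unique(gene)) {
    i <- which(gene == g)
    s <- sum(theta[i])
    for (j in i) out[[j]]$theta <- theta[j] / s
  }
  out
}

#' Compute FPKM and TPM from expected fragment counts
#'
#' Uses the raw transcript length (no effective-length correction: a
#' circle has no ends, hence no edge effects).
#'
#' @param transcripts list of transcript records with `expected_count`.
#' @param total_mapped_fragments library size for FPKM.
#' @return data.table of expression records.
#' @export
compute_expression_metrics <- function(transcripts, total_mapped_fragments) {
  stopifnot(total_mapped_fragments > 0)
  if (length(transcripts) == 0L)
    return(data.table(transcript_id = character(), gene_id = character(),
                      chrom = character(), bsj_start = integer(),
                      bsj_end = integer(), strand = character(),
                      exon_chain = character(), length = integer(),
                      theta = numeric(), read_count = numeric(),
                      FPKM = numeric(), TPM = numeric()))
  cnt <- vapply(transcripts, function(t) t$expected_count, numeric(1))
  len <- vapply(transcripts, function(t) t$length, numeric(1))
  fpkm <- cnt / (len / 1e3) / (total_mapped_fragments / 1e6)
  rate <- cnt / len
  tpm <- 1e6 * rate / sum(rate)
  data.table(
    transcript_id = vapply(transcripts, `[[`, character(1), "transcript_id"),
    gene_id = vapply(transcripts, `[[`, character(1), "gene_id"),
    chrom = vapply(transcripts, `[[`, character(1), "chrom"),
    bsj_start = vapply(transcripts, function(t) as.integer(t$bsj_start), integer(1)),
    bsj_end = vapply(transcripts, function(t) as.integer(t$bsj_end), integer(1)),
    strand = vapply(transcripts, `[[`, character(1), "strand"),
    exon_chain = vapply(transcripts, function(t)
      .chain_key(t$chain[, 1L], t$chain[, 2L]), character(1)),
    length = as.integer(len),
    theta = vapply(transcripts, function(t) t$theta, numeric(1)),
    read_count = cnt, FPKM = fpkm, TPM = tpm)
}

#' Estimate the fragment-length model from single-isoform loci
#'
#' Collects implied fragment lengths over transcripts that are the only
#' isoform of their locus (where the length is unambiguous) and fits a
#' normal model by moments. Falls back to the supplied defaults when fewer
#' than `min_fragments` lengths are available.
#'
#' @param transcripts list of transcript records.
#' @param fragments a `fragment_alignments` object.
#' @param cfg a [quant_config()].
#' @param fallback [fragment_length_model()] used when data are sparse.
#' @param min_fragments minimum usable lengths (default 50).
#' @return a [fragment_length_model()].
#' @export
fit_fragment_length <- function(transcripts, fragments, cfg = quant_config(),
                                fallback = fragment_length_model(250, 25),
                                min_fragments = 50L) {
  gene <- vapply(transcripts, function(t) t$gene_id, character(1))
  singles <- transcripts[gene %in% names(which(table(gene) == 1L))]
  if (length(singles) == 0L) return(fallback)
  seg <- fragments$segments
  lens <- numeric(0)
  for (tx in singles) {
    txm <- .tx_model(tx)
    s <- seg[seg$chrom == tx$chrom & seg$start >= tx$bsj_start &
             seg$end <= tx$bsj_end, ]
    if (nrow(s) == 0L) next
    ok_ids <- setdiff(unique(s$frag_id),
                      unique(seg$frag_id[seg$chrom != tx$chrom |
                                         seg$start < tx$bsj_start |
                                         seg$end > tx$bsj_end]))
    for (fid in ok_ids) {
      lt <- .map_fragment(s[s$frag_id == fid, ], txm, cfg$k_effective)
      if (!is.na(lt)) lens <- c(lens, lt)
      if (length(lens) >= 5000L) break
    }
    if (length(lens) >= 5000L) break
  }
  if (length(lens) < min_fragments) return(fallback)
  fragment_length_model(mean(lens), max(stats::sd(lens), 1))
}
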