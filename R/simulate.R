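#' Simulation configuration
#'
#' Defines the synthetic study conditions: gene models with uniformly drawn
#' exon/intron sizes, one or more back-splice events per locus (optionally
#' with overlapping spans), circular isoforms generated by random skipping
#' of the exons between the back-splice sites, log-uniform expression
#' levels, and paired-end fragments with normal lengths sampled uniformly
#' around the circle (any rotation, including across the back-splice
#' junction).
#'
#' @param n_loci number of gene loci.
#' @param exons_per_locus integer range (min, max) of exons per locus.
#' @param exon_length bp range of exon lengths.
#' @param intron_length bp range of intron lengths.
#' @param n_bsjs_per_locus integer range of back-splice events per locus.
#' @param overlap_fraction fraction of loci whose back-splice events are
#'   constructed with mutually overlapping genomic spans (such loci always
#'   receive at least two BSJs); the remaining loci place any extra BSJs
#'   disjointly.
#' @param span_exon_weights sampling weights for the number of exons inside
#'   a back-spliced span (1..length(weights) exons); the default favours
#'   2-4 exon circles.
#' @param isoforms_per_bsj integer range of isoforms per back-splice event
#'   (capped by the number of distinct skip patterns).
#' @param read_length read length in bp.
#' @param n_read_pairs total fragments to draw; `NA` (default) means
#'   `depth_per_transcript * number of transcripts`.
#' @param depth_per_transcript expected fragments per transcript when
#'   `n_read_pairs` is `NA`.
#' @param fragment_mean,fragment_sd normal fragment-length parameters (bp);
#'   lengths are truncated below at `read_length`.
#' @param expression_range range of the log-uniform expression levels
#'   (arbitrary units) assigned to isoforms.
#' @param error_rate uniform substitution rate applied to FASTQ bases only
#'   (alignment coordinates are unaffected).
#' @param seed integer seed; the same configuration always reproduces the
#'   same dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 50L,
                       exons_per_locus = c(4L, 12L),
                       exon_length = c(60L, 300L),
                       intron_length = c(200L, 2000L),
                       n_bsjs_per_locus = c(1L, 2L),
                       overlap_fraction = 0.3,
                       span_exon_weights = c(0.08, 0.22, 0.28, 0.22, 0.12, 0.08),
                       isoforms_per_bsj = c(1L, 2L),
                       read_length = 100L,
                       n_read_pairs = NA_integer_,
                       depth_per_transcript = 250,
                       fragment_mean = 250,
                       fragment_sd = 25,
                       expression_range = c(1, 1000),
                       error_rate = 0,
                       seed = 1L) {
  stopifnot(read_length <= fragment_mean, fragment_sd > 0, n_loci >= 1L,
            overlap_fraction >= 0, overlap_fraction <= 1,
            expression_range[1L] > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate gene models, back-splice events and truth isoforms
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth`:
#'   \describe{
#'     \item{annotation}{a `gene_annotation` (as from
#'       [read_gene_annotation()]) containing each locus's full exon set
#'       and its cognate linear transcript.}
#'     \item{bsjs}{data.table of simulated BSJs (`chrom`, `start`, `end`,
#'       `strand`; `support` filled by [simulate_reads()]).}
#'     \item{truth}{data.table of truth transcripts: `transcript_id`,
#'       `gene_id`, `chrom`, `strand`, `bsj_start`, `bsj_end`,
#'       `exon_chain`, `length`, `level`, `theta_true`;
#'       `frag_count_true` filled by [simulate_reads()].}
#'     \item{transcripts}{internal transcript records (exon chain matrices)
#'       used by the read generator.}
#'   }
#' @export
simulate_truth <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", 1:4)
  cursor <- setNames(rep(1000L, length(chroms)), chroms)
  loci <- list()
  bsj_rows <- list()
  tx_list <- list()
  runif_int <- function(n, r) if (r[1L] >= r[2L]) rep(r[1L], n) else
    sample(seq(r[1L], r[2L]), n, replace = TRUE)

  for (li in seq_len(cfg$n_loci)) {
    gid <- sprintf("G%04d", li)
    chrom <- chroms[(li - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- runif_int(1L, cfg$exons_per_locus)
    ex_len <- runif_int(n_ex, cfg$exon_length)
    in_len <- runif_int(n_ex, cfg$intron_length)
    starts <- cursor[chrom] + cumsum(c(0L, (ex_len + in_len)[-n_ex]))
    ends <- starts + ex_len
    cursor[chrom] <- ends[n_ex] + 10000L
    exons <- cbind(start = as.integer(starts), end = as.integer(ends))

    # back-splice events: (source exon, sink exon) index pairs
    overlapping <- runif(1L) < cfg$overlap_fraction
    nb <- if (overlapping)
      runif_int(1L, c(max(2L, cfg$n_bsjs_per_locus[1L]),
                      max(2L, cfg$n_bsjs_per_locus[2L])))
    else runif_int(1L, cfg$n_bsjs_per_locus)
    w <- cfg$span_exon_weights[seq_len(min(length(cfg$span_exon_weights), n_ex))]
    draw_span <- function(lo = 1L, hi = n_ex) {
      # sample span size then position within [lo, hi]
      for (try in 1:50) {
        m <- sample.int(length(w), 1L, prob = w)
        if (m > hi - lo + 1L) next
        a <- if (hi - m + 1L >= lo) sample(seq(lo, hi - m + 1L), 1L) else lo
        return(c(a, a + m - 1L))
      }
      c(lo, lo)
    }
    pairs <- list()
    if (overlapping) {
      first <- draw_span()
      pairs[[1L]] <- first
      for (j in seq_len(nb - 1L)) {
        for (try in 1:50) {
          cand <- draw_span()
          olap <- any(vapply(pairs, function(p)
            cand[1L] <= p[2L] && cand[2L] >= p[1L], logical(1)))
          dup <- any(vapply(pairs, function(p) all(p == cand), logical(1)))
          if (olap && !dup) { pairs[[length(pairs) + 1L]] <- cand; break }
        }
      }
    } else {
      lo <- 1L
      for (j in seq_len(nb)) {
        if (lo > n_ex) break
        cand <- draw_span(lo, n_ex)
        pairs[[length(pairs) + 1L]] <- cand
        lo <- cand[2L] + 1L
      }
    }
    pairs <- unique(pairs)
    ord <- order(vapply(pairs, `[`, integer(1), 1L),
                 vapply(pairs, `[`, integer(1), 2L))
    pairs <- pairs[ord]

    loci[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                        exons = exons,
                        transcripts = list(linear = seq_len(n_ex)))
    for (bi in seq_along(pairs)) {
      a <- pairs[[bi]][1L]; b <- pairs[[bi]][2L]
      bsj_rows[[length(bsj_rows) + 1L]] <- data.table(
        gene_id = gid, chrom = chrom, strand = strand,
        start = exons[a, 1L], end = exons[b, 2L], support = 0L)
      m_int <- max(0L, b - a - 1L)
      n_iso <- min(runif_int(1L, cfg$isoforms_per_bsj), 2L^m_int)
      chains <- list(seq(a, b))                # first isoform keeps all exons
      tries <- 0L
      while (length(chains) < n_iso && tries < 200L) {
        tries <- tries + 1L
        keep <- runif(m_int) < 0.5
        cand <- c(a, seq(a + 1L, length.out = m_int)[keep], b)
        cand <- unique(sort(cand))
        if (!any(vapply(chains, function(x) identical(x, cand), logical(1))))
          chains[[length(chains) + 1L]] <- cand
      }
      for (ci in seq_along(chains)) {
        chain <- exons[chains[[ci]], , drop = FALSE]
        tx_list[[length(tx_list) + 1L]] <- list(
          transcript_id = sprintf("circ%s-%d-%d", gid, bi, ci),
          gene_id = gid, chrom = chrom, strand = strand,
          bsj_start = exons[a, 1L], bsj_end = exons[b, 2L],
          bsj_ordinal = bi, chain = chain,
          length = sum(chain[, 2L] - chain[, 1L]))
      }
    }
  }

  levels <- 10^runif(length(tx_list), log10(cfg$expression_range[1L]),
                     log10(cfg$expression_range[2L]))
  truth <- rbindlist(lapply(seq_along(tx_list), function(i) {
    t <- tx_list[[i]]
    data.table(transcript_id = t$transcript_id, gene_id = t$gene_id,
               chrom = t$chrom, strand = t$strand,
               bsj_start = t$bsj_start, bsj_end = t$bsj_end,
               exon_chain = .chain_key(t$chain[, 1L], t$chain[, 2L]),
               length = t$length, level = levels[i])
  }))
  truth[, theta_true := level * length / sum(level * length), by = gene_id]
  truth[, frag_count_true := NA_integer_]
  for (i in seq_along(tx_list)) tx_list[[i]]$level <- levels[i]

  index <- rbindlist(lapply(loci, function(l) data.table(
    gene_id = l$gene_id, chrom = l$chrom, strand = l$strand,
    span_start = min(l$exons[, 1L]), span_end = max(l$exons[, 2L]))))
  annotation <- structure(list(loci = loci, index = index),
                          class = "gene_annotation")
  structure(list(annotation = annotation, bsjs = rbindlist(bsj_rows),
                 truth = truth, transcripts = tx_list, cfg = cfg),
            class = "sim_truth")
}

#' Redraw expression levels for an existing simulated truth
#'
#' Keeps the gene models, back-splice events and isoform structures of a
#' `sim_truth` but assigns fresh log-uniform expression levels — one
#' "condition" in a multi-condition design. Pass a distinct `seed` (also
#' used, offset by one, by the subsequent [simulate_reads()] call if you
#' store it in the returned object's `cfg`).
#'
#' @param sim a `sim_truth`.
#' @param seed integer seed for the new condition.
#' @return a `sim_truth` with new `level`/`theta_true` values and `cfg$seed`
#'   set to `seed`.
#' @export
reassign_expression <- function(sim, seed) {
  set.seed(seed)
  cfg <- sim$cfg
  levels <- 10^runif(length(sim$transcripts),
                     log10(cfg$expression_range[1L]),
                     log10(cfg$expression_range[2L]))
  for (i in seq_along(sim$transcripts)) sim$transcripts[[i]]$level <- levels[i]
  sim$truth$level <- levels
  sim$truth[, theta_true := level * length / sum(level * length),
            by = gene_id]
  sim$cfg$seed <- as.integer(seed)
  sim
}

# vectorized conversion of transcript-coordinate pieces [x1, x2) to SAM
# records (0-based pos, CIGAR); chain vectors are in transcription order
.piece_records <- function(chain, strand, x1, x2) {
  if (identical(strand, "-")) chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
  lens <- chain[, 2L] - chain[, 1L]
  cum <- cumsum(c(0L, lens))[seq_len(nrow(chain))]
  i1 <- findInterval(x1, cum)
  i2 <- findInterval(x2 - 1L, cum)
  nb <- i2 - i1 + 1L
  pos <- integer(length(x1))
  cigar <- character(length(x1))
  for (k in sort(unique(nb))) {
    sel <- which(nb == k)
    gs <- matrix(0L, length(sel), k)  # genomic block starts
    ge <- matrix(0L, length(sel), k)
    for (j in seq_len(k)) {
      idx <- i1[sel] + j - 1L
      xs <- pmax(cum[idx], x1[sel]); xe <- pmin(cum[idx] + lens[idx], x2[sel])
      if (identical(strand, "-")) {
        ge[, j] <- chain[idx, 2L] - (xs - cum[idx])
        gs[, j] <- chain[idx, 2L] - (xe - cum[idx])
      } else {
        gs[, j] <- chain[idx, 1L] + (xs - cum[idx])
        ge[, j] <- chain[idx, 1L] + (xe - cum[idx])
      }
    }
    if (identical(strand, "-") && k > 1L) {   # sort blocks genomically
      gs <- gs[, k:1, drop = FALSE]; ge <- ge[, k:1, drop = FALSE]
    }
    cig <- paste0(ge[, 1L] - gs[, 1L], "M")
    if (k > 1L) for (j in 2:k) {
      cig <- paste0(cig, gs[, j] - ge[, j - 1L], "N", ge[, j] - gs[, j], "M")
    }
    pos[sel] <- gs[, 1L]
    cigar[sel] <- cig
  }
  list(pos = pos, cigar = cigar, nblocks = nb)
}

#' Simulate paired-end fragments from the truth isoforms
#'
#' Fragment counts are multinomial with probability proportional to each
#' isoform's expression level; start positions are uniform on the circle,
#' so a fragment may begin at any rotation including across the back-splice
#' junction. Fragment lengths are normal, truncated below at the read
#' length. A mate crossing the junction is emitted as two primary SAM
#' records split at the junction (both carrying the mate's flag); forward
#' splices appear as N gaps in the CIGAR. Transcripts shorter than the read
#' length are skipped (a read would wrap more than once).
#'
#' @param sim a `sim_truth` from [simulate_truth()].
#' @param cfg the same [sim_config()].
#' @return list of class `sim_reads`: `sam` (data.table of SAM columns),
#'   `header` (character lines), `truth` (truth table with
#'   `frag_count_true` filled), `bsjs` (with realized junction-read
#'   `support`), `n_read_pairs`.
#' @export
simulate_reads <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 1L)
  txs <- sim$transcripts
  rl <- cfg$read_length
  viable <- vapply(txs, function(t) t$length >= rl, logical(1))
  levels <- vapply(txs, function(t) t$level, numeric(1)) * viable
  n_pairs <- if (is.na(cfg$n_read_pairs))
    as.integer(round(cfg$depth_per_transcript * length(txs)))
  else as.integer(cfg$n_read_pairs)
  counts <- if (n_pairs > 0L && sum(levels) > 0)
    as.integer(rmultinom(1L, n_pairs, levels)) else integer(length(txs))

  recs <- vector("list", length(txs))
  support_key <- paste(sim$bsjs$chrom, sim$bsjs$start, sim$bsjs$end)
  supp_vec <- setNames(rep(0L, nrow(sim$bsjs)), support_key)
  for (ti in seq_along(txs)) {
    ct <- counts[ti]
    if (ct == 0L) next
    t <- txs[[ti]]
    l <- t$length
    s <- sample.int(l, ct, replace = TRUE) - 1L
    flen <- round(rnorm(ct, cfg$fragment_mean, cfg$fragment_sd))
    for (r in 1:5) {
      short <- flen < rl
      if (!any(short)) break
      flen[short] <- round(rnorm(sum(short), cfg$fragment_mean, cfg$fragment_sd))
    }
    flen[flen < rl] <- rl
    flen <- as.integer(flen)
    m1s <- s %% l
    m2s <- as.integer((s + flen - rl) %% l)
    qn <- sprintf("f%d_%d", ti, seq_len(ct))
    mate_tab <- data.table(
      qname = rep(qn, 2L),
      mate = rep(c(1L, 2L), each = ct),
      ms = c(m1s, m2s))
    mate_tab[, split := ms + rl > l]
    # piece coordinates (transcript space)
    p1 <- mate_tab[, list(qname, mate, x1 = ms, x2 = pmin(ms + rl, l))]
    p2 <- mate_tab[split == TRUE,
                   list(qname, mate, x1 = 0L, x2 = as.integer(ms + rl - l))]
    pieces <- rbind(p1, p2)
    pr <- .piece_records(t$chain, t$strand, pieces$x1, pieces$x2)
    base1 <- 0x1L + 0x2L + 0x40L
    base2 <- 0x1L + 0x2L + 0x80L
    if (identical(t$strand, "-")) {
      f1 <- base1 + 0x10L; f2 <- base2 + 0x20L
    } else {
      f1 <- base1 + 0x20L; f2 <- base2 + 0x10L
    }
    recs[[ti]] <- data.table(
      qname = pieces$qname, flag = ifelse(pieces$mate == 1L, f1, f2),
      rname = t$chrom, pos = pr$pos + 1L, mapq = 50L, cigar = pr$cigar,
      rnext = "=", pnext = 1L, tlen = 0L, seq = "*", qual = "*",
      tx = ti, x1 = pieces$x1)
    n_span <- length(unique(mate_tab$qname[mate_tab$split]))
    key <- paste(t$chrom, t$bsj_start, t$bsj_end)
    supp_vec[key] <- supp_vec[key] + n_span
  }
  sam <- rbindlist(recs)
  if (nrow(sam)) setorder(sam, rname, pos, qname)
  truth <- data.table::copy(sim$truth)
  truth[, frag_count_true := counts[match(truth$transcript_id,
    vapply(txs, `[[`, character(1), "transcript_id"))]]
  bsjs <- data.table::copy(sim$bsjs)
  bsjs[, support := as.integer(supp_vec[paste(chrom, start, end)])]
  # header with sequence lines covering all coordinates
  chr_max <- sim$annotation$index[, list(mx = max(span_end) + 1000L),
                                  by = chrom]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chr_max$chrom, chr_max$mx))
  structure(list(sam = sam, header = header, truth = truth, bsjs = bsjs,
                 n_read_pairs = sum(counts)), class = "sim_reads")
}

#' Write a simulated dataset to disk
#'
#' Writes `annotation.gtf`, `reads.sam`, `bsj.tsv` (CIRCexplorer2-style,
#' 0-based half-open, support in column 5), `truth.tsv`, a JSON run
#' manifest and, when `write_fastq`, `reads_1.fastq`/`reads_2.fastq` with
#' random bases (optionally perturbed at `error_rate`).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param write_fastq emit FASTQ files (default `TRUE`).
#' @return invisibly, a list with the `sim_truth`, `sim_reads` and file
#'   paths.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir, write_fastq = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_truth(cfg)
  reads <- simulate_reads(sim, cfg)
  paths <- c(gtf = file.path(out_dir, "annotation.gtf"),
             sam = file.path(out_dir, "reads.sam"),
             bsj = file.path(out_dir, "bsj.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             manifest = file.path(out_dir, "manifest.json"))

  # annotation: exon features of the cognate linear transcript per locus
  ann_rows <- rbindlist(lapply(sim$annotation$loci, function(l) data.table(
    chrom = l$chrom, start = l$exons[, 1L] + 1L, end = l$exons[, 2L],
    strand = l$strand, gene_id = l$gene_id,
    transcript_id = paste0(l$gene_id, ".lin"))))
  gtf <- ann_rows[, sprintf(
    "%s\tcircflow_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    chrom, start, end, strand, gene_id, transcript_id)]
  writeLines(gtf, paths["gtf"])

  con <- file(paths["sam"], "w")
  writeLines(reads$header, con)
  close(con)
  if (nrow(reads$sam)) {
    fwrite(reads$sam[, 1:11], paths["sam"], sep = "\t", append = TRUE,
           col.names = FALSE)
  }
  bsj_out <- reads$bsjs[, list(chrom, start, end,
                               name = sprintf("circ/%d", .I),
                               support, strand)]
  fwrite(bsj_out, paths["bsj"], sep = "\t", col.names = FALSE)
  fwrite(reads$truth, paths["truth"], sep = "\t")
  jsonlite::write_json(list(seed = cfg$seed, n_loci = cfg$n_loci,
                            n_read_pairs = reads$n_read_pairs,
                            n_transcripts = nrow(reads$truth)),
                       paths["manifest"], auto_unbox = TRUE)
  if (write_fastq) {
    fq <- .write_fastq(reads, cfg, out_dir)
    paths <- c(paths, fq)
  }
  invisible(list(sim = sim, reads = reads, paths = paths))
}

.write_fastq <- function(reads, cfg, out_dir) {
  rl <- cfg$read_length
  qual <- strrep("I", rl)
  paths <- c(fq1 = file.path(out_dir, "reads_1.fastq"),
             fq2 = file.path(out_dir, "reads_2.fastq"))
  sam <- reads$sam
  for (mt in 1:2) {
    sub <- sam[bitwAnd(flag, if (mt == 1L) 0x40L else 0x80L) != 0L]
    qn <- unique(sub$qname)
    n <- length(qn)
    if (n == 0L) { writeLines(character(0), paths[mt]); next }
    bases <- matrix(sample(c("A", "C", "G", "T"), n * rl, replace = TRUE),
                    nrow = n)
    if (cfg$error_rate > 0) {
      err <- matrix(runif(n * rl) < cfg$error_rate, nrow = n)
      bases[err] <- sample(c("A", "C", "G", "T"), sum(err), replace = TRUE)
    }
    seqs <- apply(bases, 1L, paste0, collapse = "")
    out <- character(4L * n)
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", qn, "/", mt)
    out[seq(2L, by = 4L, length.out = n)] <- seqs
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- qual
    writeLines(out, paths[mt])
  }
  paths
}
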