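test_that("the simulator is deterministic given a seed", {
  cfg <- sim_config(n_loci = 5L, seed = 3L, depth_per_transcript = 50)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  run_simulate(cfg, d1, write_fastq = TRUE)
  run_simulate(cfg, d2, write_fastq = TRUE)
  for (f in c("annotation.gtf", "reads.sam", "bsj.tsv", "truth.tsv",
              "reads_1.fastq"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("isoform structure follows the configuration", {
  cfg <- sim_config(n_loci = 20L, isoforms_per_bsj = c(1L, 1L), seed = 5L)
  sim <- simulate_truth(cfg)
  per_bsj <- table(paste(sim$truth$chrom, sim$truth$bsj_start,
                         sim$truth$bsj_end))
  expect_true(all(per_bsj == 1L))
  # isoforms of one BSJ share source and sink exons and are distinct
  cfg2 <- sim_config(n_loci = 30L, isoforms_per_bsj = c(2L, 3L), seed = 6L)
  sim2 <- simulate_truth(cfg2)
  for (b in split(sim2$truth, paste(sim2$truth$chrom, sim2$truth$bsj_start,
                                    sim2$truth$bsj_end))) {
    chains <- strsplit(b$exon_chain, ",")
    expect_equal(length(unique(b$exon_chain)), nrow(b))
    firsts <- vapply(chains, head, character(1), n = 1L)
    lasts <- vapply(chains, tail, character(1), n = 1L)
    expect_equal(length(unique(firsts)), 1L)
    expect_equal(length(unique(lasts)), 1L)
  }
  # per-locus truth abundances are normalized
  th <- sim2$truth[, sum(theta_true), by = gene_id]$V1
  expect_equal(th, rep(1, length(th)), tolerance = 1e-12)
})

test_that("overlap_fraction controls loci with overlapping BSJs", {
  cfg <- sim_config(n_loci = 100L, overlap_fraction = 0.3, seed = 8L,
                    n_bsjs_per_locus = c(1L, 2L))
  sim <- simulate_truth(cfg)
  per_locus <- split(sim$bsjs, sim$bsjs$gene_id)
  n_overlap <- sum(vapply(per_locus, function(b) {
    if (nrow(b) < 2L) return(FALSE)
    any(outer(b$start, b$end, "<") & outer(b$end, b$start, ">") &
        !diag(nrow(b)))
  }, logical(1)))
  expect_gt(n_overlap, 15L)   # binomial(100, 0.3) within wide bounds
  expect_lt(n_overlap, 45L)
})

test_that("fragment lengths and counts follow the generative model", {
  cfg <- sim_config(n_loci = 2L, exons_per_locus = c(6L, 6L), seed = 13L,
                    isoforms_per_bsj = c(2L, 2L), n_read_pairs = 100000L)
  sim <- simulate_truth(cfg)
  reads <- simulate_reads(sim, cfg)
  expect_equal(reads$n_read_pairs, 100000L)
  # realized per-transcript shares converge to the level-proportional
  # sampling probabilities (law of large numbers, 3% tolerance)
  viable <- reads$truth$length >= cfg$read_length
  lv <- reads$truth$level * viable
  expect_lt(max(abs(reads$truth$frag_count_true / sum(reads$truth$frag_count_true)
                    - lv / sum(lv))), 0.03)
  # empirical fragment-length mean: map the emitted alignments of one long
  # transcript back onto it and recover the implied lengths
  len <- vapply(sim$transcripts, `[[`, numeric(1), "length")
  ti <- which.max((len >= 600) * reads$truth$frag_count_true)
  sub <- reads$sam[reads$sam$tx == ti]
  tmp <- tempfile(fileext = ".sam")
  writeLines(reads$header, tmp)
  data.table::fwrite(sub[, 1:11], tmp, sep = "\t", append = TRUE,
                     col.names = FALSE)
  al <- read_alignments(tmp)
  lts <- vapply(split(al$segments, al$segments$frag_id),
                implied_fragment_length, numeric(1),
                transcript = sim$transcripts[[ti]])
  lts <- lts[!is.na(lts)]
  expect_gt(length(lts), 0.95 * reads$truth$frag_count_true[ti])
  expect_lt(abs(mean(lts) - cfg$fragment_mean),
            2 * cfg$fragment_sd / sqrt(length(lts)) + 1)
})

test_that("SAM records have consistent CIGARs and BSJ-split alignments exist", {
  cfg <- sim_config(n_loci = 10L, seed = 21L, depth_per_transcript = 150)
  sim <- simulate_truth(cfg)
  reads <- simulate_reads(sim, cfg)
  sam <- reads$sam
  # split mates: same qname and mate flag appearing twice
  mate_flag <- bitwAnd(sam$flag, 0xC0L)
  dup <- duplicated(paste(sam$qname, mate_flag))
  expect_gt(sum(dup), 0L)
  expect_true(any(reads$bsjs$support > 0L))
  # every CIGAR consumes exactly read_length bases on the read for
  # unsplit mates (M/I/S consume read)
  read_len <- function(cig) {
    toks <- regmatches(cig, gregexpr("[0-9]+[MIDNS]", cig))[[1]]
    sum(as.integer(sub("[A-Z]", "", toks[grepl("[MIS]$", toks)])))
  }
  unsplit <- sam[!(paste(qname, bitwAnd(flag, 0xC0L)) %in%
                   paste(qname[dup], mate_flag[dup])), ]
  lens <- vapply(head(unsplit$cigar, 200L), read_len, numeric(1))
  expect_true(all(lens == cfg$read_length))
  # single-exon circles produce gapless records even when split at the BSJ
  one_ex <- which(!grepl(",", reads$truth$exon_chain) &
                  reads$truth$frag_count_true > 0L)
  if (length(one_ex)) {
    sub <- sam[sam$tx == one_ex[1L]]
    expect_gt(nrow(sub), 0L)
    expect_false(any(grepl("N", sub$cigar)))
  }
})

test_that("reassign_expression changes only the expression levels", {
  cfg <- sim_config(n_loci = 5L, seed = 31L)
  s1 <- simulate_truth(cfg)
  s2 <- reassign_expression(s1, 777L)
  expect_identical(s1$truth$exon_chain, s2$truth$exon_chain)
  expect_identical(s1$bsjs$start, s2$bsjs$start)
  expect_false(identical(s1$truth$level, s2$truth$level))
  expect_equal(s2$truth[, sum(theta_true), by = gene_id]$V1,
               rep(1, length(unique(s2$truth$gene_id))))
})
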