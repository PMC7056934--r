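# one locus: exons E1 (100,200), E2 (300,400), E3 (500,600), 0-based
.locus3 <- function(strand = "+") list(
  gene_id = "G1", chrom = "chr1", strand = strand,
  exons = cbind(start = c(100L, 300L, 500L), end = c(200L, 400L, 600L)),
  transcripts = list(lin = 1:3))

# segment rows for a spliced record covering given block pairs
.seg <- function(frag_id, mate, record, blocks) {
  data.table::data.table(frag_id = frag_id, mate = mate, record = record,
                         chrom = "chr1",
                         start = vapply(blocks, `[`, numeric(1), 1L),
                         end = vapply(blocks, `[`, numeric(1), 2L))
}

test_that("BSJs are assigned to loci by exact exon-boundary match", {
  gtf <- write_tiny_gtf(tempfile(fileext = ".gtf"), exons = list(
    t1 = cbind(c(101, 301, 501), c(200, 400, 600))))
  ann <- read_gene_annotation(gtf)
  bs <- data.table::data.table(chrom = "chr1",
                               start = c(100L, 100L), end = c(600L, 650L),
                               strand = "+", support = 10L)
  asg <- assign_bsjs_to_loci(bs, ann)
  expect_equal(asg$assigned$bsj_idx, 1L)
  expect_equal(asg$unassigned, 2L)
  # tolerance snaps near-miss boundaries
  bs2 <- data.table::data.table(chrom = "chr1", start = 99L, end = 601L,
                                strand = "+", support = 10L)
  asg2 <- assign_bsjs_to_loci(bs2, ann, tolerance = 2L)
  expect_equal(asg2$assigned$start, 100L)
  expect_equal(asg2$assigned$end, 600L)
})

test_that("a BSJ matching two overlapping genes is assigned to both", {
  path <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"gA\"; transcript_id \"a\";",
    "chr1\ttest\texon\t501\t600\t.\t+\t.\tgene_id \"gA\"; transcript_id \"a\";",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"gB\"; transcript_id \"b\";",
    "chr1\ttest\texon\t501\t600\t.\t+\t.\tgene_id \"gB\"; transcript_id \"b\";"),
    path)
  ann <- read_gene_annotation(path)
  bs <- data.table::data.table(chrom = "chr1", start = 100L, end = 600L,
                               strand = "+", support = 10L)
  expect_warning(asg <- assign_bsjs_to_loci(bs, ann), "more than one gene")
  expect_setequal(asg$assigned$gene_id, c("gA", "gB"))
})

test_that("splice graph nodes, edges and source/sink follow the evidence", {
  seg <- rbind(
    .seg(1L, 1L, 1L, list(c(150, 200), c(300, 350))),  # E1 -> E2
    .seg(1L, 2L, 1L, list(c(360, 400), c(500, 550))),  # E2 -> E3
    .seg(2L, 1L, 1L, list(c(310, 390))))               # inside E2: no edge
  g <- build_splice_graph(.locus3(), 100L, 600L, seg, support = 12L)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(g$source, 1L)
  expect_equal(g$sink, 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges[, 1L], g$edges[, 2L]), c("1 2", "2 3"))

  # exon-skipping evidence adds the E1 -> E3 edge
  seg2 <- rbind(seg, .seg(3L, 1L, 1L, list(c(150, 200), c(500, 550))))
  g2 <- build_splice_graph(.locus3(), 100L, 600L, seg2)
  expect_setequal(paste(g2$edges[, 1L], g2$edges[, 2L]),
                  c("1 2", "2 3", "1 3"))
})

test_that("unmatched boundaries or unreachable sinks are unassemblable", {
  # no exon starts at the BSJ left boundary
  expect_null(build_splice_graph(.locus3(), 110L, 600L, .seg(1L, 1L, 1L,
    list(c(150, 200)))))
  # no forward-spliced reads: middle exon unreachable, sink unreachable
  expect_null(build_splice_graph(.locus3(), 100L, 600L,
    .seg(1L, 1L, 1L, list(c(120, 180)))))
})

test_that("a single-exon circle yields a one-node graph", {
  locus <- list(gene_id = "G1", chrom = "chr1", strand = "+",
                exons = cbind(start = 100L, end = 600L),
                transcripts = list(lin = 1L))
  g <- build_splice_graph(locus, 100L, 600L,
                          .seg(1L, 1L, 1L, list(c(150, 250))))
  expect_equal(g$source, g$sink)
  expect_equal(nrow(g$nodes), 1L)
})

test_that("graph construction is deterministic", {
  seg <- rbind(.seg(1L, 1L, 1L, list(c(150, 200), c(300, 350))),
               .seg(2L, 1L, 1L, list(c(360, 400), c(500, 550))))
  g1 <- build_splice_graph(.locus3(), 100L, 600L, seg)
  g2 <- build_splice_graph(.locus3(), 100L, 600L, seg)
  expect_identical(g1, g2)
})

test_that("subpath evidence requires connected runs of three nodes", {
  seg <- rbind(
    .seg(1L, 1L, 1L, list(c(150, 200), c(300, 350))),
    .seg(1L, 2L, 1L, list(c(360, 400), c(500, 550))),
    .seg(2L, 1L, 1L, list(c(150, 200), c(300, 350))),
    .seg(2L, 2L, 1L, list(c(360, 400), c(500, 550))))
  fi <- data.table::data.table(frag_id = 1:2, qname = c("a", "b"),
                               bsj_spanning = FALSE, n_mates = 2L)
  g <- build_splice_graph(.locus3(), 100L, 600L, seg)
  sp <- extract_subpaths(g, seg, fi)
  expect_length(sp$runs, 1L)
  expect_equal(sp$runs[[1L]], 1:3)
  expect_equal(sp$multiplicity, 2L)   # duplicate runs merged
})

test_that("BSJ-spanning fragments are split at the junction", {
  # mate1 split: end of E3 then start of E1 continuing into E2
  seg <- rbind(
    .seg(1L, 1L, 1L, list(c(550, 600))),              # sink-side piece
    .seg(1L, 1L, 2L, list(c(100, 150))),              # source-side piece
    .seg(1L, 2L, 1L, list(c(150, 200), c(300, 350))), # E1 -> E2
    .seg(2L, 1L, 1L, list(c(150, 200), c(300, 350))),
    .seg(2L, 2L, 1L, list(c(360, 400), c(500, 550))))
  fi <- data.table::data.table(frag_id = 1:2, qname = c("a", "b"),
                               bsj_spanning = c(TRUE, FALSE), n_mates = 2L)
  g <- build_splice_graph(.locus3(), 100L, 600L, seg)
  sp <- extract_subpaths(g, seg, fi)
  # fragment 1 touches {3, 1, 2}: split at the junction -> runs (1,2), (3)
  # neither reaches length 3; only fragment 2 yields (1,2,3)
  expect_length(sp$runs, 1L)
  expect_equal(sp$runs[[1L]], 1:3)
  expect_equal(sp$n_inconsistent, 0L)
})
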