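#' Write assembled circular transcripts and their expression table
#'
#' Writes two files: `<out_prefix>.gtf` with one `exon` feature per
#' transcript exon (1-based GTF coordinates, `gene_id`/`transcript_id`
#' attributes plus `bsj` tag), and `<out_prefix>.expression.tsv` with
#' columns `transcript_id`, `gene_id`, `chrom`, `bsj_start`, `bsj_end`,
#' `strand`, `exon_chain`, `length`, `theta`, `read_count`, `FPKM`, `TPM`
#' (plus `RI` when present). Tabular coordinates and `exon_chain`
#' (`start-end,start-end`) are 0-based half-open, matching the internal
#' convention; the GTF is 1-based.
#'
#' @param records data.frame of expression records (see
#'   [run_assemble_quantify()]); may be empty.
#' @param out_prefix path prefix for the two output files.
#' @return invisibly, the paths of the written files.
#' @export
write_outputs <- function(records, out_prefix) {
  gtf_path <- paste0(out_prefix, ".gtf")
  tsv_path <- paste0(out_prefix, ".expression.tsv")
  cols <- c("transcript_id", "gene_id", "chrom", "bsj_start", "bsj_end",
            "strand", "exon_chain", "length", "theta", "read_count",
            "FPKM", "TPM")
  if (!is.null(records) && "RI" %in% names(records)) cols <- c(cols, "RI")
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(character(0), gtf_path)
    fwrite(setNames(data.table(matrix(nrow = 0L, ncol = length(cols))), cols),
           tsv_path, sep = "\t")
    return(invisible(c(gtf = gtf_path, tsv = tsv_path)))
  }
  records <- as.data.table(records)
  fwrite(records[, cols, with = FALSE], tsv_path, sep = "\t")

  chains <- .parse_chains(records$exon_chain)
  nex <- vapply(chains, nrow, integer(1))
  ex <- do.call(rbind, chains)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(records$chrom, nex),
    ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
    strand = rep(ifelse(records$strand %in% c("+", "-"), records$strand, "*"), nex))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "circflow", type = "exon",
    gene_id = rep(records$gene_id, nex),
    transcript_id = rep(records$transcript_id, nex),
    bsj = rep(sprintf("%s:%d-%d", records$chrom, records$bsj_start,
                      records$bsj_end), nex))
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(c(gtf = gtf_path, tsv = tsv_path))
}

# "100-200,300-400" -> integer matrix (0-based half-open)
.parse_chains <- function(chain_strings) {
  lapply(strsplit(chain_strings, ",", fixed = TRUE), function(p) {
    m <- do.call(rbind, strsplit(p, "-", fixed = TRUE))
    cbind(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
  })
}

#' Re-read an assembled-transcript GTF written by [write_outputs()]
#'
#' @param path GTF path.
#' @return data.table with `transcript_id`, `gene_id`, `chrom`, `strand` and
#'   the 0-based half-open `exon_chain` string, sorted by transcript.
#' @export
read_transcript_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(!startsWith(lines, "#") & nzchar(lines)))
    return(data.table(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      exon_chain = character()))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id))
  setorder(dt, transcript_id, start, end)
  dt[, list(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
            exon_chain = .chain_key(start, end)), by = transcript_id]
}
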