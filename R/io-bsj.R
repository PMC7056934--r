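#' Read a back-splice-junction list
#'
#' Normalizes the tabular outputs of three upstream circRNA detectors to a
#' common internal record. A back-splice junction (BSJ) is the junction
#' joining a downstream 5' splice donor to an upstream 3' splice acceptor;
#' internally it is stored as the 0-based half-open genomic interval
#' `[start, end)` covering the whole back-spliced span, i.e. `start` is the
#' left boundary of the acceptor exon and `end` the right boundary of the
#' donor exon.
#'
#' Supported dialects (coordinate conventions converted on read):
#' \describe{
#'   \item{circexplorer2}{BED-like, 0-based half-open; columns 1-6 =
#'     chrom, start, end, name, readNumber (support), strand.}
#'   \item{ciri2}{1-based inclusive; columns circRNA_ID, chr,
#'     circRNA_start, circRNA_end, junction_reads (support), ... strand in
#'     column 11.}
#'   \item{uroborus}{1-based inclusive; columns chrom, start, end, strand,
#'     ... read count in the last column.}
#' }
#'
#' One example line per dialect ships in `inst/extdata/`
#' (`example_circexplorer2.tsv`, `example_ciri2.tsv`,
#' `example_uroborus.tsv`); all three describe the same junction.
#'
#' @param path path to the BSJ list.
#' @param dialect one of `"circexplorer2"`, `"ciri2"`, `"uroborus"`.
#' @return data.table with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+`, `-` or `.`), `support` (integer). Rows with
#'   `start >= end` are dropped with a warning.
#' @export
read_bsj_list <- function(path, dialect = c("circexplorer2", "ciri2", "uroborus")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("BSJ file not found: ", path)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), support = integer())
  raw <- tryCatch(
    suppressWarnings(fread(path, header = (dialect == "ciri2"), sep = "\t",
                           fill = TRUE)),
    error = function(e) empty)
  if (nrow(raw) == 0L) return(empty)
  out <- switch(dialect,
    circexplorer2 = data.table(
      chrom = as.character(raw[[1L]]),
      start = as.integer(raw[[2L]]),
      end = as.integer(raw[[3L]]),
      strand = if (ncol(raw) >= 6L) as.character(raw[[6L]]) else ".",
      support = if (ncol(raw) >= 5L) suppressWarnings(as.integer(raw[[5L]])) else 0L),
    ciri2 = data.table(
      chrom = as.character(raw[[2L]]),
      start = as.integer(raw[[3L]]) - 1L,
      end = as.integer(raw[[4L]]),
      strand = if (ncol(raw) >= 11L) as.character(raw[[11L]]) else ".",
      support = suppressWarnings(as.integer(raw[[5L]]))),
    uroborus = data.table(
      chrom = as.character(raw[[1L]]),
      start = as.integer(raw[[2L]]) - 1L,
      end = as.integer(raw[[3L]]),
      strand = if (ncol(raw) >= 4L) as.character(raw[[4L]]) else ".",
      support = suppressWarnings(as.integer(raw[[ncol(raw)]]))))
  out[is.na(strand) | !(strand %in% c("+", "-")), strand := "."]
  out[is.na(support), support := 0L]
  bad <- out$start >= out$end | is.na(out$start) | is.na(out$end)
  if (any(bad)) {
    warning(sum(bad), " BSJ record(s) with start >= end rejected")
    out <- out[!bad]
  }
  out[]
}

#' Filter back-splice junctions by supporting-read count
#'
#' @param bsjs BSJ table as returned by [read_bsj_list()].
#' @param min_support inclusive threshold; records with
#'   `support >= min_support` are kept.
#' @return filtered BSJ table.
#' @export
filter_bsj_by_support <- function(bsjs, min_support = 10L) {
  stopifnot(min_support >= 0L)
  bsjs[bsjs$support >= min_support, ]
}

#' Resolve unknown BSJ strands from the annotation
#'
#' A `.` strand (as in UROBORUS-style lists) is replaced by the strand of a
#' stranded annotated gene whose exon boundaries match the junction; a BSJ
#' whose recorded strand conflicts with the matched annotation is flagged
#' and the annotation strand wins.
#'
#' @param bsjs BSJ table.
#' @param annotation a `gene_annotation`.
#' @return the BSJ table with strands resolved and a logical
#'   `strand_conflict` column.
#' @export
resolve_bsj_strand <- function(bsjs, annotation) {
  if (nrow(bsjs) == 0L) {
    bsjs$strand_conflict <- logical(0)
    return(bsjs)
  }
  ann_strand <- rep(NA_character_, nrow(bsjs))
  for (l in annotation$loci) {
    hit <- bsjs$chrom == l$chrom &
      bsjs$start %in% l$exons[, 1L] & bsjs$end %in% l$exons[, 2L]
    ann_strand[hit & is.na(ann_strand)] <- l$strand
  }
  conflict <- !is.na(ann_strand) & bsjs$strand %in% c("+", "-") &
    bsjs$strand != ann_strand
  if (any(conflict))
    warning(sum(conflict), " BSJ strand(s) conflict with annotation; ",
            "annotation strand used")
  out <- data.table::copy(as.data.table(bsjs))
  out[!is.na(ann_strand), strand := ann_strand[!is.na(ann_strand)]]
  out[, strand_conflict := conflict]
  out[]
}
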