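#' Read paired-end spliced alignments from a SAM file
#'
#' Reads the mandatory SAM columns, skips unmapped, secondary and
#' supplementary records, splits every CIGAR at `N` (intron gap) operations
#' into genomic blocks, and pairs mates by query name. A mate represented by
#' more than one primary record (an alignment split at a back-splice
#' junction, as emitted by the bundled simulator) is merged into one mate
#' with multiple records and the fragment is flagged as BSJ-spanning.
#'
#' @param path path to a SAM file.
#' @return An object of class `fragment_alignments`: a list with
#'   \describe{
#'     \item{segments}{data.table of genomic blocks: `frag_id` (integer),
#'       `mate` (1/2), `record` (ordinal of the SAM record within the mate),
#'       `chrom`, `start`, `end` (0-based half-open).}
#'     \item{frags}{data.table with one row per fragment: `frag_id`,
#'       `qname`, `bsj_spanning` (any mate split across records), `n_mates`.}
#'     \item{n_fragments}{total fragments kept (used as the FPKM library
#'       size).}
#'     \item{n_unpaired}{fragments for which only one mate was found.}
#'     \item{n_skipped}{records dropped (unmapped/secondary/supplementary or
#'       unsupported CIGAR).}
#'   }
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  n_header <- 0L
  has_body <- FALSE
  con <- file(path, "r")
  repeat {
    chunk <- readLines(con, n = 1000L)
    if (length(chunk) == 0L) break
    hdr <- startsWith(chunk, "@")
    if (all(hdr)) { n_header <- n_header + length(chunk); next }
    n_header <- n_header + which(!hdr)[1L] - 1L
    has_body <- TRUE
    break
  }
  close(con)
  dt <- if (!has_body) data.table() else
    fread(path, sep = "\t", header = FALSE, skip = n_header, fill = TRUE,
              select = 1:6,
              col.names = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
              colClasses = list(character = c(1, 3, 6), integer = c(2, 4, 5)))
  if (nrow(dt) == 0L) {
    return(structure(list(
      segments = data.table(frag_id = integer(), mate = integer(),
                            record = integer(), chrom = character(),
                            start = integer(), end = integer()),
      frags = data.table(frag_id = integer(), qname = character(),
                         bsj_spanning = logical(), n_mates = integer()),
      n_fragments = 0L, n_unpaired = 0L, n_skipped = 0L),
      class = "fragment_alignments"))
  }
  keep <- bitwAnd(dt$flag, 0x4L) == 0L &      # mapped
          bitwAnd(dt$flag, 0x100L) == 0L &    # primary
          bitwAnd(dt$flag, 0x800L) == 0L &    # not supplementary
          dt$rname != "*" & !is.na(dt$pos)
  cig_ok <- grepl("^([0-9]+[MIDNSH=X])+$", dt$cigar)
  n_skipped <- sum(!(keep & cig_ok))
  if (any(keep & !cig_ok)) warning(sum(keep & !cig_ok),
      " record(s) with unsupported CIGAR operations skipped")
  dt <- dt[keep & cig_ok]
  dt[, mate := ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L)]
  dt[, frag_id := match(qname, unique(qname))]
  setorder(dt, frag_id, mate, pos)
  dt[, record := seq_len(.N), by = list(frag_id, mate)]

  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    dt$cigar, pos = dt$pos, drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(blocks)
  ub <- unlist(blocks)
  segments <- data.table(
    frag_id = rep(dt$frag_id, nb), mate = rep(dt$mate, nb),
    record = rep(dt$record, nb), chrom = rep(dt$rname, nb),
    start = IRanges::start(ub) - 1L, end = IRanges::end(ub))

  frags <- dt[, list(qname = qname[1L],
                     bsj_spanning = max(record) > 1L,
                     n_mates = data.table::uniqueN(mate)), by = frag_id]
  n_unpaired <- sum(frags$n_mates < 2L)
  if (n_unpaired > 0L)
    warning(n_unpaired, " fragment(s) had a single mapped mate")
  structure(list(segments = segments, frags = frags,
                 n_fragments = nrow(frags), n_unpaired = n_unpaired,
                 n_skipped = n_skipped),
            class = "fragment_alignments")
}

#' @export
print.fragment_alignments <- function(x, ...) {
  cat("fragment_alignments:", x$n_fragments, "fragments,",
      nrow(x$segments), "genomic blocks\n")
  cat("  BSJ-spanning:", sum(x$frags$bsj_spanning),
      " unpaired:", x$n_unpaired, " records skipped:", x$n_skipped, "\n")
  invisible(x)
}
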