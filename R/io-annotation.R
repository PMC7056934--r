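#' Read a GTF gene annotation into per-locus exon models
#'
#' Parses exon features of a GTF file and groups them by `gene_id`. Within a
#' locus, identical exon intervals arising from different transcripts are
#' stored once; exon boundary variants (same start, different end, etc.) are
#' kept as distinct intervals. Each annotated transcript is stored as a chain
#' of indices into the locus exon table, sorted by genomic coordinate.
#'
#' @param path path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return An object of class `gene_annotation`: a list with
#'   \describe{
#'     \item{loci}{named list of loci; each locus holds `gene_id`, `chrom`,
#'       `strand`, `exons` (integer matrix, columns `start`/`end`, 0-based
#'       half-open, deduplicated, sorted) and `transcripts` (named list of
#'       integer exon-index chains).}
#'     \item{index}{data.table with one row per locus (`gene_id`, `chrom`,
#'       `strand`, `span_start`, `span_end`) for fast interval lookup.}
#'   }
#' Exon records with `end < start` are dropped with a warning.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      cleaned <- .gtf_drop_inverted(path)   # retry without inverted records
      if (identical(cleaned, path))
        stop(.gtf_diagnose(path, conditionMessage(e)), call. = FALSE)
      tryCatch(rtracklayer::import(cleaned, format = "gtf"),
               error = function(e2)
                 stop(.gtf_diagnose(path, conditionMessage(e2)), call. = FALSE))
    }
  )
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features found in ", path)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,    # to 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id)
  )
  bad <- dt$end <= dt$start
  if (any(bad)) {
    warning(sum(bad), " exon record(s) with end <= start rejected")
    dt <- dt[!bad]
  }
  loci <- list()
  for (g in split(dt, by = "gene_id", sorted = TRUE)) {
    exons <- unique(g[, list(start, end)])
    setorder(exons, start, end)
    emat <- cbind(start = exons$start, end = exons$end)
    key <- paste(emat[, 1L], emat[, 2L])
    txs <- lapply(split(g, by = "transcript_id", sorted = TRUE), function(tx) {
      idx <- match(paste(tx$start, tx$end), key)
      sort(unique(idx))
    })
    gid <- g$gene_id[1L]
    loci[[gid]] <- list(
      gene_id = gid, chrom = g$chrom[1L], strand = g$strand[1L],
      exons = emat, transcripts = txs
    )
  }
  index <- rbindlist(lapply(loci, function(l) data.table(
    gene_id = l$gene_id, chrom = l$chrom, strand = l$strand,
    span_start = min(l$exons[, 1L]), span_end = max(l$exons[, 2L])
  )))
  structure(list(loci = loci, index = index), class = "gene_annotation")
}

# drop records with end < start (they abort the GTF import); returns the
# original path when the file has none
.gtf_drop_inverted <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) {
    length(f) >= 5L && !startsWith(f[1L], "#") &&
      suppressWarnings(!is.na(as.integer(f[4L])) && !is.na(as.integer(f[5L])) &&
                       as.integer(f[5L]) < as.integer(f[4L]))
  }, logical(1))
  if (!any(bad)) return(path)
  warning(sum(bad), " record(s) with end < start rejected")
  tmp <- tempfile(fileext = ".gtf")
  writeLines(lines[!bad], tmp)
  tmp
}

# locate the first structurally malformed line so the error names it
.gtf_diagnose <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  off <- which(body & nfield < 9L)
  if (length(off)) {
    sprintf("malformed GTF line %d in %s (%d field(s), expected 9)",
            off[1L], path, nfield[off[1L]])
  } else {
    sprintf("failed to parse GTF %s: %s", path, msg)
  }
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(x$loci), "loci on",
      length(unique(x$index$chrom)), "chromosome(s)\n")
  nex <- vapply(x$loci, function(l) nrow(l$exons), integer(1))
  cat("  exon intervals per locus:", paste(range(nex), collapse = "-"), "\n")
  invisible(x)
}
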