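#' Relation index of back-splice junctions
#'
#' Two BSJs are directly related when their genomic spans overlap by at
#' least 1 bp on the same chromosome; the relation is closed transitively,
#' partitioning the BSJ set into equivalence classes. The relation index
#' (RI) of a BSJ is the cardinality of its class: RI = 1 marks an isolated
#' circle, larger values mark nests of overlapping circles that are harder
#' to assemble and quantify.
#'
#' Implemented by a sweep over coordinate-sorted intervals per chromosome
#' (overlapping-interval chains merge into one class), equivalent to
#' union-find over the pairwise overlap relation.
#'
#' @param bsjs BSJ table ([read_bsj_list()]); 0-based half-open `start`,
#'   `end`.
#' @param stranded if `TRUE`, only same-strand BSJs can be related
#'   (default `FALSE`: overlap is strand-agnostic).
#' @return integer vector of RI values parallel to the rows of `bsjs`;
#'   attribute `"class_id"` holds the equivalence-class labels.
#' @export
compute_relation_index <- function(bsjs, stranded = FALSE) {
  n <- nrow(bsjs)
  if (n == 0L) {
    out <- integer(0); attr(out, "class_id") <- integer(0); return(out)
  }
  grp <- if (stranded) paste(bsjs$chrom, bsjs$strand) else bsjs$chrom
  class_id <- integer(n)
  next_class <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    o <- idx[order(bsjs$start[idx], bsjs$end[idx])]
    cur_end <- -Inf
    for (i in o) {
      if (bsjs$start[i] < cur_end) {            # overlaps the running chain
        cur_end <- max(cur_end, bsjs$end[i])
      } else {
        next_class <- next_class + 1L
        cur_end <- bsjs$end[i]
      }
      class_id[i] <- next_class
    }
  }
  sizes <- table(class_id)
  ri <- as.integer(sizes[as.character(class_id)])
  attr(ri, "class_id") <- class_id
  ri
}
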