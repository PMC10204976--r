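#' Read primary mapped alignments from a SAM or BAM file
#'
#' Reads a SAM or BAM file and keeps the mapped, primary, non-supplementary
#' records that carry a sequence -- the records from which a 3' tail can be
#' extracted. Everything else is silently skipped but tallied, so that the
#' "fraction of total aligned reads" style statistics remain auditable.
#'
#' SAM input is converted on the fly with [Rsamtools::asBam()]; `region`
#' queries additionally sort and index a temporary copy when no index is
#' present.
#'
#' @param path Path to a SAM (`.sam`) or BAM file with a header.
#' @param region Optional [GenomicRanges::GRanges] of length 1 restricting
#'   the scan to one reference interval. The reference must be present in the
#'   file header.
#' @param keep_duplicates Keep duplicate-marked records (flag 0x400)?
#'   Default `TRUE`; no deduplication is applied upstream of tail calling
#'   unless requested.
#' @param min_mapq Minimum mapping quality; records below it are skipped and
#'   tallied. Default 0 (no filter).
#'
#' @return An object of class `utail_alignments`: a list with
#'   \describe{
#'     \item{records}{data.frame with one row per retained alignment:
#'       `query_name`, `flag`, `is_reverse`, `mate_index` (1, 2 or 0 for
#'       unpaired), `reference_name`, `pos` (1-based leftmost), `mapq`,
#'       `cigar`, `seq` (as stored in SAM, i.e. reference orientation).}
#'     \item{skipped}{named integer tally: `unmapped`, `secondary`,
#'       `supplementary`, `no_seq`, `duplicate`, `low_mapq`.}
#'     \item{path}{the input path.}
#'   }
#' @examples
#' spec <- sim_spec(n_genes = 4, n_fragments = 200)
#' sim <- make_genome_and_annotation(spec, dir = tempdir())
#' rd <- simulate_reads(spec, sim, dir = tempdir())
#' aln <- read_alignments(rd$sam)
#' nrow(aln$records)
#' @export
read_alignments <- function(path, region = NULL, keep_duplicates = TRUE,
                            min_mapq = 0L) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    suppressWarnings(Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                      indexDestination = FALSE))
  } else {
    path
  }

  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what)
  } else {
    stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    ref <- as.character(GenomicRanges::seqnames(region))
    if (!ref %in% names(hdr)) {
      stop("region reference '", ref, "' not present in the file header")
    }
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      sorted <- Rsamtools::sortBam(bam, tempfile())
      Rsamtools::indexBam(sorted)
      bam <- sorted
    }
    param <- Rsamtools::ScanBamParam(what = what, which = region)
  }

  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  n <- length(flag)

  unmapped <- bitwAnd(flag, 0x4L) != 0L
  secondary <- !unmapped & bitwAnd(flag, 0x100L) != 0L
  supplementary <- !unmapped & !secondary & bitwAnd(flag, 0x800L) != 0L
  candidate <- !(unmapped | secondary | supplementary)
  no_seq <- candidate & BiocGenerics::width(res$seq) == 0L
  candidate <- candidate & !no_seq
  duplicate <- logical(n)
  if (!keep_duplicates) {
    duplicate <- candidate & bitwAnd(flag, 0x400L) != 0L
    candidate <- candidate & !duplicate
  }
  low_mapq <- candidate & res$mapq < min_mapq
  candidate <- candidate & !low_mapq

  keep <- which(candidate)
  records <- data.frame(
    query_name = res$qname[keep],
    flag = flag[keep],
    is_reverse = bitwAnd(flag[keep], 0x10L) != 0L,
    mate_index = ifelse(
      bitwAnd(flag[keep], 0x1L) == 0L, 0L,
      ifelse(bitwAnd(flag[keep], 0x40L) != 0L, 1L, 2L)),
    reference_name = as.character(res$rname[keep]),
    pos = res$pos[keep],
    mapq = res$mapq[keep],
    cigar = res$cigar[keep],
    seq = as.character(res$seq[keep]),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      records = records,
      skipped = c(unmapped = sum(unmapped), secondary = sum(secondary),
                  supplementary = sum(supplementary), no_seq = sum(no_seq),
                  duplicate = sum(duplicate), low_mapq = sum(low_mapq)),
      path = path
    ),
    class = "utail_alignments"
  )
}

#' @export
print.utail_alignments <- function(x, ...) {
  cat("utail alignments:", x$path, "\n")
  cat("  retained primary mapped records:", nrow(x$records), "\n")
  cat("  skipped:",
      paste(names(x$skipped), x$skipped, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Reference span of mapped alignments
#'
#' First and last reference base (1-based, inclusive) covered by each
#' alignment, i.e. `pos` and `pos` plus the summed lengths of
#' reference-consuming CIGAR operations (M, D, N, =, X) minus one.
#'
#' @param pos Integer vector of 1-based leftmost mapping positions.
#' @param cigar Character vector of CIGAR strings (same length as `pos`).
#' @return data.frame with columns `first_ref_base`, `last_ref_base`.
#' @examples
#' aligned_reference_span(100L, "20M100N20M6S")
#' @export
aligned_reference_span <- function(pos, cigar) {
  stopifnot(length(pos) == length(cigar), all(pos >= 1L))
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  if (any(rw == 0L)) {
    stop("CIGAR without reference-consuming operation at record(s): ",
         paste(which(rw == 0L), collapse = ", "))
  }
  data.frame(first_ref_base = pos, last_ref_base = pos + rw - 1L)
}

# records accessor tolerant of either the S3 wrapper or a bare data.frame
.alignment_records <- function(x) {
  if (inherits(x, "utail_alignments")) x$records
  else if (is.data.frame(x)) x
  else stop("expected a utail_alignments object or a records data.frame")
}
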