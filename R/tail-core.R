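#' Extract the 3'-end soft-clipped extension of each alignment
#'
#' For each mapped primary record, returns the soft clip at the read's
#' biological 3' end, oriented 5'->3' in the read's own orientation, together
#' with the junction: the genomic coordinate of the last templated (aligned)
#' base.
#'
#' SAM stores sequences in reference orientation, so the biological 3' end of
#' a plus-strand read is the right end of the stored sequence and CIGAR,
#' while for a minus-strand read it is the left end, reverse-complemented.
#' A clip at the read's biological 5' end is always ignored; hard clips (H)
#' outside a terminal soft clip carry no sequence and are skipped over.
#'
#' @param records `utail_alignments` object or its `records` data.frame.
#' @return data.frame with one row per input record: `read_id`,
#'   `reference_name`, `junction` (1-based), `strand` (`+`/`-`),
#'   `tail_seq` (DNA alphabet, 5'->3', `NA` when the 3' terminus has no soft
#'   clip), `clip_len`, `anchor_len` (reference-consuming aligned length).
#' @examples
#' rec <- data.frame(query_name = "r1", flag = 0L, is_reverse = FALSE,
#'                   mate_index = 0L, reference_name = "chr1", pos = 100L,
#'                   mapq = 60L, cigar = "20M6S",
#'                   seq = paste0(strrep("G", 20), "AAAATT"))
#' extract_three_prime_clip(rec)
#' @export
extract_three_prime_clip <- function(records) {
  rec <- .alignment_records(records)
  n <- nrow(rec)
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  anchor <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)

  clip_len <- integer(n)
  tail_seq <- rep(NA_character_, n)
  junction <- integer(n)
  minus <- rec$is_reverse

  for (i in seq_len(n)) {
    o <- ops[[i]]
    l <- lens[[i]]
    k <- length(o)
    if (minus[i]) {
      # biological 3' end is the left terminus of the stored record
      j <- 1L
      if (o[j] == "H" && k > 1L) j <- 2L
      if (o[j] == "S") clip_len[i] <- l[j]
      junction[i] <- rec$pos[i]
    } else {
      j <- k
      if (o[j] == "H" && k > 1L) j <- k - 1L
      if (o[j] == "S") clip_len[i] <- l[j]
      junction[i] <- rec$pos[i] + anchor[i] - 1L
    }
  }

  has_clip <- clip_len > 0L
  plus_idx <- which(has_clip & !minus)
  if (length(plus_idx)) {
    nc <- nchar(rec$seq[plus_idx])
    tail_seq[plus_idx] <- substr(rec$seq[plus_idx],
                                 nc - clip_len[plus_idx] + 1L, nc)
  }
  minus_idx <- which(has_clip & minus)
  if (length(minus_idx)) {
    raw <- substr(rec$seq[minus_idx], 1L, clip_len[minus_idx])
    tail_seq[minus_idx] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(raw)))
  }

  data.frame(
    read_id = rec$query_name,
    reference_name = rec$reference_name,
    junction = junction,
    strand = ifelse(minus, "-", "+"),
    tail_seq = tail_seq,
    clip_len = clip_len,
    anchor_len = anchor,
    stringsAsFactors = FALSE
  )
}

#' Classify an oriented tail sequence by the A/U tail grammar
#'
#' A tail is accepted only if, after orientation, it contains nothing but
#' A and U (T as reported by the sequencer; any other character, including
#' N, rejects the tail). Accepted tails fall into exactly one category:
#' `polyA` (`^A+$`), `oligoU` (`^T+$`), `polyAU` (`^A+T+$`, a poly(A) stretch
#' terminated by uridines -- the uridylation signature), or `mixed`
#' (any other pure-A/U arrangement).
#'
#' @param tail_seq Character vector of non-empty tail sequences, 5'->3',
#'   DNA alphabet (T for U).
#' @return data.frame with columns `category` (factor with levels
#'   polyA, polyAU, oligoU, mixed; `NA` = rejected), `a_run` (length of the
#'   maximal leading A-run), `u_run` (length of the maximal trailing U-run)
#'   and `tail_len`. Runs are `NA` for rejected tails.
#' @examples
#' classify_tail(c("AAAA", "AAATT", "TTAA", "AAAC"))
#' @export
classify_tail <- function(tail_seq) {
  if (length(tail_seq) == 0L) {
    return(data.frame(category = factor(character(), levels = TAIL_CATEGORIES),
                      a_run = integer(), u_run = integer(),
                      tail_len = integer()))
  }
  if (any(is.na(tail_seq)) || any(!nzchar(tail_seq))) {
    stop("classify_tail: empty tail sequence")
  }
  s <- toupper(tail_seq)
  tail_len <- nchar(s)
  rejected <- grepl("[^AT]", s)

  category <- rep(NA_character_, length(s))
  ok <- !rejected
  category[ok & grepl("^A+$", s)] <- "polyA"
  category[ok & grepl("^T+$", s)] <- "oligoU"
  category[ok & grepl("^A+T+$", s)] <- "polyAU"
  category[ok & is.na(category)] <- "mixed"

  a_run <- ifelse(ok, nchar(sub("^(A*).*$", "\\1", s)), NA_integer_)
  u_run <- ifelse(ok, tail_len - nchar(sub("T*$", "", s)), NA_integer_)

  data.frame(
    category = factor(category, levels = TAIL_CATEGORIES),
    a_run = as.integer(a_run),
    u_run = as.integer(u_run),
    tail_len = tail_len
  )
}

#' Tail length filter
#'
#' Retains only tails at least `min_len` nucleotides long. Extensions of up
#' to 3 nt are too easily produced by sequencing error; the default of 4
#' keeps only extensions longer than 3 nt.
#'
#' @param tail_len Integer vector of tail lengths (or a data.frame with a
#'   `tail_len` column).
#' @param min_len Minimum length, default 4.
#' @return Logical vector.
#' @export
passes_length <- function(tail_len, min_len = 4L) {
  if (is.data.frame(tail_len)) tail_len <- tail_len$tail_len
  if (length(min_len) != 1L || is.na(min_len) || min_len < 1L) {
    stop("min_len must be a positive integer")
  }
  tail_len >= min_len
}

#' Extract, classify and filter 3' tails from alignments
#'
#' The main tail-calling entry point: extracts the biological 3' soft clip
#' of every retained alignment, classifies it by the A/U grammar, and applies
#' the anchor-length and tail-length filters. Rejection reasons are tallied
#' in the `tallies` attribute of the result.
#'
#' @param alignments `utail_alignments` object (from [read_alignments()]) or
#'   a records data.frame.
#' @param min_tail_len Minimum accepted tail length, default 4.
#' @param min_anchor Minimum aligned (reference-consuming) length, default
#'   20 nt; a tail hanging off a tiny aligned anchor is unreliable.
#' @param dedup_fragments If `TRUE`, keep at most one tail per `query_name`,
#'   preferring the longer tail, ties broken in favour of mate 1. Default
#'   `FALSE`: every primary alignment is scanned independently, so fractions
#'   are read-level.
#' @return data.frame of accepted tail calls with columns `read_id`,
#'   `reference_name`, `junction`, `strand`, `tail_seq` (U alphabet),
#'   `category`, `a_run`, `u_run`, `tail_len`. Attributes: `tallies` (named
#'   integer: `n_aligned`, `no_clip`, `short_anchor`, `rejected_alphabet`,
#'   `short_tail`, `dedup_removed`, `accepted`) and `skipped` (copied from
#'   the input object when present).
#' @examples
#' spec <- sim_spec(n_genes = 4, n_fragments = 500)
#' sim <- make_genome_and_annotation(spec, dir = tempdir())
#' rd <- simulate_reads(spec, sim, dir = tempdir())
#' tails <- extract_tails(read_alignments(rd$sam))
#' table(tails$category)
#' @export
extract_tails <- function(alignments, min_tail_len = 4L, min_anchor = 20L,
                          dedup_fragments = FALSE) {
  rec <- .alignment_records(alignments)
  clips <- extract_three_prime_clip(rec)
  n_aligned <- nrow(rec)

  no_clip <- is.na(clips$tail_seq)
  short_anchor <- !no_clip & clips$anchor_len < min_anchor
  cand <- which(!no_clip & !short_anchor)

  cls <- classify_tail(clips$tail_seq[cand])
  rejected <- is.na(cls$category)
  short_tail <- !rejected & !passes_length(cls$tail_len, min_tail_len)
  keep <- cand[!rejected & !short_tail]

  out <- cbind(
    clips[keep, c("read_id", "reference_name", "junction", "strand",
                  "tail_seq"), drop = FALSE],
    cls[!rejected & !short_tail, , drop = FALSE]
  )
  # user-facing alphabet is RNA-like: report uridines as U
  out$tail_seq <- chartr("T", "U", out$tail_seq)
  rownames(out) <- NULL

  dedup_removed <- 0L
  if (dedup_fragments && nrow(out) > 1L) {
    mate <- rec$mate_index[keep]
    ord <- order(out$read_id, -out$tail_len, mate)
    out <- out[ord, , drop = FALSE]
    dup <- duplicated(out$read_id)
    dedup_removed <- sum(dup)
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }

  attr(out, "tallies") <- c(
    n_aligned = n_aligned,
    no_clip = sum(no_clip),
    short_anchor = sum(short_anchor),
    rejected_alphabet = sum(rejected),
    short_tail = sum(short_tail),
    dedup_removed = dedup_removed,
    accepted = nrow(out)
  )
  if (inherits(alignments, "utail_alignments")) {
    attr(out, "skipped") <- alignments$skipped
  }
  out
}
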