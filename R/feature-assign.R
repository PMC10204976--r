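# Default mapping from common annotation biotype strings to the closed
# vocabulary used throughout the package. Unmapped values become "other".
default_biotype_map <- function() {
  c(mRNA = "mRNA", protein_coding = "mRNA", protein_coding_gene = "mRNA",
    ncRNA_antisense = "ncRNA_antisense", antisense = "ncRNA_antisense",
    antisense_RNA = "ncRNA_antisense",
    ncRNA_bidirectional = "ncRNA_bidirectional",
    bidirectional = "ncRNA_bidirectional",
    ncRNA_intergenic = "ncRNA_intergenic", intergenic = "ncRNA_intergenic",
    lincRNA = "ncRNA_intergenic",
    ncRNA_overlapping = "ncRNA_overlapping", overlapping = "ncRNA_overlapping",
    rRNA = "rRNA", rRNA_gene = "rRNA",
    tRNA = "tRNA", tRNA_gene = "tRNA",
    snoRNA = "snoRNA", snoRNA_gene = "snoRNA",
    snRNA = "snRNA", snRNA_gene = "snRNA")
}

#' Load a genome annotation as a feature set
#'
#' Reads GFF3 or BED into a [GenomicRanges::GRanges] with `feature_id` and
#' `biotype` metadata columns. GFF3 coordinates (1-based inclusive) and BED
#' coordinates (0-based half-open) are converted by the reader; a GFF3 line
#' with `start=101, end=200` and a BED line with `100 200` describe the same
#' 100-base feature.
#'
#' @param path Annotation file path.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param biotype_attr GFF3 attribute holding the biotype (default
#'   `"biotype"`). BED carries no biotype; all features become `"other"`.
#' @param biotype_map Named character vector mapping raw biotype strings to
#'   the closed vocabulary; defaults cover common synonyms
#'   (e.g. `protein_coding` -> `mRNA`). Unmapped values become `"other"`.
#' @return `GRanges` with mcols `feature_id`, `biotype`.
#' @export
load_annotation <- function(path, dialect = c("auto", "gff3", "bed"),
                            biotype_attr = "biotype",
                            biotype_map = default_biotype_map()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- if (dialect == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }

  mc <- S4Vectors::mcols(gr)
  feature_id <- if (dialect == "bed") {
    as.character(mc$name)
  } else if (!is.null(mc$ID)) {
    as.character(mc$ID)
  } else if (!is.null(mc$Name)) {
    as.character(mc$Name)
  } else {
    stop("GFF3 features carry neither ID nor Name attributes")
  }
  if (anyNA(feature_id) || any(!nzchar(feature_id))) {
    stop("annotation contains features without an identifier")
  }
  if (anyDuplicated(feature_id)) {
    stop("duplicate feature_id in annotation: ",
         paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  }

  raw_bt <- if (dialect != "bed" && biotype_attr %in% names(mc)) {
    as.character(mc[[biotype_attr]])
  } else {
    rep(NA_character_, length(gr))
  }
  biotype <- unname(biotype_map[raw_bt])
  biotype[is.na(biotype)] <- "other"

  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = feature_id,
    biotype = factor(biotype, levels = BIOTYPES)
  )
  gr
}

#' Transcription end site of each feature
#'
#' The TES is the feature's 3'-most base in its own orientation: the last
#' (highest) genomic base for plus-strand features, the first (lowest) for
#' minus-strand features. Returned 1-based.
#'
#' @param features `GRanges` of annotated features.
#' @return Integer vector of 1-based TES coordinates.
#' @export
tes_of <- function(features) {
  minus <- as.character(GenomicRanges::strand(features)) == "-"
  ifelse(minus, GenomicRanges::start(features), GenomicRanges::end(features))
}

#' Assign tail calls to the closest annotated feature
#'
#' Each tail junction is assigned to the feature that overlaps it or,
#' failing that, to the feature with the smallest absolute genomic distance
#' on the same reference (and same strand unless `same_strand = FALSE`).
#' A junction inside a feature is always assigned to that feature even if
#' another feature's boundary is nearer; equidistant candidates are broken
#' deterministically in favour of the lexicographically smallest
#' `feature_id`. Junctions farther than `max_distance` from every candidate,
#' or on references absent from the annotation, stay unassigned (`NA`) and
#' are tallied.
#'
#' The signed TES distance is `junction - TES` for plus-strand features and
#' `TES - junction` for minus-strand features: 0 means the junction sits
#' exactly at the annotated transcription end site, positive values lie
#' downstream of it in the transcript's orientation.
#'
#' @param tails Tail-call data.frame from [extract_tails()].
#' @param features `GRanges` from [load_annotation()].
#' @param same_strand Restrict candidates to the tail's alignment strand
#'   (default `TRUE`: tails derive from the transcript's own 3' end).
#' @param max_distance Maximum junction-to-feature distance in nt
#'   (default 1000; `Inf` disables the cutoff).
#' @return `tails` with columns `feature_id`, `biotype`, `tes_distance`
#'   appended (`NA` for unassigned tails) and a `tallies` attribute
#'   (`assigned`, `unassigned_no_reference`, `unassigned_too_far`).
#' @export
assign_tails <- function(tails, features, same_strand = TRUE,
                         max_distance = 1000) {
  n <- nrow(tails)
  feature_id <- rep(NA_character_, n)
  tes_distance <- rep(NA_integer_, n)
  no_ref <- 0L

  f_ref <- as.character(GenomicRanges::seqnames(features))
  f_strand <- as.character(GenomicRanges::strand(features))
  f_start <- GenomicRanges::start(features)
  f_end <- GenomicRanges::end(features)
  f_id <- features$feature_id
  f_tes <- tes_of(features)

  groups <- if (same_strand) {
    split(seq_len(n), paste(tails$reference_name, tails$strand))
  } else {
    split(seq_len(n), tails$reference_name)
  }

  for (g in groups) {
    ref <- tails$reference_name[g[1]]
    sel <- f_ref == ref
    if (same_strand) sel <- sel & f_strand == tails$strand[g[1]]
    idx <- which(sel)
    if (!length(idx)) {
      no_ref <- no_ref + length(g)
      next
    }
    # order candidates by feature_id so that which.min resolves distance
    # ties in favour of the lexicographically smallest identifier
    idx <- idx[order(f_id[idx])]
    s <- f_start[idx]
    e <- f_end[idx]
    # chunked dense scan: junctions x candidate features
    for (chunk in split(g, ceiling(seq_along(g) / 5000L))) {
      j <- tails$junction[chunk]
      # distance from base j to interval [s, e]: 0 inside, else gap size
      d <- pmax(outer(s, j, "-"), t(outer(j, e, "-")), 0L)
      best <- apply(d, 2L, which.min)
      dist <- d[cbind(best, seq_along(chunk))]
      ok <- dist <= max_distance
      fi <- idx[best[ok]]
      feature_id[chunk[ok]] <- f_id[fi]
      td <- ifelse(f_strand[fi] == "-",
                   f_tes[fi] - j[ok],
                   j[ok] - f_tes[fi])
      tes_distance[chunk[ok]] <- as.integer(td)
    }
  }

  tails$feature_id <- feature_id
  bt <- factor(rep(NA_character_, n), levels = BIOTYPES)
  hit <- !is.na(feature_id)
  bt[hit] <- features$biotype[match(feature_id[hit], f_id)]
  tails$biotype <- bt
  tails$tes_distance <- tes_distance

  attr(tails, "assign_tallies") <- c(
    assigned = sum(hit),
    unassigned_no_reference = no_ref,
    unassigned_too_far = n - sum(hit) - no_ref
  )
  tails
}
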