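# shared fixture builders and independent oracles

# one-line SAM record with sensible defaults
sam_line <- function(qname = "r1", flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "50M",
                     seq = strrep("A", 50L)) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, mapq, cigar, seq)
}

write_sam <- function(lines, refs = c(chr1 = 100000L),
                      path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(header, lines), path)
  path
}

# records data.frame row for direct calls into tail extraction
make_record <- function(query_name = "r1", flag = 0L, is_reverse = FALSE,
                        mate_index = 0L, reference_name = "chr1",
                        pos = 100L, mapq = 60L, cigar = "50M",
                        seq = strrep("A", 50L)) {
  data.frame(query_name = query_name, flag = flag, is_reverse = is_reverse,
             mate_index = mate_index, reference_name = reference_name,
             pos = pos, mapq = mapq, cigar = cigar, seq = seq,
             stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# independent classification oracle: run-length decomposition instead of
# regular expressions
rle_classify <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  if (any(!ch %in% c("A", "T"))) return("rejected")
  r <- rle(ch)
  if (length(r$values) == 1L && r$values == "A") return("polyA")
  if (length(r$values) == 1L && r$values == "T") return("oligoU")
  if (length(r$values) == 2L && identical(r$values, c("A", "T"))) {
    return("polyAU")
  }
  "mixed"
}

# brute-force closest-feature oracle: plain loop over all features
brute_force_closest <- function(junction, strand, ref, feat_df,
                                same_strand = TRUE, max_distance = 1000) {
  best_id <- NA_character_
  best_d <- Inf
  best_tes <- NA_integer_
  best_strand <- NA_character_
  for (i in seq_len(nrow(feat_df))) {
    f <- feat_df[i, ]
    if (f$ref != ref) next
    if (same_strand && f$strand != strand) next
    d <- max(f$start - junction, junction - f$end, 0)
    if (d < best_d || (d == best_d && !is.na(best_id) &&
                       f$feature_id < best_id)) {
      best_d <- d
      best_id <- f$feature_id
      best_strand <- f$strand
      best_tes <- if (f$strand == "-") f$start else f$end
    }
  }
  if (is.infinite(best_d) || best_d > max_distance) {
    return(list(feature_id = NA_character_, tes_distance = NA_integer_))
  }
  td <- if (best_strand == "-") best_tes - junction else junction - best_tes
  list(feature_id = best_id, tes_distance = as.integer(td))
}

# quick assigned-tail data.frame for summary-level tests
make_tails <- function(category, tes_distance = 0L, u_run = NULL,
                       biotype = "mRNA", feature_id = "gene001") {
  n <- length(category)
  if (is.null(u_run)) {
    u_run <- ifelse(category == "polyA", 0L,
                    ifelse(category %in% c("polyAU", "oligoU"), 1L, 1L))
  }
  data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    reference_name = rep_len("chr1", n),
    junction = rep_len(1000L, n),
    strand = rep_len("+", n),
    tail_seq = rep_len("AAAA", n),
    category = factor(category, levels = c("polyA", "polyAU", "oligoU",
                                           "mixed")),
    a_run = rep_len(4L, n),
    u_run = rep_len(u_run, n),
    tail_len = rep_len(4L, n),
    feature_id = rep_len(feature_id, n),
    biotype = factor(rep_len(biotype, n),
                     levels = utail:::BIOTYPES),
    tes_distance = rep_len(as.integer(tes_distance), n),
    stringsAsFactors = FALSE
  )
}

# evaluate an empirical CDF (from tes_distance_cdf) at arbitrary points
cdf_at <- function(cdf, x) {
  if (!nrow(cdf)) return(rep(0, length(x)))
  f <- stats::stepfun(cdf$distance, c(0, cdf$cum_fraction))
  f(x)
}
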