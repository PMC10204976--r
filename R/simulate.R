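#' Simulation specification for a tailed-read library
#'
#' Collects every parameter of the synthetic genome / annotation / read
#' generator and validates it. The defaults emulate the structure of a
#' ligation-based RNA-seq library from an actively uridylating
#' transcriptome: about 1.5% of aligned reads carry an A/U 3' extension of
#' at least 4 nt; poly(A) and poly(AU) together dominate the tail mixture
#' (93%), with poly(AU) making up ~11% of the poly(A)-bearing tails;
#' uridine runs are mostly 1-2 nt; poly(A)/poly(AU)/mixed junctions sit at
#' the annotated TES (Gaussian jitter), while oligo(U) junctions are
#' dispersed uniformly over gene bodies.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_genes Number of non-overlapping single-exon genes.
#' @param gene_length_range Min/max gene length (nt).
#' @param genome_padding Gap between consecutive genes (nt).
#' @param n_fragments Number of sequenced fragments.
#' @param read_length Read length (nt).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of the
#'   per-gene expression rates.
#' @param tailed_read_probability Probability that a fragment carries a 3'
#'   tail.
#' @param category_mix Named probabilities over
#'   `c("polyA","polyAU","oligoU","mixed")`, summing to 1.
#' @param a_run_mean Mean poly(A) run length (geometric above a minimum of
#'   4 for polyA, 3 for polyAU, so every tail is at least 4 nt).
#' @param u_run_probs Probabilities of 1, 2 or 3 terminal uridines on
#'   poly(AU) tails.
#' @param tes_jitter_sd SD (nt) of junction placement around the TES for
#'   TES-anchored categories.
#' @param antisense_fraction Fraction of untailed background reads emitted
#'   antisense to their gene.
#' @param sequencing_error_rate Per-base substitution probability applied to
#'   the stored read sequence.
#' @param biotype_probs Named probabilities over biotypes for gene
#'   annotation.
#' @param paired Emit paired-end records (the tail carrier is mate 1)?
#'   Default `FALSE` (single-end).
#' @return `utail_sim_spec` list of validated parameters.
#' @export
sim_spec <- function(seed = 1L,
                     n_genes = 40L,
                     gene_length_range = c(500L, 1500L),
                     genome_padding = 300L,
                     n_fragments = 50000L,
                     read_length = 75L,
                     expression_meanlog = 0,
                     expression_sdlog = 1,
                     tailed_read_probability = 0.015,
                     category_mix = c(polyA = 0.828, polyAU = 0.102,
                                      oligoU = 0.04, mixed = 0.03),
                     a_run_mean = 8,
                     u_run_probs = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                     tes_jitter_sd = 20,
                     antisense_fraction = 0.02,
                     sequencing_error_rate = 0,
                     biotype_probs = c(mRNA = 0.9, ncRNA_intergenic = 0.05,
                                       ncRNA_antisense = 0.03,
                                       snoRNA = 0.02),
                     paired = FALSE) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_genes >= 1L, n_fragments >= 0L,
    length(gene_length_range) == 2L,
    gene_length_range[1] >= 2L * read_length,
    gene_length_range[1] <= gene_length_range[2],
    genome_padding >= 30L,
    read_length >= 40L,
    tailed_read_probability >= 0, tailed_read_probability <= 1,
    antisense_fraction >= 0, antisense_fraction <= 1,
    sequencing_error_rate >= 0, sequencing_error_rate < 1,
    a_run_mean > 4,
    tes_jitter_sd >= 0
  )
  if (!identical(sort(names(category_mix)), sort(TAIL_CATEGORIES))) {
    stop("category_mix must be named by ",
         paste(TAIL_CATEGORIES, collapse = ", "))
  }
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-9) {
    stop("category_mix must be non-negative and sum to 1")
  }
  if (length(u_run_probs) != 3L || any(u_run_probs < 0) ||
      abs(sum(u_run_probs) - 1) > 1e-9) {
    stop("u_run_probs must be 3 non-negative probabilities summing to 1")
  }
  if (!all(names(biotype_probs) %in% BIOTYPES) ||
      abs(sum(biotype_probs) - 1) > 1e-9) {
    stop("biotype_probs must be named by known biotypes and sum to 1")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         genome_padding = as.integer(genome_padding),
         n_fragments = as.integer(n_fragments),
         read_length = as.integer(read_length),
         expression_meanlog = expression_meanlog,
         expression_sdlog = expression_sdlog,
         tailed_read_probability = tailed_read_probability,
         category_mix = category_mix[TAIL_CATEGORIES],
         a_run_mean = a_run_mean,
         u_run_probs = u_run_probs,
         tes_jitter_sd = tes_jitter_sd,
         antisense_fraction = antisense_fraction,
         sequencing_error_rate = sequencing_error_rate,
         biotype_probs = biotype_probs,
         paired = isTRUE(paired)),
    class = "utail_sim_spec"
  )
}

#' Tail category mixture with a target uridylation frequency
#'
#' Convenience constructor for strain comparisons: builds a `category_mix`
#' in which poly(A) + poly(AU) keep a fixed share of all tails while
#' poly(AU) makes up `urid_freq` of that share, i.e. the simulated sample's
#' expected uridylation frequency equals `urid_freq`.
#'
#' @param urid_freq Target polyAU / (polyA + polyAU) frequency.
#' @param pa_share Combined poly(A) + poly(AU) share of all tails
#'   (default 0.93).
#' @param oligoU,mixed Shares of the remaining categories (must sum with
#'   `pa_share` to 1).
#' @return Named mixture vector usable as `category_mix` in [sim_spec()].
#' @export
category_mix <- function(urid_freq, pa_share = 0.93, oligoU = 0.04,
                         mixed = 0.03) {
  stopifnot(urid_freq >= 0, urid_freq <= 1,
            abs(pa_share + oligoU + mixed - 1) < 1e-9)
  c(polyA = pa_share * (1 - urid_freq), polyAU = pa_share * urid_freq,
    oligoU = oligoU, mixed = mixed)
}

#' Generate a synthetic genome and annotation
#'
#' Lays out `n_genes` non-overlapping single-exon genes on both strands of
#' one synthetic chromosome, separated by `genome_padding`. The 10 genomic
#' bases immediately downstream of every TES are forced to C/G so that the
#' boundary between templated sequence and an appended A/U tail is
#' unambiguous for any aligner run on the fixture.
#'
#' @param spec [sim_spec()] object.
#' @param dir Output directory (created if needed); writes `genome.fa`,
#'   `genes.gff3` and `genes.bed`.
#' @return list: `genome` (named character, one chromosome), `features`
#'   (`GRanges` with `feature_id`, `biotype`), `fasta`, `gff3`, `bed`
#'   (paths).
#' @export
make_genome_and_annotation <- function(spec, dir = tempfile("utail_sim_")) {
  stopifnot(inherits(spec, "utail_sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                 spec$n_genes, replace = TRUE)
  pad <- spec$genome_padding
  starts <- pad + cumsum(c(1L, (lens + pad)[-spec$n_genes]))
  ends <- starts + lens - 1L
  glen <- ends[spec$n_genes] + pad
  if (any(ends + 10L > glen)) {
    stop("genes do not fit in the genome layout")
  }
  strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
  biotype <- sample(names(spec$biotype_probs), spec$n_genes, replace = TRUE,
                    prob = spec$biotype_probs)

  base <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  # disambiguating decamer downstream of each TES (never A/T)
  for (i in seq_len(spec$n_genes)) {
    decamer <- if (strand[i] == "+") (ends[i] + 1L):(ends[i] + 10L)
               else (starts[i] - 10L):(starts[i] - 1L)
    base[decamer] <- sample(c("C", "G"), 10L, replace = TRUE)
  }
  chrom <- "sim_1"
  genome <- setNames(paste(base, collapse = ""), chrom)

  features <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strand,
    feature_id = sprintf("gene%03d", seq_len(spec$n_genes)),
    biotype = factor(biotype, levels = BIOTYPES),
    seqlengths = setNames(glen, chrom)
  )

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta)

  gff3 <- file.path(dir, "genes.gff3")
  gr_out <- features
  S4Vectors::mcols(gr_out) <- S4Vectors::DataFrame(
    type = "gene",
    ID = features$feature_id,
    biotype = as.character(features$biotype)
  )
  rtracklayer::export(gr_out, gff3, format = "GFF3")

  bed <- file.path(dir, "genes.bed")
  gr_bed <- features
  S4Vectors::mcols(gr_bed) <- S4Vectors::DataFrame(
    name = features$feature_id, score = 0L)
  rtracklayer::export(gr_bed, bed, format = "BED")

  list(genome = genome, features = features,
       fasta = fasta, gff3 = gff3, bed = bed)
}

# random pure-A/T strings that fit none of the three simple grammars
.random_mixed_tails <- function(n, min_len = 4L) {
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    lens <- min_len + rpois(length(todo), 2)
    s <- vapply(lens, function(l) {
      paste(sample(c("A", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
    ok <- !grepl("^A+$|^T+$|^A+T+$", s)
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate aligned tailed reads with ground truth
#'
#' Emits primary alignments in SAM with authoritative CIGARs: untailed
#' background reads are fully matched (`xM`); tailed reads end in a soft
#' clip (`xMyS` on the plus strand, `ySxM` reverse-complemented on the
#' minus strand, per SAM convention) whose bases are drawn from the tail
#' model of `spec`. One truth row is written per tailed read. The same seed
#' reproduces the output byte for byte.
#'
#' @param spec [sim_spec()] object.
#' @param sim Output of [make_genome_and_annotation()] (same spec).
#' @param dir Output directory; writes `reads.sam` and `truth.tsv`.
#' @return list: `sam`, `truth_path` (paths), `truth` (data.frame
#'   `read_id`, `category`, `a_run`, `u_run`, `tail_len`, `gene`,
#'   `junction`, `strand`), `expression` (data.frame `gene_id`, `count`
#'   of simulated fragments per gene), `n_fragments`.
#' @export
simulate_reads <- function(spec, sim, dir = dirname(sim$fasta)) {
  stopifnot(inherits(spec, "utail_sim_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed + 1L)

  genome <- sim$genome[[1]]
  feats <- sim$features
  g_start <- GenomicRanges::start(feats)
  g_end <- GenomicRanges::end(feats)
  g_strand <- as.character(GenomicRanges::strand(feats))
  g_tes <- tes_of(feats)
  g_id <- feats$feature_id
  n_genes <- length(feats)
  L <- spec$read_length
  max_tail <- L - 25L  # always leaves a >= 25 nt aligned anchor

  n <- spec$n_fragments
  rates <- rlnorm(n_genes, spec$expression_meanlog, spec$expression_sdlog)
  gene_idx <- sample.int(n_genes, n, replace = TRUE, prob = rates)
  tailed <- runif(n) < spec$tailed_read_probability

  read_id <- sprintf("frag%07d", seq_len(n))
  flag <- integer(n)
  pos <- integer(n)
  cig <- character(n)
  sq <- character(n)

  ## untailed background reads
  iu <- which(!tailed)
  if (length(iu)) {
    gi <- gene_idx[iu]
    p0 <- g_start[gi] +
      floor(runif(length(iu)) * (g_end[gi] - g_start[gi] - L + 2L))
    sense <- runif(length(iu)) >= spec$antisense_fraction
    minus <- ifelse(sense, g_strand[gi] == "-", g_strand[gi] == "+")
    pos[iu] <- as.integer(p0)
    flag[iu] <- ifelse(minus, 16L, 0L)
    cig[iu] <- paste0(L, "M")
    sq[iu] <- substring(genome, p0, p0 + L - 1L)
  }

  ## tailed reads
  it <- which(tailed)
  truth <- NULL
  if (length(it)) {
    m <- length(it)
    gi <- gene_idx[it]
    cat_i <- sample(TAIL_CATEGORIES, m, replace = TRUE,
                    prob = spec$category_mix)

    a_run <- integer(m)
    u_run <- integer(m)
    tail_str <- character(m)
    p_geo <- 1 / (spec$a_run_mean - 4 + 1)

    ipa <- cat_i == "polyA"
    a_run[ipa] <- pmin(4L + rgeom(sum(ipa), p_geo), max_tail)
    tail_str[ipa] <- strrep("A", a_run[ipa])

    iau <- cat_i == "polyAU"
    u_run[iau] <- sample(1:3, sum(iau), replace = TRUE,
                         prob = spec$u_run_probs)
    a_run[iau] <- pmin(3L + rgeom(sum(iau), p_geo), max_tail - u_run[iau])
    tail_str[iau] <- paste0(strrep("A", a_run[iau]),
                            strrep("T", u_run[iau]))

    iou <- cat_i == "oligoU"
    u_run[iou] <- pmin(4L + rgeom(sum(iou), 1 / 3), max_tail)
    tail_str[iou] <- strrep("T", u_run[iou])

    imx <- cat_i == "mixed"
    if (any(imx)) {
      mx <- .random_mixed_tails(sum(imx))
      tail_str[imx] <- mx
      a_run[imx] <- nchar(sub("^(A*).*$", "\\1", mx))
      u_run[imx] <- nchar(mx) - nchar(sub("T*$", "", mx))
    }

    tail_len <- nchar(tail_str)
    anchor <- L - tail_len
    minus <- g_strand[gi] == "-"

    # junction placement: TES-anchored categories jitter around the TES,
    # oligo(U) junctions fall uniformly over the gene body
    at_tes <- cat_i != "oligoU"
    jit <- as.integer(round(rnorm(m, 0, spec$tes_jitter_sd)))
    j <- integer(m)
    j[at_tes & !minus] <- pmin(pmax(g_tes[gi] + jit,
                                    g_start[gi] + anchor),
                               g_tes[gi] + 10L)[at_tes & !minus]
    j[at_tes & minus] <- pmax(pmin(g_tes[gi] + jit,
                                   g_end[gi] - anchor),
                              g_tes[gi] - 10L)[at_tes & minus]
    uu <- runif(m)
    j[!at_tes & !minus] <- (g_start[gi] + anchor +
      floor(uu * (g_end[gi] - g_start[gi] - anchor + 1L)))[!at_tes & !minus]
    j[!at_tes & minus] <- (g_start[gi] +
      floor(uu * (g_end[gi] - g_start[gi] - anchor + 1L)))[!at_tes & minus]

    ip <- it[!minus]
    if (length(ip)) {
      jj <- j[!minus]; aa <- anchor[!minus]
      pos[ip] <- jj - aa + 1L
      cig[ip] <- paste0(aa, "M", tail_len[!minus], "S")
      sq[ip] <- paste0(substring(genome, jj - aa + 1L, jj),
                       tail_str[!minus])
      flag[ip] <- 0L
    }
    im <- it[minus]
    if (length(im)) {
      jj <- j[minus]; aa <- anchor[minus]
      pos[im] <- jj
      cig[im] <- paste0(tail_len[minus], "S", aa, "M")
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(tail_str[minus])))
      sq[im] <- paste0(rc, substring(genome, jj, jj + aa - 1L))
      flag[im] <- 16L
    }

    truth <- data.frame(
      read_id = read_id[it],
      category = factor(cat_i, levels = TAIL_CATEGORIES),
      a_run = ifelse(cat_i == "oligoU", 0L, a_run),
      u_run = ifelse(cat_i == "polyA", 0L, u_run),
      tail_len = tail_len,
      gene = g_id[gi],
      junction = j,
      strand = g_strand[gi],
      stringsAsFactors = FALSE
    )
  }

  ## sequencing errors on the stored sequence
  if (spec$sequencing_error_rate > 0 && n > 0) {
    n_err <- rbinom(n, nchar(sq), spec$sequencing_error_rate)
    for (i in which(n_err > 0)) {
      p <- sample.int(nchar(sq[i]), n_err[i])
      old <- substring(sq[i], p, p)
      new <- vapply(old, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
      for (k in seq_along(p)) {
        substr(sq[i], p[k], p[k]) <- new[k]
      }
    }
  }

  chrom <- names(sim$genome)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, nchar(genome)),
              "@PG\tID:utail\tPN:utail")

  if (!spec$paired) {
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                     read_id, flag, chrom, pos, cig, sq)
  } else {
    # mate 1 carries the 3' end (and tail, when present); mate 2 is a fully
    # matched read from the same gene
    gi_all <- gene_idx
    p2 <- g_start[gi_all] +
      floor(runif(n) * (g_end[gi_all] - g_start[gi_all] - L + 2L))
    sq2 <- substring(genome, p2, p2 + L - 1L)
    # mates sit on opposite strands: read2 is reverse iff read1 is forward
    m1_rev <- bitwAnd(flag, 16L) != 0L
    f1 <- flag + 1L + 2L + 64L + ifelse(m1_rev, 0L, 32L)
    f2 <- 1L + 2L + 128L + ifelse(m1_rev, 32L, 16L)
    lines <- as.vector(rbind(
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t*",
              read_id, f1, chrom, pos, cig, p2, sq),
      sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t*",
              read_id, f2, chrom, as.integer(p2), L, pos, sq2)
    ))
  }

  sam <- file.path(dir, "reads.sam")
  writeLines(c(header, lines), sam)

  if (is.null(truth)) {
    truth <- data.frame(read_id = character(),
                        category = factor(character(),
                                          levels = TAIL_CATEGORIES),
                        a_run = integer(), u_run = integer(),
                        tail_len = integer(), gene = character(),
                        junction = integer(), strand = character())
  }
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  expression <- data.frame(
    gene_id = g_id,
    count = as.integer(tabulate(gene_idx, nbins = n_genes))
  )

  list(sam = sam, truth = truth, truth_path = truth_path,
       expression = expression, n_fragments = n)
}

#' Compare tail calls with simulation ground truth
#'
#' Joins calls and truth by `read_id` and reports the per-category
#' confusion matrix, precision and recall. With zero sequencing error and a
#' length threshold no higher than the shortest simulated tail, the full
#' pipeline recovers the truth exactly.
#'
#' @param calls Tail-call data.frame (`read_id`, `category`).
#' @param truth Truth data.frame from [simulate_reads()].
#' @return list: `confusion` (truth x called, with a `missed` column),
#'   `metrics` (per category: `n_truth`, `n_called`, `precision`,
#'   `recall`), `n_false_calls` (calls whose read is not in the truth set).
#' @export
evaluate_calls <- function(calls, truth) {
  if (anyDuplicated(calls$read_id)) {
    stop("duplicate read_ids in calls; deduplicate fragments first")
  }
  m <- match(truth$read_id, calls$read_id)
  called <- as.character(calls$category)[m]
  called[is.na(called)] <- "missed"
  confusion <- table(
    truth = factor(as.character(truth$category), levels = TAIL_CATEGORIES),
    called = factor(called, levels = c(TAIL_CATEGORIES, "missed"))
  )
  in_truth <- calls$read_id %in% truth$read_id
  n_false <- sum(!in_truth)

  metrics <- do.call(rbind, lapply(TAIL_CATEGORIES, function(cc) {
    tp <- confusion[cc, cc]
    n_truth <- sum(confusion[cc, ])
    n_called <- sum(calls$category == cc)
    data.frame(category = cc, n_truth = n_truth, n_called = n_called,
               precision = if (n_called > 0) tp / n_called else NA_real_,
               recall = if (n_truth > 0) tp / n_truth else NA_real_)
  }))

  list(confusion = confusion, metrics = metrics, n_false_calls = n_false)
}
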