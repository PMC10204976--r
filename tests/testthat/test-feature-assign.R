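write_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  lines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   df$ref, df$start, df$end, df$strand, df$feature_id,
                   df$biotype)
  writeLines(c("##gff-version 3", lines), path)
  path
}

test_that("GFF3 and BED describe the same interval after conversion", {
  gff <- write_gff3(data.frame(ref = "chr1", start = 101L, end = 200L,
                               strand = "+", feature_id = "g1",
                               biotype = "mRNA"))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1\t0\t+", bed)
  fg <- load_annotation(gff)
  fb <- load_annotation(bed)
  expect_equal(GenomicRanges::start(fg), 101L)
  expect_equal(GenomicRanges::end(fg), 200L)
  expect_equal(GenomicRanges::start(fb), GenomicRanges::start(fg))
  expect_equal(GenomicRanges::end(fb), GenomicRanges::end(fg))
  expect_equal(GenomicRanges::width(fg), 100L)
  expect_equal(fg$feature_id, "g1")
  expect_equal(as.character(fg$biotype), "mRNA")
  # BED has no biotype attribute
  expect_equal(as.character(fb$biotype), "other")
})

test_that("biotype strings map onto the closed vocabulary", {
  gff <- write_gff3(data.frame(ref = "chr1", start = c(1L, 500L, 900L),
                               end = c(100L, 600L, 1000L), strand = "+",
                               feature_id = c("a", "b", "c"),
                               biotype = c("protein_coding", "snoRNA_gene",
                                           "weird_thing")))
  f <- load_annotation(gff)
  expect_equal(as.character(f$biotype), c("mRNA", "snoRNA", "other"))
})

test_that("duplicate feature identifiers are rejected", {
  gff <- write_gff3(data.frame(ref = "chr1", start = c(1L, 500L),
                               end = c(100L, 600L), strand = "+",
                               feature_id = c("dup", "dup"),
                               biotype = "mRNA"))
  expect_error(load_annotation(gff), "duplicate")
})

test_that("TES is the 3'-most base in the feature's own orientation", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                               strand = c("+", "-"))
  gr <- rep(gr[1], 2)
  GenomicRanges::strand(gr) <- c("+", "-")
  expect_equal(tes_of(gr), c(200L, 101L))
})

test_that("overlap assignment and the signed TES distance convention", {
  gff <- write_gff3(data.frame(ref = "chr1", start = 1L, end = 1000L,
                               strand = "+", feature_id = "g1",
                               biotype = "mRNA"))
  feats <- load_annotation(gff)
  tails <- make_tails(c("polyA", "polyA", "polyA"))
  tails$junction <- c(1000L, 990L, 1010L)
  tails$feature_id <- NULL; tails$biotype <- NULL; tails$tes_distance <- NULL
  asn <- assign_tails(tails, feats)
  expect_equal(asn$feature_id, rep("g1", 3))
  expect_equal(asn$tes_distance, c(0L, -10L, 10L))

  # minus-strand sign convention mirrors
  gffm <- write_gff3(data.frame(ref = "chr1", start = 101L, end = 1000L,
                                strand = "-", feature_id = "gm",
                                biotype = "mRNA"))
  fm <- load_annotation(gffm)
  tm <- tails
  tm$strand <- "-"
  tm$junction <- c(101L, 111L, 95L)
  am <- assign_tails(tm, fm)
  expect_equal(am$tes_distance, c(0L, -10L, 6L))
})

test_that("overlap beats proximity and ties break lexicographically", {
  gff <- write_gff3(data.frame(
    ref = "chr1", start = c(1L, 1003L, 2000L, 2100L),
    end = c(1000L, 1500L, 2050L, 2150L), strand = "+",
    feature_id = c("host", "near", "zb", "za"),
    biotype = "mRNA"))
  feats <- load_annotation(gff)
  t1 <- make_tails("polyA")[, 1:9]
  # junction inside "host" but only 4 nt from "near"'s start
  t1$junction <- 999L
  expect_equal(assign_tails(t1, feats)$feature_id, "host")
  # equidistant between zb (end 2050) and za (start 2100): za wins on id
  t2 <- make_tails("polyA")[, 1:9]
  t2$junction <- 2075L
  expect_equal(assign_tails(t2, feats)$feature_id, "za")
})

test_that("strand restriction keeps antisense tails off the sense gene", {
  gff <- write_gff3(data.frame(ref = "chr1", start = 1L, end = 1000L,
                               strand = "+", feature_id = "sense",
                               biotype = "mRNA"))
  feats <- load_annotation(gff)
  t <- make_tails("polyA")[, 1:9]
  t$strand <- "-"
  t$junction <- 500L
  expect_true(is.na(assign_tails(t, feats)$feature_id))
  expect_equal(assign_tails(t, feats, same_strand = FALSE)$feature_id,
               "sense")
})

test_that("junctions beyond max_distance or on unknown references stay unassigned", {
  gff <- write_gff3(data.frame(ref = "chr1", start = 1L, end = 1000L,
                               strand = "+", feature_id = "g1",
                               biotype = "mRNA"))
  feats <- load_annotation(gff)
  t <- make_tails(c("polyA", "polyA"))[, 1:9]
  t$junction <- c(2500L, 1500L)
  t$reference_name <- c("chr1", "chr2")
  asn <- assign_tails(t, feats, max_distance = 1000)
  expect_true(all(is.na(asn$feature_id)))
  tal <- attr(asn, "assign_tallies")
  expect_equal(tal[["unassigned_too_far"]], 1L)
  expect_equal(tal[["unassigned_no_reference"]], 1L)
  # unlimited distance assigns the far junction
  expect_equal(assign_tails(t[1, ], feats,
                            max_distance = Inf)$feature_id, "g1")
})

test_that("closest-feature assignment equals the brute-force scan on random instances", {
  set.seed(202)
  for (inst in 1:10) {
    n_feat <- sample(3:30, 1)
    starts <- sort(sample.int(50000L, n_feat))
    widths <- sample(50:500, n_feat, replace = TRUE)
    feat_df <- data.frame(
      ref = "chr1", start = starts, end = starts + widths,
      strand = sample(c("+", "-"), n_feat, replace = TRUE),
      feature_id = sprintf("f%03d", sample.int(999L, n_feat)))
    gff <- write_gff3(cbind(feat_df, biotype = "mRNA"))
    feats <- load_annotation(gff)

    n_j <- 200L
    tails <- make_tails(rep("polyA", n_j))[, 1:9]
    tails$junction <- sample.int(60000L, n_j, replace = TRUE)
    tails$strand <- sample(c("+", "-"), n_j, replace = TRUE)
    asn <- assign_tails(tails, feats, max_distance = 1000)
    for (k in seq_len(n_j)) {
      oracle <- brute_force_closest(tails$junction[k], tails$strand[k],
                                    "chr1", feat_df, max_distance = 1000)
      expect_identical(asn$feature_id[k], oracle$feature_id)
      expect_identical(asn$tes_distance[k], oracle$tes_distance)
    }
  }
})

test_that("TES distance is invariant under a global coordinate shift", {
  set.seed(99)
  starts <- sort(sample.int(10000L, 5))
  feat_df <- data.frame(ref = "chr1", start = starts, end = starts + 300L,
                        strand = "+", feature_id = sprintf("g%d", 1:5),
                        biotype = "mRNA")
  tails <- make_tails(rep("polyA", 50))[, 1:9]
  tails$junction <- sample.int(11000L, 50)
  base <- assign_tails(tails, load_annotation(write_gff3(feat_df)))
  shift <- 12345L
  feat_df2 <- feat_df
  feat_df2$start <- feat_df2$start + shift
  feat_df2$end <- feat_df2$end + shift
  tails2 <- tails
  tails2$junction <- tails2$junction + shift
  shifted <- assign_tails(tails2, load_annotation(write_gff3(feat_df2)))
  expect_equal(shifted$feature_id, base$feature_id)
  expect_equal(shifted$tes_distance, base$tes_distance)
})
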