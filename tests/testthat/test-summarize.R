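test_that("category fractions report auditable numerators and denominators", {
  tails <- make_tails(c("polyA", "polyA", "polyAU", "oligoU"))
  sm <- category_fractions(tails, total_aligned = 400L, sample_id = "s1")
  expect_equal(sm$tailed_fraction, 0.01)
  expect_equal(sm$n_tailed, 4L)
  expect_equal(unname(sm$counts), c(2L, 1L, 1L, 0L))
  share <- sum(sm$fraction_of_tailed[c("polyA", "polyAU")])
  expect_equal(share, 0.75)
  expect_error(category_fractions(tails, 0L), "positive")

  empty <- category_fractions(make_tails(character()), 100L)
  expect_equal(empty$n_tailed, 0L)
  expect_true(all(empty$fraction_of_tailed == 0))
  expect_equal(empty$tailed_fraction, 0)
})

test_that("recovered fractions track a known binomial mixture", {
  set.seed(5)
  mix <- c(polyA = 0.80, polyAU = 0.13, oligoU = 0.04, mixed = 0.03)
  n <- 50000L
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  sm <- category_fractions(make_tails(cats), total_aligned = n * 60L)
  for (cc in names(mix)) {
    sd3 <- 3 * sqrt(mix[[cc]] * (1 - mix[[cc]]) / n)
    expect_lt(abs(sm$fraction_of_tailed[[cc]] - mix[[cc]]), sd3)
  }
})

test_that("uridylation frequency uses the chosen denominator and biotype filter", {
  tails <- make_tails(c(rep("polyA", 90), rep("polyAU", 10),
                        rep("oligoU", 20)))
  ur <- uridylation_frequency(tails)
  expect_equal(ur$frequency, 0.10)
  expect_equal(ur$n_denominator, 100L)
  ur_all <- uridylation_frequency(tails, denominator = "all-tailed")
  expect_equal(ur_all$n_denominator, 120L)
  # no uridylated reads is 0, an empty denominator is undefined (NA)
  expect_equal(uridylation_frequency(make_tails(rep("polyA", 5)))$frequency,
               0)
  nc <- make_tails(rep("polyAU", 5), biotype = "snoRNA")
  expect_true(is.na(uridylation_frequency(nc)$frequency))
  expect_equal(uridylation_frequency(nc, biotypes = NULL)$frequency, 1)
})

test_that("strain loss averages replicates before the ratio", {
  freqs <- data.frame(
    sample_id = c("wt1", "wt2", "m1", "m2"),
    strain = c("WT", "WT", "mut", "mut"),
    frequency = c(0.10, 0.12, 0.05, 0.056))
  sl <- strain_loss(freqs, "WT")
  expect_equal(sl$loss_pct[sl$strain == "WT"], 0)
  expect_equal(sl$frequency[sl$strain == "mut"], 0.053)
  expect_equal(sl$loss_pct[sl$strain == "mut"],
               100 * (1 - 0.053 / 0.11))
  # printed-frequency arithmetic: 0.11 vs 0.053 is a 51.8% loss
  sl2 <- strain_loss(data.frame(sample_id = c("a", "b"),
                                strain = c("WT", "d1"),
                                frequency = c(0.11, 0.053)), "WT")
  expect_equal(round(sl2$loss_pct[2], 1), 51.8)
  # degenerate comparisons
  sl3 <- strain_loss(data.frame(sample_id = c("a", "b", "c"),
                                strain = c("WT", "same", "gone"),
                                frequency = c(0.11, 0.11, 0)), "WT")
  expect_equal(sl3$loss_pct[sl3$strain == "same"], 0)
  expect_equal(sl3$loss_pct[sl3$strain == "gone"], 100)
  expect_error(strain_loss(freqs, "absent"), "not present")
  expect_error(strain_loss(data.frame(sample_id = "a", strain = "WT",
                                      frequency = 0), "WT"), "zero")
})

test_that("TES-distance CDF is a monotone step function over the window", {
  t0 <- make_tails(rep("polyA", 3), tes_distance = 0L)
  cdf0 <- tes_distance_cdf(t0)
  expect_equal(cdf0, data.frame(distance = 0, cum_fraction = 1),
               ignore_attr = TRUE)

  t1 <- make_tails(rep("polyA", 3), tes_distance = c(0L, -10L, 100L))
  cdf1 <- tes_distance_cdf(t1)
  expect_equal(cdf1$cum_fraction, c(1, 2, 3) / 3)
  expect_equal(cdf1$distance, c(0, 10, 100))

  set.seed(8)
  tr <- make_tails(rep("polyAU", 500),
                   tes_distance = as.integer(rnorm(500, 0, 300)))
  cdf <- tes_distance_cdf(tr, window = 400)
  expect_true(all(diff(cdf$cum_fraction) > 0))
  expect_equal(max(cdf$cum_fraction), 1)
  expect_equal(attr(cdf, "n_within") + attr(cdf, "n_outside"), 500L)
  expect_warning(tes_distance_cdf(tr, category = "oligoU"), "no tails")
})

test_that("uridine-run histogram counts the poly(AU) subset", {
  tails <- make_tails(c("polyAU", "polyAU", "polyAU", "polyA"),
                      u_run = c(1L, 2L, 1L, 0L))
  h <- u_run_histogram(tails)
  expect_equal(h, data.frame(u_run = c(1L, 2L), count = c(2L, 1L)))
  expect_equal(sum(h$count), 3L)
  expect_equal(nrow(u_run_histogram(make_tails("polyA"))), 0L)
})

test_that("recovered u-run distribution matches a known multinomial", {
  set.seed(9)
  probs <- c(0.6, 0.3, 0.1)
  n <- 10000L
  u <- sample(1:3, n, replace = TRUE, prob = probs)
  h <- u_run_histogram(make_tails(rep("polyAU", n), u_run = u))
  for (k in 1:3) {
    sd3 <- 3 * sqrt(probs[k] * (1 - probs[k]) * n)
    expect_lt(abs(h$count[h$u_run == k] - probs[k] * n), sd3)
  }
})

test_that("per-gene threshold keeps the boundary gene with 5, drops 4", {
  rep1 <- make_tails(rep("polyA", 6),
                     feature_id = c("gA", "gA", "gB", "gB", "gB", "gB"))
  rep2 <- make_tails(c("polyA", "polyAU", "polyAU", "oligoU"),
                     feature_id = c("gA", "gA", "gB", "gB"))
  gt <- per_gene_table(list(r1 = rep1, r2 = rep2), min_total = 5L)
  # gA: 2+1 polyA + 1 polyAU = 4 -> dropped; gB: 4 polyA + 1 polyAU = 5
  # (the oligoU read never counts)
  expect_equal(gt$gene_id, "gB")
  expect_equal(gt$total_tailed, 5L)
  expect_true(gt$both_categories)
  gt0 <- per_gene_table(list(r1 = rep1, r2 = rep2), min_total = 0L)
  expect_setequal(gt0$gene_id, c("gA", "gB"))
})

test_that("threshold filtering commutes with manual filtering", {
  set.seed(12)
  reps <- lapply(1:2, function(i) {
    n <- 400L
    make_tails(sample(c("polyA", "polyAU"), n, TRUE, prob = c(0.9, 0.1)),
               feature_id = sprintf("g%02d", sample.int(30L, n, TRUE)))
  })
  names(reps) <- c("r1", "r2")
  full <- per_gene_table(reps, min_total = 0L)
  for (k in c(1L, 5L, 20L)) {
    manual <- full[full$total_tailed >= k, ]
    direct <- per_gene_table(reps, min_total = k)
    expect_equal(direct$gene_id, manual$gene_id)
    expect_equal(direct$total_tailed, manual$total_tailed)
  }
})

test_that("expression correlation is 1 for proportional counts and NA for constants", {
  gt <- per_gene_table(list(r1 = make_tails(
    rep("polyA", 60), feature_id = rep(sprintf("g%d", 1:3), c(10, 20, 30)))),
    min_total = 0L,
    expression = data.frame(gene_id = sprintf("g%d", 1:3),
                            count = c(100L, 200L, 300L)))
  # tailed exactly proportional to expression -> r = 1 on the log scale
  expect_equal(expression_correlation(gt), 1, tolerance = 1e-3)

  gtc <- gt
  gtc$total_tailed <- 5L
  expect_warning(r <- expression_correlation(gtc), "zero variance")
  expect_true(is.na(r))
  expect_error(expression_correlation(gt[1:2, ]), "at least 3")
})

test_that("binomial tail sampling across an expression range gives r > 0.8", {
  set.seed(31)
  n_genes <- 100L
  expr <- round(10 ^ runif(n_genes, 1, 3))  # 100-fold range
  tailed <- rbinom(n_genes, expr, 0.05)
  ids <- sprintf("g%03d", seq_len(n_genes))
  tl <- make_tails(rep("polyA", sum(tailed)),
                   feature_id = rep(ids, tailed))
  gt <- per_gene_table(list(r1 = tl), min_total = 0L,
                       expression = data.frame(gene_id = ids, count = expr))
  expect_gt(expression_correlation(gt), 0.8)
})

test_that("correlation matrix is symmetric with unit diagonal; permutation kills r", {
  set.seed(77)
  n_genes <- 200L
  rate <- rlnorm(n_genes, 3, 0.8)
  ids <- sprintf("g%03d", seq_len(n_genes))
  reps <- lapply(1:2, function(i) {
    counts <- rpois(n_genes, rate)
    make_tails(rep("polyA", sum(counts)), feature_id = rep(ids, counts))
  })
  names(reps) <- c("s1", "s2")
  gt <- per_gene_table(reps, min_total = 0L)
  cm <- correlation_matrix(gt, columns = c("s1.polyA", "s2.polyA"))
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), c(1, 1))
  expect_gt(cm["s1.polyA", "s2.polyA"], 0.9)

  gt_perm <- gt
  gt_perm$s2.polyA <- sample(gt_perm$s2.polyA)
  cmp <- correlation_matrix(gt_perm, columns = c("s1.polyA", "s2.polyA"))
  expect_lt(abs(cmp["s1.polyA", "s2.polyA"]), 0.2)
  expect_error(correlation_matrix(gt[1:2, ]), "fewer than 3")
})

test_that("biotype breakdown counts sum to the assigned-tail count", {
  tails <- rbind(make_tails(rep("polyA", 9)),
                 make_tails("polyA", biotype = "snoRNA"))
  tails$feature_id[5] <- NA
  tails$biotype[5] <- NA
  bb <- biotype_breakdown(tails)
  expect_equal(sum(bb$count), 9L)
  expect_equal(attr(bb, "n_unassigned"), 1L)
  expect_equal(bb$fraction[bb$biotype == "mRNA"], 8 / 9)
})
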