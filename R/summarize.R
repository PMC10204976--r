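#' Per-sample tail category counts and fractions
#'
#' Counts accepted tails per category, their fractions of all tailed reads,
#' and the tailed fraction of total aligned reads. Numerators and
#' denominators are kept alongside every fraction so the statistics remain
#' auditable.
#'
#' @param tails Tail-call data.frame (already length-filtered).
#' @param total_aligned Number of primary mapped reads in the sample.
#' @param sample_id Sample label.
#' @return `utail_sample_summary` list: `sample_id`, `total_aligned`,
#'   `counts` (per category), `n_tailed`, `fraction_of_tailed`,
#'   `tailed_fraction`, `biotype_counts` (when tails are assigned),
#'   `uridylation` (when tails carry biotypes; see
#'   [uridylation_frequency()]).
#' @export
category_fractions <- function(tails, total_aligned, sample_id = "sample") {
  if (length(total_aligned) != 1L || is.na(total_aligned) ||
      total_aligned <= 0) {
    stop("total_aligned must be a positive count")
  }
  counts <- table(factor(tails$category, levels = TAIL_CATEGORIES))
  counts <- setNames(as.integer(counts), TAIL_CATEGORIES)
  n_tailed <- sum(counts)
  frac <- if (n_tailed > 0) counts / n_tailed else setNames(
    rep(0, length(TAIL_CATEGORIES)), TAIL_CATEGORIES)

  out <- list(
    sample_id = sample_id,
    total_aligned = as.integer(total_aligned),
    counts = counts,
    n_tailed = n_tailed,
    fraction_of_tailed = frac,
    tailed_fraction = n_tailed / total_aligned
  )
  if ("biotype" %in% names(tails)) {
    out$biotype_counts <- table(tails$biotype)
    out$uridylation <- uridylation_frequency(tails)
  }
  class(out) <- "utail_sample_summary"
  out
}

#' @export
print.utail_sample_summary <- function(x, ...) {
  cat("Sample", x$sample_id, "-", x$n_tailed, "tailed /", x$total_aligned,
      sprintf("aligned reads (%.2f%%)\n", 100 * x$tailed_fraction))
  print(data.frame(count = x$counts,
                   fraction = round(x$fraction_of_tailed, 4)))
  if (!is.null(x$uridylation) && !is.na(x$uridylation$frequency)) {
    cat(sprintf("uridylation frequency (mRNA): %.3f (%d / %d)\n",
                x$uridylation$frequency, x$uridylation$n_uridylated,
                x$uridylation$n_denominator))
  }
  invisible(x)
}

#' Uridylation frequency of a sample
#'
#' Share of uridylated poly(A) tails: poly(AU) count divided by the chosen
#' denominator, restricted to tails assigned to the given biotypes
#' (default mRNA). The default denominator, `"polyA+polyAU"`, reads as
#' "fraction of poly(A)-bearing tails that carry terminal uridines";
#' `"all-tailed"` divides by all accepted tails instead. A zero denominator
#' yields `NA` (undefined), never 0.
#'
#' @param tails Assigned tail-call data.frame (needs `biotype` unless
#'   `biotypes = NULL`).
#' @param biotypes Biotype filter; `NULL` disables filtering.
#' @param denominator `"polyA+polyAU"` (default) or `"all-tailed"`.
#' @return list: `frequency`, `n_uridylated`, `n_denominator`.
#' @export
uridylation_frequency <- function(tails, biotypes = "mRNA",
                                  denominator = c("polyA+polyAU",
                                                  "all-tailed")) {
  denominator <- match.arg(denominator)
  if (!is.null(biotypes)) {
    if (!"biotype" %in% names(tails)) {
      stop("tails carry no biotype column; assign them first or set ",
           "biotypes = NULL")
    }
    tails <- tails[!is.na(tails$biotype) & tails$biotype %in% biotypes, ,
                   drop = FALSE]
  }
  n_au <- sum(tails$category == "polyAU")
  n_den <- if (denominator == "polyA+polyAU") {
    sum(tails$category %in% c("polyA", "polyAU"))
  } else {
    nrow(tails)
  }
  list(
    frequency = if (n_den > 0) n_au / n_den else NA_real_,
    n_uridylated = n_au,
    n_denominator = n_den
  )
}

#' Relative uridylation loss between strains
#'
#' Per-replicate uridylation frequencies are averaged within each strain,
#' then each strain's loss relative to the baseline is
#' `100 * (1 - f_strain / f_baseline)` percent, the scale on which a
#' terminal-uridyltransferase deletion is reported (e.g. a drop from 0.11
#' to 0.053 is a 51.8% loss).
#'
#' @param frequencies data.frame with columns `sample_id`, `strain`,
#'   `frequency` (one row per replicate).
#' @param baseline Baseline strain name.
#' @return data.frame: `strain`, `n_replicates`, `frequency` (strain mean),
#'   `loss_pct`; baseline loss is 0 by construction.
#' @export
strain_loss <- function(frequencies, baseline) {
  stopifnot(all(c("strain", "frequency") %in% names(frequencies)))
  if (!baseline %in% frequencies$strain) {
    stop("baseline strain '", baseline, "' not present")
  }
  if (anyNA(frequencies$frequency)) {
    stop("undefined (NA) frequencies cannot enter a strain comparison")
  }
  agg <- stats::aggregate(frequency ~ strain, data = frequencies, FUN = mean)
  nrep <- stats::aggregate(frequency ~ strain, data = frequencies,
                           FUN = length)
  f_base <- agg$frequency[agg$strain == baseline]
  if (f_base == 0) stop("baseline uridylation frequency is zero")
  out <- data.frame(
    strain = agg$strain,
    n_replicates = nrep$frequency,
    frequency = agg$frequency,
    loss_pct = 100 * (1 - agg$frequency / f_base)
  )
  out[order(match(out$strain, unique(frequencies$strain))), , drop = FALSE]
}

#' Cumulative distribution of junction-to-TES distances
#'
#' Empirical CDF of the (absolute, by default) distance between tail
#' junctions and the TES of their assigned feature, over a window. Tails
#' beyond the window, or unassigned, are excluded and tallied.
#'
#' @param tails Assigned tail-call data.frame.
#' @param category Optional single category to restrict to.
#' @param window Window in nt (default 1000).
#' @param signed Use signed distances instead of absolute (default FALSE).
#' @return data.frame `distance`, `cum_fraction` (monotone, reaching 1 at
#'   the largest in-window distance); attributes `n_within`, `n_outside`.
#'   Zero in-window tails give an empty frame with a warning.
#' @export
tes_distance_cdf <- function(tails, category = NULL, window = 1000,
                             signed = FALSE) {
  d <- tails$tes_distance
  if (!is.null(category)) d <- d[tails$category == category]
  d <- d[!is.na(d)]
  x <- if (signed) d else abs(d)
  within <- abs(d) <= window
  n_within <- sum(within)
  x <- sort(x[within])
  if (n_within == 0L) {
    warning("no tails within the TES window",
            if (!is.null(category)) paste0(" for category ", category))
    out <- data.frame(distance = numeric(), cum_fraction = numeric())
  } else {
    ux <- unique(x)
    out <- data.frame(
      distance = ux,
      cum_fraction = cumsum(tabulate(match(x, ux))) / n_within
    )
  }
  attr(out, "n_within") <- n_within
  attr(out, "n_outside") <- length(d) - n_within
  out
}

#' Histogram of terminal uridine run lengths
#'
#' Distribution of the number of uridines terminating poly(AU) tails; in
#' uridylated transcriptomes the mass sits on runs of one or two.
#'
#' @param tails Tail-call data.frame; only its poly(AU) rows are used.
#' @return data.frame `u_run`, `count` (counts sum to the poly(AU) subset
#'   size).
#' @export
u_run_histogram <- function(tails) {
  u <- tails$u_run[tails$category == "polyAU"]
  if (!length(u)) {
    return(data.frame(u_run = integer(), count = integer()))
  }
  tab <- table(u)
  data.frame(u_run = as.integer(names(tab)), count = as.integer(tab))
}

#' Per-gene tail count table across replicates
#'
#' Counts poly(A) and poly(AU) tails per assigned gene in each replicate,
#' sums across replicates, and keeps genes whose summed poly(A) + poly(AU)
#' count reaches `min_total` (default 5, the detection threshold under which
#' per-gene uridylation calls are unreliable at typical depth).
#'
#' @param assigned Named list of assigned tail-call data.frames, one per
#'   replicate (names become column prefixes).
#' @param min_total Minimum summed poly(A)+poly(AU) count (default 5; 0
#'   keeps every gene).
#' @param expression Optional data.frame `gene_id`, `count` of total reads
#'   per gene (any reads, tailed or not), merged as an `expression` column.
#' @return `utail_gene_table` data.frame: `gene_id`, one
#'   `<replicate>.polyA` and `<replicate>.polyAU` column per replicate,
#'   `total_polyA`, `total_polyAU`, `total_tailed`, `both_categories`,
#'   and `expression` when supplied.
#' @export
per_gene_table <- function(assigned, min_total = 5L, expression = NULL) {
  stopifnot(is.list(assigned), length(assigned) >= 1L)
  if (is.null(names(assigned)) || any(!nzchar(names(assigned)))) {
    names(assigned) <- paste0("rep", seq_along(assigned))
  }

  per_rep <- lapply(assigned, function(tl) {
    tl <- tl[!is.na(tl$feature_id) & tl$category %in% c("polyA", "polyAU"), ,
             drop = FALSE]
    tab <- table(tl$feature_id, factor(tl$category,
                                       levels = c("polyA", "polyAU")))
    df <- as.data.frame.matrix(tab)
    df$gene_id <- rownames(df)
    df
  })

  genes <- sort(unique(unlist(lapply(per_rep, `[[`, "gene_id"))))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (s in names(per_rep)) {
    m <- match(genes, per_rep[[s]]$gene_id)
    out[[paste0(s, ".polyA")]] <- ifelse(is.na(m), 0L,
                                         per_rep[[s]]$polyA[m])
    out[[paste0(s, ".polyAU")]] <- ifelse(is.na(m), 0L,
                                          per_rep[[s]]$polyAU[m])
  }
  pa_cols <- grep("\\.polyA$", names(out))
  pau_cols <- grep("\\.polyAU$", names(out))
  out$total_polyA <- as.integer(rowSums(out[, pa_cols, drop = FALSE]))
  out$total_polyAU <- as.integer(rowSums(out[, pau_cols, drop = FALSE]))
  out$total_tailed <- out$total_polyA + out$total_polyAU
  out$both_categories <- out$total_polyA > 0L & out$total_polyAU > 0L

  if (!is.null(expression)) {
    stopifnot(all(c("gene_id", "count") %in% names(expression)))
    out$expression <- expression$count[match(out$gene_id,
                                             expression$gene_id)]
  }

  out <- out[out$total_tailed >= min_total, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("utail_gene_table", "data.frame")
  out
}

#' Correlation between expression level and tailed-read count
#'
#' Pearson correlation between `log10(expression + 1)` and
#' `log10(poly(A)+poly(AU) count + 1)` across genes; tail detection tracks
#' transcript abundance, so this is expected to be strongly positive.
#'
#' @param gene_table [per_gene_table()] output with an `expression` column.
#' @return Pearson r, or `NA` with a warning when either variable has zero
#'   variance.
#' @export
expression_correlation <- function(gene_table) {
  if (!"expression" %in% names(gene_table)) {
    stop("gene table carries no expression column")
  }
  keep <- !is.na(gene_table$expression)
  if (sum(keep) < 3L) stop("need at least 3 genes with expression counts")
  x <- log10(gene_table$expression[keep] + 1)
  y <- log10(gene_table$total_tailed[keep] + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Pearson correlation matrix across samples and read classes
#'
#' Correlates per-gene count columns (replicate poly(A) / poly(AU) counts
#' and, when present, expression) across samples, after restricting to genes
#' complete in every selected column. Counts are `log10(x + 1)` transformed.
#'
#' @param gene_table [per_gene_table()] output (typically built with
#'   `min_total = 0` and filtered as needed).
#' @param columns Columns to correlate; default all per-replicate count
#'   columns.
#' @param log Apply `log10(x + 1)` first (default TRUE).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(gene_table, columns = NULL, log = TRUE) {
  if (is.null(columns)) {
    columns <- grep("\\.polyAU?$", names(gene_table), value = TRUE)
  }
  stopifnot(all(columns %in% names(gene_table)))
  m <- as.matrix(gene_table[, columns, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("fewer than 3 genes shared across the selected columns")
  }
  if (log) m <- log10(m + 1)
  cor(m)
}

#' Breakdown of assigned tails by feature biotype
#'
#' @param tails Assigned tail-call data.frame.
#' @return data.frame `biotype`, `count`, `fraction` over assigned tails;
#'   unassigned tails are reported in the `n_unassigned` attribute and
#'   excluded from the fractions.
#' @export
biotype_breakdown <- function(tails) {
  assigned <- tails[!is.na(tails$biotype), , drop = FALSE]
  tab <- table(assigned$biotype)
  out <- data.frame(
    biotype = factor(names(tab), levels = BIOTYPES),
    count = as.integer(tab)
  )
  out$fraction <- if (nrow(assigned)) out$count / nrow(assigned) else 0
  attr(out, "n_unassigned") <- nrow(tails) - nrow(assigned)
  out
}
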