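# write a TSV with "#"-prefixed provenance header lines (no timestamps, so
# identical inputs + config give byte-identical outputs)
write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# utail %s", as.character(packageVersion("utail"))),
             con)
  if (!is.null(params)) {
    writeLines(sprintf("# %s", paste(names(params), unlist(params),
                                     sep = "=", collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tail-call or assigned-tail TSV
#'
#' Reads tables written by the pipeline (or CLI), skipping `#` provenance
#' headers and restoring the category / biotype factor levels.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tail_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if ("category" %in% names(df)) {
    df$category <- factor(df$category, levels = TAIL_CATEGORIES)
  }
  if ("biotype" %in% names(df)) {
    df$biotype <- factor(df$biotype, levels = BIOTYPES)
  }
  df
}

#' Per-gene expression counts from alignments
#'
#' Counts, for every annotated feature, the primary mapped reads whose
#' aligned span overlaps it (strand-blind, like a plain overlap count).
#' Used as the expression covariate for [expression_correlation()].
#'
#' @param alignments `utail_alignments` object or records data.frame.
#' @param features `GRanges` from [load_annotation()].
#' @return data.frame `gene_id`, `count`.
#' @export
count_gene_expression <- function(alignments, features) {
  rec <- .alignment_records(alignments)
  span <- aligned_reference_span(rec$pos, rec$cigar)
  reads <- GenomicRanges::GRanges(
    rec$reference_name,
    IRanges::IRanges(span$first_ref_base, span$last_ref_base))
  feats_nostrand <- features
  GenomicRanges::strand(feats_nostrand) <- "*"
  suppressWarnings(
    counts <- GenomicRanges::countOverlaps(feats_nostrand, reads,
                                           ignore.strand = TRUE))
  data.frame(gene_id = features$feature_id, count = counts)
}

#' Default pipeline configuration
#'
#' @param samples Named list; each element is a list with `alignments`
#'   (SAM/BAM path), optional `strain` (defaults to the sample name) and
#'   optional `expression` (TSV `gene_id`, `count`; computed from the
#'   alignments when absent).
#' @param annotation Annotation path (GFF3 or BED).
#' @param out_dir Output directory.
#' @param baseline Baseline strain for the uridylation-loss comparison
#'   (optional).
#' @param ... Overrides for thresholds: `min_tail_len` (4), `min_anchor`
#'   (20), `max_distance` (1000), `same_strand` (TRUE), `dedup_fragments`
#'   (FALSE), `keep_duplicates` (TRUE), `min_mapq` (0), `min_total` (5),
#'   `freq_denominator` ("polyA+polyAU"), `tes_window` (1000).
#' @return `utail_config` list.
#' @export
pipeline_config <- function(samples, annotation, out_dir,
                            baseline = NULL, ...) {
  defaults <- list(
    min_tail_len = 4L, min_anchor = 20L, max_distance = 1000,
    same_strand = TRUE, dedup_fragments = FALSE, keep_duplicates = TRUE,
    min_mapq = 0L, min_total = 5L, freq_denominator = "polyA+polyAU",
    tes_window = 1000
  )
  cfg <- modifyList(defaults, list(...))
  cfg$samples <- samples
  cfg$annotation <- annotation
  cfg$out_dir <- out_dir
  cfg$baseline <- baseline
  structure(cfg, class = "utail_config")
}

#' Run the full uridylation-detection pipeline
#'
#' Chains alignment reading, tail extraction/classification, closest-feature
#' TES assignment and summarisation for one or more samples, writes all
#' stage outputs as provenance-headed TSVs plus a machine-readable
#' `summary.json`, and records a run manifest (tool version, configuration,
#' input checksums, per-stage tallies). Identical configuration and inputs
#' produce byte-identical tables.
#'
#' @param config [pipeline_config()] object.
#' @return Invisibly, a list with `out_dir`, per-sample `summaries`,
#'   `gene_tables` per strain, `strain_comparison` (or NULL) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "utail_config"))
  for (s in names(config$samples)) {
    p <- config$samples[[s]]$alignments
    if (is.null(p) || !file.exists(p)) {
      stop("configuration error: alignments for sample '", s,
           "' not found: ", p)
    }
  }
  if (!file.exists(config$annotation)) {
    stop("configuration error: annotation not found: ", config$annotation)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  features <- load_annotation(config$annotation)

  summaries <- list()
  assigned_all <- list()
  expr_all <- list()
  tallies <- list()
  freq_rows <- NULL

  for (s in names(config$samples)) {
    sm <- config$samples[[s]]
    aln <- read_alignments(sm$alignments,
                           keep_duplicates = config$keep_duplicates,
                           min_mapq = config$min_mapq)
    tails <- extract_tails(aln,
                           min_tail_len = config$min_tail_len,
                           min_anchor = config$min_anchor,
                           dedup_fragments = config$dedup_fragments)
    assigned <- assign_tails(tails, features,
                             same_strand = config$same_strand,
                             max_distance = config$max_distance)
    write_tsv(assigned, file.path(config$out_dir,
                                  paste0("assigned_", s, ".tsv")),
              params = list(sample = s,
                            min_tail_len = config$min_tail_len,
                            min_anchor = config$min_anchor,
                            max_distance = config$max_distance))

    total_aligned <- nrow(aln$records)
    summaries[[s]] <- category_fractions(assigned, total_aligned,
                                         sample_id = s)
    assigned_all[[s]] <- assigned
    expr_all[[s]] <- if (!is.null(sm$expression)) {
      utils::read.delim(sm$expression, stringsAsFactors = FALSE)
    } else {
      count_gene_expression(aln, features)
    }
    tallies[[s]] <- list(skipped = as.list(aln$skipped),
                         tails = as.list(attr(tails, "tallies")),
                         assignment = as.list(attr(assigned,
                                                   "assign_tallies")))
    ur <- uridylation_frequency(
      assigned, denominator = config$freq_denominator)
    strain <- if (!is.null(sm$strain)) sm$strain else s
    freq_rows <- rbind(freq_rows,
                       data.frame(sample_id = s, strain = strain,
                                  frequency = ur$frequency))
  }

  ## per-sample category fractions
  frac_df <- do.call(rbind, lapply(summaries, function(x) {
    data.frame(sample_id = x$sample_id, category = TAIL_CATEGORIES,
               count = unname(x$counts),
               fraction_of_tailed = unname(x$fraction_of_tailed),
               n_tailed = x$n_tailed, total_aligned = x$total_aligned,
               tailed_fraction = x$tailed_fraction)
  }))
  write_tsv(frac_df, file.path(config$out_dir, "category_fractions.tsv"))

  ## biotype breakdown
  bt_df <- do.call(rbind, lapply(names(assigned_all), function(s) {
    b <- biotype_breakdown(assigned_all[[s]])
    if (nrow(b)) cbind(sample_id = s, b) else NULL
  }))
  write_tsv(bt_df, file.path(config$out_dir, "biotype_breakdown.tsv"))

  ## TES-distance CDFs per category
  cdf_df <- do.call(rbind, unlist(recursive = FALSE, lapply(
    names(assigned_all), function(s) {
      lapply(TAIL_CATEGORIES, function(cc) {
        n_cat <- sum(assigned_all[[s]]$category == cc &
                     !is.na(assigned_all[[s]]$tes_distance))
        if (n_cat == 0L) return(NULL)
        cdf <- tes_distance_cdf(assigned_all[[s]], category = cc,
                                window = config$tes_window)
        if (!nrow(cdf)) return(NULL)
        cbind(sample_id = s, category = cc, cdf)
      })
    })))
  write_tsv(cdf_df, file.path(config$out_dir, "tes_distance_cdf.tsv"),
            params = list(window = config$tes_window))

  ## uridine-run histogram
  ur_df <- do.call(rbind, lapply(names(assigned_all), function(s) {
    h <- u_run_histogram(assigned_all[[s]])
    if (nrow(h)) cbind(sample_id = s, h) else NULL
  }))
  write_tsv(ur_df, file.path(config$out_dir, "u_run_histogram.tsv"))

  ## per-gene tables per strain (replicates summed within a strain)
  strains <- vapply(names(config$samples), function(s) {
    sm <- config$samples[[s]]
    if (!is.null(sm$strain)) sm$strain else s
  }, character(1))
  gene_tables <- list()
  gt_rows <- NULL
  for (st in unique(strains)) {
    reps <- names(config$samples)[strains == st]
    expr <- expr_all[[reps[1]]]
    if (length(reps) > 1L) {
      pooled <- Reduce(function(a, b) {
        m <- match(a$gene_id, b$gene_id)
        a$count <- a$count + ifelse(is.na(m), 0L, b$count[m])
        a
      }, expr_all[reps[-1]], expr)
      expr <- pooled
    }
    gt <- per_gene_table(assigned_all[reps], min_total = config$min_total,
                         expression = expr)
    gene_tables[[st]] <- gt
    if (nrow(gt)) gt_rows <- rbind(gt_rows, cbind(strain = st,
                                                  as.data.frame(gt)[
                                                    c("gene_id",
                                                      "total_polyA",
                                                      "total_polyAU",
                                                      "total_tailed",
                                                      "both_categories",
                                                      "expression")]))
  }
  if (!is.null(gt_rows)) {
    write_tsv(gt_rows, file.path(config$out_dir, "gene_tail_table.tsv"),
              params = list(min_total = config$min_total))
  }

  ## replicate correlations within strains (computed on unfiltered tables)
  cor_rows <- NULL
  for (st in unique(strains)) {
    reps <- names(config$samples)[strains == st]
    if (length(reps) < 2L) next
    gt0 <- per_gene_table(assigned_all[reps], min_total = 0L)
    cm <- tryCatch(correlation_matrix(gt0), error = function(e) NULL)
    if (is.null(cm)) next
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    cor_rows <- rbind(cor_rows, data.frame(
      strain = st, var1 = rownames(cm)[idx[, 1]],
      var2 = colnames(cm)[idx[, 2]], pearson_r = cm[idx]))
  }
  if (!is.null(cor_rows)) {
    write_tsv(cor_rows, file.path(config$out_dir, "correlations.tsv"))
  }

  ## strain comparison
  strain_comparison <- NULL
  if (!is.null(config$baseline) && !anyNA(freq_rows$frequency)) {
    strain_comparison <- strain_loss(freq_rows, config$baseline)
    write_tsv(strain_comparison,
              file.path(config$out_dir, "strain_comparison.tsv"),
              params = list(baseline = config$baseline,
                            denominator = config$freq_denominator))
  }

  summary_json <- list(
    samples = lapply(summaries, function(x) {
      list(sample_id = x$sample_id, total_aligned = x$total_aligned,
           counts = as.list(x$counts), n_tailed = x$n_tailed,
           tailed_fraction = x$tailed_fraction,
           uridylation = x$uridylation)
    }),
    strain_comparison = strain_comparison
  )
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  inputs <- c(config$annotation,
              vapply(config$samples, `[[`, character(1), "alignments"))
  manifest <- list(
    tool = "utail",
    version = as.character(packageVersion("utail")),
    config = unclass(config)[setdiff(names(config),
                                     c("samples", "out_dir"))],
    samples = lapply(config$samples, function(x) x["alignments"]),
    input_md5 = as.list(tools::md5sum(inputs)),
    tallies = tallies
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(out_dir = config$out_dir, summaries = summaries,
                 gene_tables = gene_tables,
                 strain_comparison = strain_comparison,
                 manifest = manifest))
}
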