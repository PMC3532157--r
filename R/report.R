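#' Assemble a run report
#'
#' Collects the pipeline outputs into one bundle of summary tables — a
#' per-replicate tag-accounting table with mapping rates, an optional
#' reference/assembly summary, the DE summary (optionally with annotation
#' categories), the fungal top-N abundance table, and coverage/gene-capture
#' percentages — and cross-checks internal consistency (QC count conservation,
#' partition sums), failing loudly on violation.
#'
#' @param qc_reports list of QC report rows ([filter_library()]), one per
#'   replicate.
#' @param mappings list of [map_library()] results in the same order.
#' @param de optional [de_scan()] result.
#' @param ranking optional [abundance_rank()] result.
#' @param categories optional [category_summary()] result.
#' @param reference_summary optional data.frame of assembly counts (free-form).
#' @param coverage optional named numeric, e.g. output of
#'   [coverage_estimate()] / [gene_capture()].
#' @return object of class `sage_report` (list of sections).
#' @export
build_report <- function(qc_reports, mappings, de = NULL, ranking = NULL,
                         categories = NULL, reference_summary = NULL,
                         coverage = NULL) {
  stopifnot(is.list(qc_reports), is.list(mappings),
            length(qc_reports) == length(mappings), length(qc_reports) > 0)
  rows <- vector("list", length(qc_reports))
  for (i in seq_along(qc_reports)) {
    qr <- qc_reports[[i]]; mp <- mappings[[i]]
    stopifnot(inherits(qr, "sage_qc_report"), inherits(mp, "sage_mapping"))
    if (qr$total != qr$with_anchor + qr$removed_no_anchor ||
        qr$with_anchor != qr$after_polyA + qr$removed_polyA) {
      stop("QC count conservation violated for ", qr$sample, " replicate ",
           qr$replicate, call. = FALSE)
    }
    if (!isTRUE(all.equal(sum(mp$tally), qr$after_polyA))) {
      stop("mapping partitions do not sum to the QC-passed total for ",
           qr$sample, " replicate ", qr$replicate, call. = FALSE)
    }
    rows[[i]] <- mapping_rates(mp, qr)
  }
  tag_table <- do.call(rbind, rows)

  de_summary <- NULL
  if (!is.null(de)) {
    stopifnot(inherits(de, "sage_de"))
    sig <- de[de$significant, ]
    de_summary <- list(
      n_tested = nrow(de),
      n_significant = nrow(sig),
      n_up = sum(sig$fold_change > 0, na.rm = TRUE),
      n_down = sum(sig$fold_change < 0, na.rm = TRUE),
      fold_range = if (nrow(sig)) range(sig$fold_change, na.rm = TRUE) else c(NA, NA),
      table = sig
    )
  }
  out <- list(
    tag_table = tag_table,
    reference_summary = reference_summary,
    de = de_summary,
    categories = categories,
    top_fungal = ranking,
    coverage = coverage
  )
  class(out) <- "sage_report"
  out
}

#' @export
print.sage_report <- function(x, ...) {
  cat("== Tag accounting and mapping rates ==\n")
  print(x$tag_table, row.names = FALSE)
  if (!is.null(x$reference_summary)) {
    cat("\n== Reference summary ==\n")
    print(x$reference_summary, row.names = FALSE)
  }
  if (!is.null(x$de)) {
    cat(sprintf("\n== Differential expression ==\n%d tags tested, %d significant (%d up, %d down), fold range %+.1f to %+.1f\n",
                x$de$n_tested, x$de$n_significant, x$de$n_up, x$de$n_down,
                x$de$fold_range[2], x$de$fold_range[1]))
  }
  if (!is.null(x$categories)) {
    cat("\n== DE tags by category ==\n")
    print(x$categories$table, row.names = FALSE)
    cat(sprintf("Totals: %d up, %d down, %d all\n",
                x$categories$totals["up"], x$categories$totals["down"],
                x$categories$totals["all"]))
  }
  if (!is.null(x$top_fungal)) {
    cat(sprintf("\n== Abundant fungal tags ==\n%d tags at/above threshold, summed share %.2f%%\n",
                x$top_fungal$n, x$top_fungal$share))
    print(head(x$top_fungal$ranking, 20), row.names = FALSE)
  }
  if (!is.null(x$coverage)) {
    cat("\n== Coverage ==\n")
    print(x$coverage)
  }
  invisible(x)
}

#' Write a run report as a TSV bundle plus a text summary
#'
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sage_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wt(report$tag_table, "tag_accounting.tsv")
  if (!is.null(report$reference_summary))
    wt(report$reference_summary, "reference_summary.tsv")
  if (!is.null(report$de)) wt(report$de$table, "de_significant.tsv")
  if (!is.null(report$categories))
    wt(report$categories$table, "de_categories.tsv")
  if (!is.null(report$top_fungal))
    wt(report$top_fungal$ranking, "fungal_abundance_rank.tsv")
  con <- file(file.path(dir, "summary.txt"), open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
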