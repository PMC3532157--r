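#' Map several replicate libraries against one reference
#'
#' Convenience wrapper: maps the union of distinct tags once (mapping is a
#' property of the tag sequence, not of the replicate), then tallies each
#' replicate separately.
#'
#' @param libs list of QC-passed [tag_library()] objects.
#' @param reference a [reference_set()] or [build_site_index()].
#' @param budget mismatch budget (default 2).
#' @return list with `mapping` (the union [map_library()] result) and
#'   `per_library` (list of per-replicate `sage_mapping` tallies).
#' @export
map_libraries <- function(libs, reference, budget = 2L) {
  stopifnot(is.list(libs), length(libs) > 0)
  index <- if (inherits(reference, "sage_site_index")) reference
           else build_site_index(reference)
  union_tags <- unique(unlist(lapply(libs, `[[`, "tag"), use.names = FALSE))
  union_lib <- tag_library(union_tags, sample = "union")
  mapping <- map_library(union_lib, index, budget)
  asn <- as.data.table(mapping$assignments)[, .(tag, partition)]
  per <- lapply(libs, function(l) {
    m <- merge(as.data.table(l)[, .(tag, count)], asn, by = "tag")
    tal <- m[, .(n = sum(count)), by = partition]
    tally <- c(plant_mapped = 0, fungal_mapped = 0, ambiguous = 0, unmapped = 0)
    lab <- c(plant = "plant_mapped", fungal = "fungal_mapped",
             ambiguous = "ambiguous", unmapped = "unmapped")
    tally[lab[tal$partition]] <- tal$n
    out <- list(hits = mapping$hits, assignments = mapping$assignments,
                tally = tally, budget = budget)
    class(out) <- "sage_mapping"
    out
  })
  list(mapping = mapping, per_library = per)
}

#' Run the full tag pipeline on raw replicate libraries
#'
#' QC-filters each library, maps all distinct tags against the two-part
#' reference, assembles the expression matrix, scans for plant differential
#' expression, ranks abundant fungal tags, and pairs antisense transcripts.
#'
#' @param raw_libs list of raw [tag_library()] objects (one per replicate,
#'   with `sample`/`replicate` attributes; two samples expected for DE).
#' @param refset a [reference_set()] spanning both origins.
#' @param budget mismatch budget (default 2).
#' @param alpha DE significance level (default 0.05).
#' @param abundance_threshold fungal abundance threshold in percent of mapped
#'   (default 0.01).
#' @return list with `qc` (list of QC reports), `filtered` (QC-passed
#'   libraries), `mapping`, `per_library_mapping`, `expr`, `de`, `ranking`,
#'   `antisense`, `report`.
#' @export
run_sage_pipeline <- function(raw_libs, refset, budget = 2L, alpha = 0.05,
                              abundance_threshold = 0.01) {
  stopifnot(is.list(raw_libs), length(raw_libs) >= 2)
  qc <- lapply(raw_libs, filter_library)
  filtered <- lapply(qc, `[[`, "library")
  reports <- lapply(qc, `[[`, "report")
  mp <- map_libraries(filtered, refset, budget)
  expr <- expression_matrix(filtered, mp$mapping)
  de <- de_scan(expr, alpha = alpha)
  has_fungal <- any(expr$tags$origin == "fungal")
  ranking <- if (has_fungal) abundance_rank(expr, abundance_threshold) else NULL
  anti <- if (has_fungal) pair_antisense(mp$mapping, expr) else NULL
  report <- build_report(reports, mp$per_library, de = de, ranking = ranking)
  list(qc = reports, filtered = filtered, mapping = mp$mapping,
       per_library_mapping = mp$per_library, expr = expr, de = de,
       ranking = ranking, antisense = anti, report = report)
}
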