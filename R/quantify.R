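#' Tags per million mapped tags
#'
#' Simple library-size scaling of a raw tag count, the normalization used for
#' host-plant tags. (This is per-million scaling, not the trimmed-mean-of-M-
#' values normalization that shares the "TMM" acronym in count-based DE
#' packages.)
#'
#' @param count raw tag count(s).
#' @param mapped_total total mapped tags in the same library and partition.
#' @return `1e6 * count / mapped_total`.
#' @export
normalize_tpm <- function(count, mapped_total) {
  if (any(mapped_total <= 0)) stop("mapped_total must be positive", call. = FALSE)
  1e6 * count / mapped_total
}

#' Percent of mapped tags
#'
#' Normalization used for fungal tags: raw count as a percentage of all mapped
#' tags of the same partition in that library.
#'
#' @param count raw tag count(s).
#' @param partition_total total mapped tags of the partition in that library.
#' @return `100 * count / partition_total`.
#' @export
percent_of_mapped <- function(count, partition_total) {
  if (any(partition_total <= 0)) {
    stop("partition_total must be positive", call. = FALSE)
  }
  100 * count / partition_total
}

#' Assemble an expression matrix from mapped replicate libraries
#'
#' Builds the tags-by-replicates count matrix over all plant- and
#' fungal-assigned distinct tags, plus the normalized matrix: tags per million
#' plant-mapped tags for plant tags, percent of fungal-mapped tags for fungal
#' tags. Ambiguous and unmapped tags are excluded from both partitions and
#' from both denominators.
#'
#' @param libs list of QC-passed [tag_library()] objects (one per replicate,
#'   with `sample`/`replicate` attributes).
#' @param mapping a [map_library()] result covering the union of distinct tags
#'   in `libs` (see [map_libraries()] for a convenience wrapper).
#' @return object of class `sage_expr`: list with
#'   \describe{
#'     \item{counts}{numeric matrix, tags x replicate columns}
#'     \item{norm}{matching matrix of normalized values (TMM or percent)}
#'     \item{tags}{data.frame `tag`, `origin` (partition of each row)}
#'     \item{samples}{data.frame per column: `column`, `sample`, `replicate`,
#'       `plant_total`, `fungal_total`}
#'   }
#' @export
expression_matrix <- function(libs, mapping) {
  stopifnot(is.list(libs), length(libs) > 0,
            all(vapply(libs, inherits, logical(1), "sage_library")),
            inherits(mapping, "sage_mapping"))
  asn <- as.data.table(mapping$assignments)[partition %in% c("plant", "fungal")]
  if (nrow(asn) == 0L) stop("no mapped tags to quantify", call. = FALSE)
  tags <- asn$tag
  cols <- vapply(libs, function(l) {
    paste0(attr(l, "sample"), "_", attr(l, "replicate"))
  }, character(1))
  if (anyDuplicated(cols)) stop("duplicate sample/replicate labels", call. = FALSE)
  counts <- matrix(0, nrow = length(tags), ncol = length(libs),
                   dimnames = list(tags, cols))
  for (j in seq_along(libs)) {
    i <- match(libs[[j]]$tag, tags)
    ok <- !is.na(i)
    counts[i[ok], j] <- libs[[j]]$count[ok]
  }
  is_plant <- asn$partition == "plant"
  plant_total <- colSums(counts[is_plant, , drop = FALSE])
  fungal_total <- colSums(counts[!is_plant, , drop = FALSE])
  norm <- counts
  for (j in seq_along(libs)) {
    if (any(is_plant)) {
      norm[is_plant, j] <- if (plant_total[j] > 0)
        normalize_tpm(counts[is_plant, j], plant_total[j]) else NA_real_
    }
    if (any(!is_plant)) {
      norm[!is_plant, j] <- if (fungal_total[j] > 0)
        percent_of_mapped(counts[!is_plant, j], fungal_total[j]) else NA_real_
    }
  }
  out <- list(
    counts = counts,
    norm = norm,
    tags = data.frame(tag = tags, origin = asn$partition,
                      stringsAsFactors = FALSE),
    samples = data.frame(
      column = cols,
      sample = vapply(libs, function(l) attr(l, "sample"), character(1)),
      replicate = vapply(libs, function(l) attr(l, "replicate"), integer(1)),
      plant_total = unname(plant_total),
      fungal_total = unname(fungal_total),
      stringsAsFactors = FALSE
    )
  )
  class(out) <- "sage_expr"
  out
}

#' @export
print.sage_expr <- function(x, ...) {
  cat("<sage_expr> ", nrow(x$counts), " tags x ", ncol(x$counts),
      " replicates (", sum(x$tags$origin == "plant"), " plant, ",
      sum(x$tags$origin == "fungal"), " fungal)\n", sep = "")
  invisible(x)
}

#' Unpaired two-sample t-test on replicate values
#'
#' Two-sided pooled-variance Student's t (df = nA + nB - 2), the convention of
#' the classic GraphPad-style unpaired t-test at n = 3 + 3. Degenerate inputs
#' (zero variance in both groups) return t = 0, p = 1 for equal means, and
#' t = Inf, p = 0 flagged degenerate for unequal means.
#'
#' @param group_a,group_b numeric vectors of normalized values (>= 2 each).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
unpaired_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, p = 1, df = length(group_a) + length(group_b) - 2L,
                  degenerate = FALSE))
    }
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)), p = 0,
                df = length(group_a) + length(group_b) - 2L, degenerate = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Signed fold change between group means
#'
#' Convention: positive when the treated (infected, E+) mean is at least the
#' control (uninfected, E-) mean, `+mean_trt/mean_ctrl`; negative otherwise,
#' `-mean_ctrl/mean_trt`. A zero mean on one side is replaced by `pseudo`
#' (typically half the smallest nonzero normalized value in the matrix) so the
#' ratio stays finite; such values should be flagged by callers.
#'
#' @param mean_ctrl,mean_trt group mean normalized values.
#' @param pseudo substitute for a zero mean (default `NA`: zero means give
#'   `NA`).
#' @return signed ratio (magnitude >= 1), or `NA` when undefined.
#' @export
#' @examples
#' fold_change(10, 74)  # +7.4
#' fold_change(72, 10)  # -7.2
fold_change <- function(mean_ctrl, mean_trt, pseudo = NA_real_) {
  n <- max(length(mean_ctrl), length(mean_trt))
  mean_ctrl <- rep_len(mean_ctrl, n); mean_trt <- rep_len(mean_trt, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- mean_ctrl[i]; b <- mean_trt[i]
    if (a == 0 && b == 0) { out[i] <- NA_real_; next }
    if (a == 0) a <- pseudo
    if (b == 0) b <- pseudo
    if (is.na(a) || is.na(b)) { out[i] <- NA_real_; next }
    out[i] <- if (b >= a) b / a else -a / b
  }
  out
}

#' Differential-expression scan across biological replicates
#'
#' Runs the unpaired pooled-variance t-test on the normalized values of every
#' plant tag, comparing the two samples, and reports group means, signed fold
#' change, t statistic and p-value, sorted by p. Significance is the raw
#' p < alpha with no multiple-testing correction by default (set `correct` to
#' a [stats::p.adjust()] method to adjust instead).
#'
#' @param expr a [expression_matrix()].
#' @param control,treatment sample labels of the two groups (defaults: the
#'   first and second distinct sample in `expr`).
#' @param alpha significance level (default 0.05).
#' @param correct multiple-testing correction method, `"none"` (default) or
#'   any method of [stats::p.adjust()].
#' @param origin which partition to test (default `"plant"`).
#' @return data.frame of class `sage_de`: `tag`, `mean_ctrl`, `mean_trt`,
#'   `fold_change`, `t`, `p`, `significant`, `degenerate`, `zero_floored`.
#' @export
de_scan <- function(expr, control = NULL, treatment = NULL, alpha = 0.05,
                    correct = "none", origin = "plant") {
  stopifnot(inherits(expr, "sage_expr"))
  samples <- unique(expr$samples$sample)
  if (is.null(control)) control <- samples[1L]
  if (is.null(treatment)) treatment <- samples[2L]
  stopifnot(control %in% samples, treatment %in% samples, control != treatment)
  ca <- expr$samples$sample == control
  cb <- expr$samples$sample == treatment
  if (sum(ca) < 2 || sum(cb) < 2) {
    stop("each sample needs >= 2 replicates", call. = FALSE)
  }
  rows <- which(expr$tags$origin == origin)
  m <- expr$norm[rows, , drop = FALSE]
  pseudo <- {
    nz <- m[m > 0 & !is.na(m)]
    if (length(nz)) min(nz) / 2 else NA_real_
  }
  res <- lapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ca]; b <- m[i, cb]
    tt <- unpaired_t(a, b)
    c(mean_ctrl = mean(a), mean_trt = mean(b), t = tt$t, p = tt$p,
      degenerate = as.numeric(tt$degenerate))
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    tag = expr$tags$tag[rows],
    mean_ctrl = res[, "mean_ctrl"],
    mean_trt = res[, "mean_trt"],
    fold_change = fold_change(res[, "mean_ctrl"], res[, "mean_trt"], pseudo),
    t = res[, "t"],
    p = res[, "p"],
    degenerate = res[, "degenerate"] > 0,
    zero_floored = (res[, "mean_ctrl"] == 0) != (res[, "mean_trt"] == 0),
    stringsAsFactors = FALSE
  )
  out$p_used <- if (identical(correct, "none")) out$p else p.adjust(out$p, correct)
  out$significant <- !is.na(out$p_used) & out$p_used < alpha
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "control") <- control
  attr(out, "treatment") <- treatment
  class(out) <- c("sage_de", "data.frame")
  out
}

#' Rank abundant fungal tags
#'
#' Ranks tags by mean percent-of-mapped abundance and keeps those at or above
#' an abundance threshold (the "abundant" designation; default 0.01 percent of
#' fungal mapped tags).
#'
#' @param mean_percent named numeric vector of mean percent-of-mapped values
#'   (names are tags or transcript labels), or a `sage_expr` from which fungal
#'   means are taken over all replicates with fungal counts.
#' @param threshold minimum mean percent to be included (default 0.01).
#' @return list with `ranking` (data.frame `rank`, `tag`, `mean_percent`,
#'   descending), `n` (number of abundant tags), `share` (their summed percent
#'   of all mapped fungal tags).
#' @export
abundance_rank <- function(mean_percent, threshold = 0.01) {
  if (inherits(mean_percent, "sage_expr")) {
    expr <- mean_percent
    rows <- expr$tags$origin == "fungal"
    use <- expr$samples$fungal_total > 0
    if (!any(rows) || !any(use)) stop("no fungal tags present", call. = FALSE)
    mean_percent <- rowMeans(expr$norm[rows, use, drop = FALSE])
    names(mean_percent) <- expr$tags$tag[rows]
  }
  keep <- mean_percent >= threshold
  v <- sort(mean_percent[keep], decreasing = TRUE)
  list(
    ranking = data.frame(rank = seq_along(v), tag = names(v),
                         mean_percent = unname(v), stringsAsFactors = FALSE),
    n = length(v),
    share = sum(v)
  )
}

#' Cumulative share of the top-k ranked tags
#' @param ranking result of [abundance_rank()].
#' @param k number of top tags.
#' @return summed mean percent of the top `k` tags.
#' @export
top_share <- function(ranking, k = 5L) {
  df <- ranking$ranking
  sum(df$mean_percent[seq_len(min(k, nrow(df)))])
}

#' Fraction of genes captured by unique tags
#'
#' @param unique_tags number of distinct mapped tags.
#' @param gene_count estimated number of genes in the genome.
#' @return rounded percentage.
#' @export
#' @examples
#' gene_capture(6298, 9440) # 67
gene_capture <- function(unique_tags, gene_count) {
  stopifnot(gene_count > 0)
  round_half_away(100 * unique_tags / gene_count)
}

#' Crude gene-content estimate for a polyploid
#'
#' @param base_genes gene count of a related diploid.
#' @param ploidy_factor multiple of the base genome (3 for a hexaploid).
#' @return estimated gene content.
#' @export
estimate_gene_content <- function(base_genes, ploidy_factor) {
  stopifnot(base_genes > 0, ploidy_factor > 0)
  base_genes * ploidy_factor
}

#' Transcriptome coverage of an assembly
#'
#' @param unigenes assembled unigene count.
#' @param base_genes,ploidy_factor see [estimate_gene_content()].
#' @return rounded percent of the estimated gene content covered.
#' @export
#' @examples
#' coverage_estimate(68817, 41000, 3) # 56
coverage_estimate <- function(unigenes, base_genes, ploidy_factor) {
  stopifnot(unigenes > 0)
  round_half_away(100 * unigenes / estimate_gene_content(base_genes, ploidy_factor))
}

#' Summarize differentially expressed tags by annotation category
#'
#' Counts tags per (category, direction) and expresses each as a percent of
#' that direction's total, rounded half away from zero to integer percent.
#' Unlabeled tags (`NA` or empty category) are counted under `"no match"`.
#'
#' @param labels data.frame with columns `category` and `direction`
#'   (`"up"`/`"down"`), one row per differentially expressed tag.
#' @return list with `table` (data.frame `category`, `up_n`, `up_pct`,
#'   `down_n`, `down_pct`) and `totals` (named vector `up`, `down`, `all`).
#' @export
category_summary <- function(labels) {
  stopifnot(is.data.frame(labels),
            all(c("category", "direction") %in% names(labels)))
  dir <- as.character(labels$direction)
  if (!all(dir %in% c("up", "down"))) {
    stop('direction must be "up" or "down"', call. = FALSE)
  }
  cat_ <- as.character(labels$category)
  cat_[is.na(cat_) | !nzchar(cat_)] <- "no match"
  tot_up <- sum(dir == "up"); tot_down <- sum(dir == "down")
  cats <- sort(unique(cat_))
  up_n <- vapply(cats, function(cc) sum(cat_ == cc & dir == "up"), numeric(1))
  down_n <- vapply(cats, function(cc) sum(cat_ == cc & dir == "down"), numeric(1))
  tab <- data.frame(
    category = cats,
    up_n = up_n,
    up_pct = if (tot_up > 0) round_half_away(100 * up_n / tot_up) else 0,
    down_n = down_n,
    down_pct = if (tot_down > 0) round_half_away(100 * down_n / tot_down) else 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(table = tab,
       totals = c(up = tot_up, down = tot_down, all = tot_up + tot_down))
}
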