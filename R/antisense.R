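# Antisense transcription is detected from tag directionality: a tag mapping
# to the reverse complement of an oriented reference at a CATG-anchored site
# is evidence of an antisense transcript. The antisense tag need not be the
# reverse complement of the sense canonical tag - sense and antisense strands
# generally anchor at different CATG sites - so pairing is per transcript.

#' Sense:antisense abundance ratio
#'
#' Expresses an antisense abundance relative to the matching sense abundance
#' as 1:N with N rounded half away from zero. Scale-invariant: both abundances
#' may be on any common scale (percent of mapped, TMM).
#'
#' @param sense,antisense abundances on a common scale; `antisense` must be
#'   positive.
#' @return integer N such that the ratio reads "1:N".
#' @export
#' @examples
#' sense_antisense_ratio(10.12, 1.17) # 9
#' sense_antisense_ratio(2.60, 0.03)  # 87
sense_antisense_ratio <- function(sense, antisense) {
  if (any(antisense <= 0)) stop("antisense abundance must be positive",
                                call. = FALSE)
  as.integer(round_half_away(sense / antisense))
}

#' Format a sense:antisense ratio as "1:N"
#' @inheritParams sense_antisense_ratio
#' @return character, e.g. `"1:9"`.
#' @export
format_ratio <- function(sense, antisense) {
  paste0("1:", sense_antisense_ratio(sense, antisense))
}

#' Pair sense and antisense tags per transcript
#'
#' For every oriented transcript with at least one antisense-mapping tag,
#' aggregates the mean normalized abundance (across replicates) of its sense
#' tags and of its antisense tags and computes the 1:N ratio. Transcripts with
#' antisense signal but no sense tag are emitted flagged `antisense_only`.
#' Tags with several best hits contribute their full abundance to each hit
#' transcript (a tag keeps one count; it is annotated with all best hits).
#'
#' @param mapping a [map_library()] result (strand recorded per hit).
#' @param expr the matching [expression_matrix()].
#' @param origin partition to scan (default `"fungal"`).
#' @param columns which replicate columns to average over; default: all
#'   columns with nonzero mapped total for `origin`.
#' @return data.frame of class `sage_antisense`: `transcript_id`,
#'   `sense_abundance`, `antisense_abundance`, `ratio_n`, `ratio`,
#'   `antisense_only`, sorted by antisense abundance.
#' @export
pair_antisense <- function(mapping, expr, origin = "fungal", columns = NULL) {
  stopifnot(inherits(mapping, "sage_mapping"), inherits(expr, "sage_expr"))
  if (is.null(columns)) {
    tot <- if (origin == "fungal") expr$samples$fungal_total
           else expr$samples$plant_total
    columns <- expr$samples$column[tot > 0]
  }
  stopifnot(length(columns) > 0, all(columns %in% colnames(expr$norm)))
  rows <- expr$tags$origin == origin
  abund <- rowMeans(expr$norm[rows, columns, drop = FALSE])
  names(abund) <- expr$tags$tag[rows]

  org <- origin
  hits <- as.data.table(mapping$hits)[origin == org &
                                        strand %in% c("sense", "antisense")]
  hits <- hits[tag %in% names(abund)]
  if (nrow(hits) == 0L) {
    out <- data.frame(transcript_id = character(0), sense_abundance = numeric(0),
                      antisense_abundance = numeric(0), ratio_n = integer(0),
                      ratio = character(0), antisense_only = logical(0))
    class(out) <- c("sage_antisense", "data.frame")
    return(out)
  }
  hits[, abundance := abund[tag]]
  per <- hits[, .(
    sense_abundance = sum(abundance[strand == "sense"]),
    antisense_abundance = sum(abundance[strand == "antisense"])
  ), by = transcript_id]
  per <- per[antisense_abundance > 0]
  per[, antisense_only := sense_abundance == 0]
  per[, ratio_n := ifelse(antisense_only, NA_integer_,
                          sense_antisense_ratio(pmax(sense_abundance, .Machine$double.eps),
                                                antisense_abundance))]
  per[, ratio := ifelse(antisense_only, NA_character_,
                        paste0("1:", ratio_n))]
  setorder(per, -antisense_abundance)
  out <- as.data.frame(per[, .(transcript_id, sense_abundance,
                               antisense_abundance, ratio_n, ratio,
                               antisense_only)])
  class(out) <- c("sage_antisense", "data.frame")
  out
}
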