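#' Construct a raw tag library
#'
#' A tag library is the multiset of 27-base tags sequenced from one biological
#' replicate, stored as (tag, count) pairs.
#'
#' @param tags character vector of 27-base tag sequences (need not be unique;
#'   duplicates are aggregated).
#' @param counts integer counts per tag (default 1 each).
#' @param sample sample label (e.g. `"Eminus"` / `"Eplus"`).
#' @param replicate replicate number (integer >= 1).
#' @return object of class `sage_library`: data.frame with columns `tag`,
#'   `count` and attributes `sample`, `replicate`.
#' @export
tag_library <- function(tags, counts = NULL, sample = "sample", replicate = 1L) {
  stopifnot(is.character(tags))
  if (is.null(counts)) counts <- rep(1L, length(tags))
  stopifnot(length(counts) == length(tags), all(counts >= 1))
  if (length(tags)) {
    if (any(nchar(tags) != .TAG_LEN)) {
      stop("all tags must be ", .TAG_LEN, " bases long", call. = FALSE)
    }
    .check_nucleotides(tags, what = "tags")
  }
  dt <- data.table(tag = tags, count = as.numeric(counts))
  dt <- dt[, .(count = sum(count)), by = tag]
  out <- as.data.frame(dt)
  attr(out, "sample") <- sample
  attr(out, "replicate") <- as.integer(replicate)
  class(out) <- c("sage_library", "data.frame")
  out
}

#' Read a tag library from disk
#'
#' Accepts either a two-column TSV (`tag`, `count`, with or without a header)
#' or plain text with one tag per line.
#'
#' @param path input file.
#' @inheritParams tag_library
#' @return a [tag_library()].
#' @export
read_tag_library <- function(path, sample = "sample", replicate = 1L) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty tag library file: ", path, call. = FALSE)
  has_header <- grepl("^tag\\b", first)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    tag_library(df[[1]], sample = sample, replicate = replicate)
  } else {
    tag_library(df[[1]], df[[2]], sample = sample, replicate = replicate)
  }
}

#' Write a tag library to TSV
#' @param lib a `sage_library`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tag_library <- function(lib, path) {
  write.table(as.data.frame(lib)[, c("tag", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Anchor filter: does a tag begin with the NlaIII site?
#'
#' Tags lacking CATG at the 5' end arise from random ligation of adaptors to
#' cDNA and cannot be used quantitatively. The test is a strict prefix test;
#' a CATG elsewhere in the tag does not count.
#'
#' @param tag character vector of 27-base tags.
#' @return logical vector.
#' @export
has_anchor <- function(tag) {
  if (length(tag) && any(nchar(tag) != .TAG_LEN)) {
    stop("tags must be ", .TAG_LEN, " bases long", call. = FALSE)
  }
  startsWith(tag, .ANCHOR)
}

#' Length of the terminal run of A at the 3' end of a tag
#'
#' Tags whose anchor lies close to the transcript end read into the poly(A)
#' tail; since template A's cannot be distinguished from poly(A) A's, tags with
#' a long terminal A run are removed. This measures the maximal terminal
#' homopolymer run of `A`.
#'
#' @param tag character vector of 27-base tags.
#' @return integer vector of run lengths (0 if the tag does not end in A).
#' @export
trailing_a_run <- function(tag) {
  if (length(tag) == 0L) return(integer(0))
  if (any(nchar(tag) != .TAG_LEN)) {
    stop("tags must be ", .TAG_LEN, " bases long", call. = FALSE)
  }
  m <- regexpr("A+$", tag)
  ifelse(m == -1L, 0L, attr(m, "match.length"))
}

#' Apply both quality filters to a tag library
#'
#' Keeps tags that (a) begin with the CATG anchor and (b) have at most 10
#' terminal A's ("greater than 10 A's" are removed as putative poly(A) runoff).
#' Tags containing N fail the anchor step. The surviving tags are the
#' "potential mappable" tags.
#'
#' @param lib a [tag_library()].
#' @param max_trailing_a maximum allowed terminal A run (default 10).
#' @return list with
#'   \describe{
#'     \item{library}{the filtered `sage_library`}
#'     \item{report}{one-row data.frame of class `sage_qc_report` with columns
#'       `sample`, `replicate`, `total`, `with_anchor`, `after_polyA`,
#'       `removed_no_anchor`, `removed_polyA`; satisfies
#'       `total == with_anchor + removed_no_anchor` and
#'       `with_anchor == after_polyA + removed_polyA`.}
#'   }
#' @export
filter_library <- function(lib, max_trailing_a = 10L) {
  stopifnot(inherits(lib, "sage_library"))
  n_total <- sum(lib$count)
  anchored <- has_anchor(lib$tag) & !grepl("N", lib$tag, fixed = TRUE)
  n_anchor <- sum(lib$count[anchored])
  keep <- anchored & trailing_a_run(lib$tag) <= max_trailing_a
  n_pass <- sum(lib$count[keep])
  out <- lib[keep, , drop = FALSE]
  attr(out, "sample") <- attr(lib, "sample")
  attr(out, "replicate") <- attr(lib, "replicate")
  class(out) <- c("sage_library", "data.frame")
  report <- data.frame(
    sample = attr(lib, "sample") %||% NA_character_,
    replicate = attr(lib, "replicate") %||% NA_integer_,
    total = n_total,
    with_anchor = n_anchor,
    after_polyA = n_pass,
    removed_no_anchor = n_total - n_anchor,
    removed_polyA = n_anchor - n_pass,
    stringsAsFactors = FALSE
  )
  class(report) <- c("sage_qc_report", "data.frame")
  list(library = out, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mapped tags as a percentage of potential mappable tags
#'
#' @param mapped_count tags that mapped to one partition of the reference.
#' @param potential_mappable tags surviving both QC filters.
#' @param digits decimal places for the report convention: 0 for host-plant
#'   percentages, 1 for fungal percentages.
#' @return percentage, rounded half away from zero.
#' @export
#' @examples
#' mapped_fraction(4346031, 7194891)        # 60
#' mapped_fraction(43199, 3041847, digits = 1) # 1.4
mapped_fraction <- function(mapped_count, potential_mappable, digits = 0) {
  if (any(potential_mappable <= 0)) {
    stop("potential_mappable must be positive", call. = FALSE)
  }
  round_half_away(100 * mapped_count / potential_mappable, digits)
}
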