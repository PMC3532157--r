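# SAGE tag geometry: the anchoring enzyme NlaIII cuts at CATG and the tagging
# enzyme releases a fixed-length fragment, giving 27-base tags of the form
# CATG + 23 downstream bases, taken from the most 3' eligible site.
.ANCHOR <- "CATG"
.TAG_LEN <- 27L
.DOWNSTREAM <- .TAG_LEN - nchar(.ANCHOR) # 23

#' Construct a reference transcript set
#'
#' A reference set holds oriented transcript sequences from one or both of the
#' two organisms in a mixed sample (host plant and fungal symbiont). The two
#' origins together form the two-part mapping database used to partition tags.
#'
#' @param ids character vector of unique transcript identifiers.
#' @param seqs character vector of nucleotide sequences (A/C/G/T/N; lower case
#'   and U are normalized).
#' @param origin `"plant"` or `"fungal"`, recycled to `length(ids)`.
#' @param oriented logical; whether sequences are in known 5'->3' mRNA
#'   orientation (required for antisense calls). Recycled.
#' @param provenance optional free-text note on where the sequences came from.
#' @return an object of class `sage_refset`: a data.frame with columns
#'   `transcript_id`, `seq`, `origin`, `oriented`.
#' @seealso [read_reference_fasta()], [digest_reference()]
#' @export
reference_set <- function(ids, seqs, origin = c("plant", "fungal"),
                          oriented = TRUE, provenance = NULL) {
  origin <- match.arg(origin, c("plant", "fungal"), several.ok = TRUE)
  stopifnot(length(ids) == length(seqs), length(seqs) > 0)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ", paste(ids[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  }
  .check_nucleotides(seqs, ids)
  out <- data.frame(
    transcript_id = as.character(ids),
    seq = seqs,
    origin = rep_len(origin, length(ids)),
    oriented = rep_len(oriented, length(ids)),
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("sage_refset", "data.frame")
  out
}

#' Load reference transcripts from a FASTA file
#'
#' @param path path to a (multi-)FASTA file of nucleotide sequences.
#' @param origin organism partition of all records in this file: `"plant"`
#'   or `"fungal"`.
#' @param oriented logical; whether records are oriented mRNA sequences.
#' @return a [reference_set()] with one transcript per FASTA record.
#' @export
read_reference_fasta <- function(path, origin = c("plant", "fungal"),
                                 oriented = TRUE) {
  origin <- match.arg(origin)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss)) # first token of header
  reference_set(ids, as.character(ss), origin = origin, oriented = oriented,
                provenance = path)
}

#' Combine plant and fungal reference sets
#'
#' @param ... `sage_refset` objects (typically one plant, one fungal).
#' @return a single `sage_refset` spanning both origins.
#' @export
combine_references <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "sage_refset")))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  reference_set(df$transcript_id, df$seq, origin = df$origin,
                oriented = df$oriented,
                provenance = paste(unlist(lapply(parts, attr, "provenance")),
                                   collapse = "; "))
}

#' @export
print.sage_refset <- function(x, ...) {
  tab <- table(x$origin)
  cat("<sage_refset> ", nrow(x), " transcripts (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# 1-based start positions of eligible anchors: CATG occurrences followed by at
# least 23 bases, skipping windows that contain N (ambiguity codes cannot be
# part of an observed tag)
.eligible_anchors <- function(seq) {
  hits <- gregexpr(.ANCHOR, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  pos <- as.integer(hits)
  pos <- pos[pos + .TAG_LEN - 1L <= nchar(seq)]
  if (length(pos) == 0L) return(integer(0))
  windows <- substring(seq, pos, pos + .TAG_LEN - 1L)
  pos[!grepl("N", windows, fixed = TRUE)]
}

#' Extract the canonical tag of a transcript
#'
#' The canonical tag is the 27-mer starting at the most 3' CATG that has at
#' least 23 bases downstream. If the most 3' CATG is too close to the end
#' (truncated reference) or its window contains an N, the next eligible CATG
#' upstream is used. Returns `NULL` when no eligible site exists.
#'
#' @param seq a single nucleotide sequence (character scalar).
#' @return `NULL`, or a list with `tag_seq` (27-base string beginning with
#'   CATG) and `tag_start` (0-based offset of the anchor on the transcript).
#' @export
#' @examples
#' extract_tag(paste0("AA", "CATG", strrep("T", 23)))
extract_tag <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  pos <- .eligible_anchors(seq)
  if (length(pos) == 0L) return(NULL)
  p <- max(pos)
  list(tag_seq = substr(seq, p, p + .TAG_LEN - 1L), tag_start = p - 1L)
}

#' In-silico NlaIII digest of a reference set
#'
#' Computes the canonical 27-bp tag of every transcript. Transcripts with no
#' eligible CATG site cannot be represented among SAGE tags and are listed
#' separately.
#'
#' @param refset a [reference_set()].
#' @return an object of class `sage_catalog`: list with
#'   \describe{
#'     \item{catalog}{data.frame `transcript_id`, `origin`, `tag_seq`,
#'       `tag_start` (0-based anchor offset)}
#'     \item{tagless}{character vector of transcript ids with no eligible tag}
#'     \item{tagless_fraction}{proportion of transcripts without a tag}
#'   }
#' @export
digest_reference <- function(refset) {
  stopifnot(inherits(refset, "sage_refset"), nrow(refset) > 0)
  tags <- lapply(refset$seq, extract_tag)
  ok <- !vapply(tags, is.null, logical(1))
  catalog <- data.frame(
    transcript_id = refset$transcript_id[ok],
    origin = refset$origin[ok],
    tag_seq = vapply(tags[ok], `[[`, character(1), "tag_seq"),
    tag_start = vapply(tags[ok], `[[`, integer(1), "tag_start"),
    stringsAsFactors = FALSE
  )
  out <- list(
    catalog = catalog,
    tagless = refset$transcript_id[!ok],
    tagless_fraction = mean(!ok)
  )
  class(out) <- "sage_catalog"
  out
}

#' @export
print.sage_catalog <- function(x, ...) {
  cat("<sage_catalog> ", nrow(x$catalog), " canonical tags; ",
      length(x$tagless), " tagless transcripts (",
      sprintf("%.1f%%", 100 * x$tagless_fraction), ")\n", sep = "")
  invisible(x)
}

#' Write a tag catalog to TSV
#'
#' Coordinates are emitted 1-based for human consumption.
#'
#' @param x a `sage_catalog`.
#' @param path output file for the catalog.
#' @param tagless_path optional output file listing tagless transcript ids.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(x, path, tagless_path = NULL) {
  stopifnot(inherits(x, "sage_catalog"))
  df <- x$catalog
  df$tag_start_1based <- df$tag_start + 1L
  df$tag_start <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tagless_path)) {
    writeLines(x$tagless, tagless_path)
  }
  invisible(path)
}

#' Unigene count from assembly summaries
#'
#' Unigenes are non-redundant assembled sequences: contigs plus singletons.
#'
#' @param contig_count,singleton_count non-negative integer counts.
#' @return their sum.
#' @export
#' @examples
#' unigene_count(19496, 49321)
unigene_count <- function(contig_count, singleton_count) {
  stopifnot(is.numeric(contig_count), is.numeric(singleton_count))
  if (any(contig_count < 0) || any(singleton_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  contig_count + singleton_count
}
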