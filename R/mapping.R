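# Tag mapping is CATG-anchored: a tag can only be placed at reference
# positions where the reference itself has the NlaIII recognition site, and
# the mismatch budget applies to the 23 bases downstream of the anchor.
# Candidate sites are enumerated on both strands so that tag directionality
# reveals antisense transcription.

#' Enumerate candidate tag sites of a transcript
#'
#' All CATG occurrences with at least 23 downstream bases, on the transcript
#' as given (sense) and on its reverse complement (antisense). Antisense
#' positions are 0-based offsets on the reverse-complement sequence.
#'
#' @param seq a single nucleotide sequence.
#' @return data.frame with columns `position` (0-based anchor offset on the
#'   matched strand), `strand` (`"sense"`/`"antisense"`), `window` (the 27-mer
#'   at the site).
#' @export
candidate_sites <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  one <- function(s, strand) {
    pos <- .eligible_anchors(s)
    if (length(pos) == 0L) {
      return(data.frame(position = integer(0), strand = character(0),
                        window = character(0), stringsAsFactors = FALSE))
    }
    data.frame(position = pos - 1L, strand = strand,
               window = substring(s, pos, pos + .TAG_LEN - 1L),
               stringsAsFactors = FALSE)
  }
  rbind(one(seq, "sense"), one(reverse_complement(seq), "antisense"))
}

#' Build a site index over a reference set
#'
#' Precomputes every candidate site of every transcript, for use by
#' [map_library()]. For transcripts not flagged as oriented, strand is
#' reported as `"unknown"` on both strands (directionality is meaningless).
#'
#' @param refset a [reference_set()].
#' @return object of class `sage_site_index` (a data.table with columns
#'   `transcript_id`, `origin`, `strand`, `position`, `window`).
#' @export
build_site_index <- function(refset) {
  stopifnot(inherits(refset, "sage_refset"))
  per <- lapply(seq_len(nrow(refset)), function(i) {
    s <- candidate_sites(refset$seq[i])
    if (nrow(s) == 0L) return(NULL)
    s$transcript_id <- refset$transcript_id[i]
    s$origin <- refset$origin[i]
    if (!refset$oriented[i]) s$strand <- "unknown"
    s
  })
  dt <- rbindlist(per)
  if (nrow(dt) == 0L) stop("reference has no candidate tag sites", call. = FALSE)
  setcolorder(dt, c("transcript_id", "origin", "strand", "position", "window"))
  dt[, site_id := .I]
  setattr(dt, "class", c("sage_site_index", class(dt)))
  dt
}

#' Mismatch count between a tag and a candidate site window
#'
#' Both strings are 27 bases and the window begins with CATG; the Hamming
#' distance is computed over the 23 non-anchor positions (QC guarantees the
#' tag's anchor, so anchor positions cannot mismatch). Returns `NA` when the
#' distance exceeds the budget.
#'
#' @param tag,site_window 27-base strings (vectorized, recycled pairwise).
#' @param budget maximum mismatches allowed (default 2).
#' @return integer vector of mismatch counts, `NA` where over budget.
#' @export
match_tag <- function(tag, site_window, budget = 2L) {
  n <- max(length(tag), length(site_window))
  tag <- rep_len(tag, n); site_window <- rep_len(site_window, n)
  if (any(nchar(tag) != .TAG_LEN) || any(nchar(site_window) != .TAG_LEN)) {
    stop("tag and window must both be ", .TAG_LEN, " bases", call. = FALSE)
  }
  tm <- .char_matrix(substr(tag, 5L, .TAG_LEN), .DOWNSTREAM)
  sm <- .char_matrix(substr(site_window, 5L, .TAG_LEN), .DOWNSTREAM)
  mm <- as.integer(rowSums(tm != sm))
  mm[mm > budget] <- NA_integer_
  mm
}

# pigeonhole chunk boundaries: split the 23-base suffix into budget+1 pieces;
# any hit within budget must match at least one piece exactly
.chunk_bounds <- function(budget) {
  k <- budget + 1L
  sizes <- rep(.DOWNSTREAM %/% k, k)
  extra <- .DOWNSTREAM %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = 4L + c(1L, head(ends, -1L) + 1L), end = 4L + ends)
}

# core search: best (minimal-mismatch) hits for each distinct tag
# returns data.table: tag, site_id, mismatches (best hits only)
.best_hits <- function(tags, index, budget) {
  stopifnot(!anyDuplicated(tags))
  eligible <- startsWith(tags, .ANCHOR) & !grepl("N", tags, fixed = TRUE)
  cand <- data.table(tag = tags[eligible])
  if (nrow(cand) == 0L) return(data.table(tag = character(0),
                                          site_id = integer(0),
                                          mismatches = integer(0)))
  sites <- data.table(site_id = index$site_id, window = index$window)

  # exact pass
  exact <- merge(cand, sites[, .(tag = window, site_id)],
                 by = "tag", allow.cartesian = TRUE)
  exact[, mismatches := 0L]
  hit0 <- unique(exact$tag)

  pairs <- list(exact)
  if (budget > 0L) {
    rest <- setdiff(cand$tag, hit0)
    if (length(rest) > 0L) {
      bounds <- .chunk_bounds(budget)
      cp <- vector("list", nrow(bounds))
      for (k in seq_len(nrow(bounds))) {
        tk <- data.table(tag = rest,
                         kmer = substr(rest, bounds[k, 1L], bounds[k, 2L]))
        sk <- data.table(site_id = sites$site_id,
                         kmer = substr(sites$window, bounds[k, 1L], bounds[k, 2L]))
        cp[[k]] <- merge(tk, sk, by = "kmer", allow.cartesian = TRUE)[, .(tag, site_id)]
      }
      cp <- unique(rbindlist(cp))
      if (nrow(cp) > 0L) {
        # verify candidates by Hamming distance over the 23-base suffix
        utags <- unique(cp$tag)
        tm <- .char_matrix(substr(utags, 5L, .TAG_LEN), .DOWNSTREAM)
        wm <- .char_matrix(substr(sites$window, 5L, .TAG_LEN), .DOWNSTREAM)
        ti <- match(cp$tag, utags)
        si <- match(cp$site_id, sites$site_id)
        mm <- integer(nrow(cp))
        step <- 500000L
        for (off in seq(1L, nrow(cp), by = step)) {
          idx <- off:min(off + step - 1L, nrow(cp))
          mm[idx] <- as.integer(rowSums(tm[ti[idx], , drop = FALSE] !=
                                        wm[si[idx], , drop = FALSE]))
        }
        cp[, mismatches := mm]
        cp <- cp[mismatches <= budget]
        pairs <- c(pairs, list(cp))
      }
    }
  }
  all_hits <- rbindlist(pairs, use.names = TRUE)
  if (nrow(all_hits) == 0L) return(all_hits)
  all_hits[, best := min(mismatches), by = tag]
  out <- all_hits[mismatches == best][, best := NULL]
  unique(out)
}

#' Map a tag library onto a two-part reference
#'
#' Each distinct QC-passed tag is placed at its minimal-mismatch candidate
#' sites (CATG-anchored, both strands, mismatch budget over the 23 non-anchor
#' bases). Tags are then partitioned by the origin of their best hits:
#' plant-only hits make a plant tag, fungal-only a fungal tag; tags whose best
#' hits span both origins are ambiguous and excluded from both partitions.
#' Quantification stays per distinct tag: a tag hitting several transcripts
#' within one partition keeps a single count, annotated with all best hits.
#'
#' @param lib a QC-passed [tag_library()] (see [filter_library()]).
#' @param reference a [reference_set()] or a prebuilt [build_site_index()].
#' @param budget maximum mismatches allowed outside the anchor (default 2).
#' @return object of class `sage_mapping`: list with
#'   \describe{
#'     \item{hits}{data.frame of best hits: `tag`, `transcript_id`, `position`
#'       (0-based), `strand`, `mismatches`, `origin`}
#'     \item{assignments}{data.frame per distinct tag: `tag`, `partition`
#'       (`plant`/`fungal`/`ambiguous`/`unmapped`), `best_mismatches`,
#'       `n_best_hits`}
#'     \item{tally}{named numeric: `plant_mapped`, `fungal_mapped`,
#'       `ambiguous`, `unmapped` (weighted by tag counts; sums to the
#'       QC-passed total)}
#'     \item{budget}{the mismatch budget used}
#'   }
#' @export
map_library <- function(lib, reference, budget = 2L) {
  stopifnot(inherits(lib, "sage_library"))
  index <- if (inherits(reference, "sage_site_index")) reference
           else build_site_index(reference)
  hits <- .best_hits(lib$tag, index, budget)
  idx <- as.data.table(index)[, .(site_id, transcript_id, origin, strand, position)]
  hits_full <- merge(hits, idx, by = "site_id")[, .(
    tag, transcript_id, position, strand, mismatches, origin)]
  setorder(hits_full, tag, mismatches, transcript_id)

  part <- hits_full[, .(
    best_mismatches = mismatches[1L],
    n_best_hits = .N,
    partition = if (length(unique(origin)) > 1L) "ambiguous" else origin[1L]
  ), by = tag]
  assignments <- merge(data.table(tag = lib$tag), part, by = "tag",
                       all.x = TRUE)
  assignments[is.na(partition), `:=`(partition = "unmapped", n_best_hits = 0L)]

  counts <- merge(assignments[, .(tag, partition)],
                  as.data.table(lib)[, .(tag, count)], by = "tag")
  tal <- counts[, .(n = sum(count)), by = partition]
  tally <- c(plant_mapped = 0, fungal_mapped = 0, ambiguous = 0, unmapped = 0)
  lab <- c(plant = "plant_mapped", fungal = "fungal_mapped",
           ambiguous = "ambiguous", unmapped = "unmapped")
  tally[lab[tal$partition]] <- tal$n

  out <- list(hits = as.data.frame(hits_full),
              assignments = as.data.frame(assignments),
              tally = tally,
              budget = budget)
  class(out) <- "sage_mapping"
  out
}

#' @export
print.sage_mapping <- function(x, ...) {
  cat("<sage_mapping> budget ", x$budget, "; tallies: ",
      paste(sprintf("%s=%g", names(x$tally), x$tally), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-replicate mapping rates
#'
#' Combines a mapping tally with the QC report of the same replicate into a
#' summary row in the style of per-library tag accounting tables: mapped tags
#' as a percentage of the potential mappable tags (integer percent for plant,
#' one decimal for fungal).
#'
#' @param mapping a [map_library()] result.
#' @param qc_report the QC report row of the same library ([filter_library()]).
#' @return one-row data.frame: `sample`, `replicate`, `total`, `with_anchor`,
#'   `after_polyA`, `plant_mapped`, `plant_pct`, `fungal_mapped`, `fungal_pct`.
#' @export
mapping_rates <- function(mapping, qc_report) {
  stopifnot(inherits(mapping, "sage_mapping"),
            inherits(qc_report, "sage_qc_report"))
  pm <- qc_report$after_polyA
  data.frame(
    sample = qc_report$sample,
    replicate = qc_report$replicate,
    total = qc_report$total,
    with_anchor = qc_report$with_anchor,
    after_polyA = pm,
    plant_mapped = unname(mapping$tally["plant_mapped"]),
    plant_pct = mapped_fraction(unname(mapping$tally["plant_mapped"]), pm, 0),
    fungal_mapped = unname(mapping$tally["fungal_mapped"]),
    fungal_pct = mapped_fraction(unname(mapping$tally["fungal_mapped"]), pm, 1),
    stringsAsFactors = FALSE
  )
}

#' Write mapping hits to TSV (positions 1-based)
#' @param mapping a `sage_mapping`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  df <- mapping$hits
  df$position_1based <- df$position + 1L
  df$position <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
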