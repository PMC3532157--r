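# Test helpers: small fixture builders and an independent brute-force mapping
# oracle. The oracle shares no code with the package mapper: it slides over
# every position of every transcript on both strands, requires the window to
# begin with CATG, and computes the full 27-base Hamming distance.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# a random 27-base tag with the CATG anchor (QC-passable unless mutated)
rand_tag <- function() paste0("CATG", rand_seq(23))

# mutate k positions of a tag outside the anchor
mutate_tag <- function(tag, k) {
  ch <- strsplit(tag, "")[[1]]
  pos <- sample(5:27, k)
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

rc <- function(x) sagetag::reverse_complement(x)

random_refset <- function(n, len = c(80, 300)) {
  seqs <- character(n)
  for (i in seq_len(n)) {
    # ensure at least one eligible CATG so the refset is never siteless
    body <- rand_seq(sample(len[1]:len[2], 1))
    seqs[i] <- paste0(body, "CATG", rand_seq(23))
  }
  origin <- sample(c("plant", "fungal"), n, replace = TRUE)
  origin[1] <- "plant"
  if (n > 1) origin[2] <- "fungal"
  reference_set(sprintf("tr%03d", seq_len(n)), seqs, origin = origin)
}

hamming27 <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# brute-force oracle: best hits and partition per tag
oracle_map <- function(tags, refset, budget = 2L) {
  res <- lapply(tags, function(tg) {
    hits <- list()
    for (i in seq_len(nrow(refset))) {
      for (strand in c("sense", "antisense")) {
        s <- if (strand == "sense") refset$seq[i] else rc(refset$seq[i])
        L <- nchar(s)
        if (L < 27) next
        for (p in 1:(L - 26)) {
          w <- substr(s, p, p + 26)
          if (substr(w, 1, 4) != "CATG") next
          d <- hamming27(tg, w)
          if (d <= budget) {
            hits[[length(hits) + 1]] <- data.frame(
              transcript_id = refset$transcript_id[i], position = p - 1L,
              strand = strand, mismatches = d, origin = refset$origin[i],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(hits) == 0) {
      return(list(partition = "unmapped", best = NA_integer_,
                  hits = data.frame()))
    }
    h <- do.call(rbind, hits)
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    part <- if (length(unique(h$origin)) > 1) "ambiguous" else h$origin[1]
    list(partition = part, best = min(h$mismatches), hits = h)
  })
  names(res) <- tags
  res
}

# random QC-passed library over a refset's canonical tags plus noise tags
random_instance <- function(n_transcripts, n_tags, budget = 2L) {
  refset <- random_refset(n_transcripts)
  catalog <- digest_reference(refset)$catalog
  tags <- character(n_tags)
  for (j in seq_len(n_tags)) {
    u <- runif(1)
    tags[j] <- if (u < 0.5) {
      mutate_tag(sample(catalog$tag_seq, 1), sample(0:4, 1))
    } else if (u < 0.7) {
      # tag from an internal (non-canonical) or antisense site
      i <- sample(nrow(refset), 1)
      sites <- candidate_sites(refset$seq[i])
      mutate_tag(sample(sites$window, 1), sample(0:2, 1))
    } else {
      rand_tag()
    }
  }
  tags <- unique(tags)
  tags <- tags[trailing_a_run(tags) <= 10]
  list(refset = refset, tags = tags)
}
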