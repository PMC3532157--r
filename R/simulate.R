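# Synthetic data with known ground truth, shaped like a mixed host/endophyte
# SOLiD-SAGE experiment: a large plant transcript population plus a small
# fungal one (a few percent of mapped tags), a strongly skewed fungal
# abundance distribution (top transcript ~10% of fungal tags), a configurable
# set of truly differentially expressed plant tags across 3+3 replicates,
# antisense transcripts at set sense:antisense ratios, adaptor-ligation
# artifacts lacking the CATG anchor, poly(A)-runoff tags, and per-base
# substitution errors.

#' Simulation configuration
#'
#' Defaults emulate the observed structure of a grass/endophyte SOLiD-SAGE
#' experiment at desk scale: fungal tags about 2% of mapped tags in the
#' infected sample, the top fungal transcript about 10% of fungal tags, a
#' top plant tag near 1% of plant tags, ~30% of raw tags lacking the anchor,
#' and 3 biological replicates per sample.
#'
#' @param seed integer seed; identical seeds give identical outputs.
#' @param n_plant,n_fungal transcript counts per origin.
#' @param length_mean,length_sd,min_length transcript length distribution (nt).
#' @param gc GC fraction of random sequence.
#' @param polya_len poly(A) tail length appended to every transcript.
#' @param library_size tags per replicate library (before QC).
#' @param replicates biological replicates per sample (default 3 + 3).
#' @param plant_meanlog,plant_sdlog log-normal plant abundance model.
#' @param fungal_top_share share of fungal tags taken by the top transcript;
#'   the Zipf exponent is solved from this.
#' @param fungal_fraction fraction of mapped tags that are fungal in the
#'   infected sample (the uninfected sample has none).
#' @param n_de number of truly differentially expressed plant tags (half up,
#'   half down in the infected sample).
#' @param de_fold true fold change of DE tags.
#' @param de_cv within-group coefficient of variation of replicate abundance
#'   (biological noise, applied to every plant tag; the fungal composition is
#'   held fixed across replicates so fungal ranking and antisense ratios are
#'   governed by counting noise alone).
#' @param de_min_expected_count DE tags are drawn only from plant tags whose
#'   expected count per library is at least this (a t-test at n = 3 has no
#'   power on near-zero counts).
#' @param antisense_ratios true sense:antisense ratios 1:R; ratio `j` is
#'   attached to the j-th most abundant fungal transcript.
#' @param no_anchor_rate fraction of library tags that are adaptor artifacts
#'   without the CATG prefix.
#' @param polya_runoff_rate fraction of library tags that are poly(A) runoff
#'   (anchored but ending in >10 A's).
#' @param error_rate per-base substitution error rate over the 23 non-anchor
#'   bases (anchor-breaking errors are governed by `no_anchor_rate`).
#' @return object of class `sage_sim_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_plant = 1200L, n_fungal = 800L,
                              length_mean = 400, length_sd = 120,
                              min_length = 100L,
                              gc = 0.5, polya_len = 30L,
                              library_size = 1e5, replicates = 3L,
                              plant_meanlog = 0, plant_sdlog = 1,
                              fungal_top_share = 0.10,
                              fungal_fraction = 0.02,
                              n_de = 50L, de_fold = 4, de_cv = 0.2,
                              de_min_expected_count = 20,
                              antisense_ratios = c(9, 30),
                              no_anchor_rate = 0.30,
                              polya_runoff_rate = 0.002,
                              error_rate = 0.005) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(seed == as.integer(seed),
              n_plant >= 1, n_fungal >= length(antisense_ratios),
              length_mean > 0, length_sd >= 0, min_length >= .TAG_LEN,
              gc >= 0, gc <= 1,
              polya_len >= 0,
              library_size > 0, replicates >= 2,
              fungal_top_share > 0, fungal_top_share < 1,
              fungal_fraction >= 0, fungal_fraction < 1,
              n_de >= 0, de_fold >= 1, de_cv >= 0,
              all(antisense_ratios > 0),
              no_anchor_rate >= 0, no_anchor_rate <= 1,
              polya_runoff_rate >= 0, polya_runoff_rate <= 1,
              no_anchor_rate + polya_runoff_rate < 1,
              error_rate >= 0, error_rate < 1)
  })
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sage_sim_config"
  cfg
}

#' Random nucleotide sequence
#'
#' @param length sequence length in bases.
#' @param gc GC fraction (default 0.5, i.e. uniform over A/C/G/T).
#' @return a single character string.
#' @export
simulate_sequence <- function(length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Mean spacing between CATG sites in a sequence
#'
#' Mean distance between consecutive CATG occurrence starts on the given
#' strand. For uniform random sequence the expectation is 4^4 = 256 bp.
#'
#' @param seq a single nucleotide sequence.
#' @return mean spacing in bp (`NA` if fewer than two sites).
#' @export
catg_spacing <- function(seq) {
  hits <- gregexpr(.ANCHOR, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L || length(hits) < 2L) return(NA_real_)
  mean(diff(as.integer(hits)))
}

# one random transcript whose canonical tag passes QC and is not in `taken`;
# if `need_antisense`, the reverse complement must also carry a QC-clean,
# non-colliding tag (returned as `as_tag`)
.simulate_transcript <- function(cfg, taken, need_antisense = FALSE) {
  repeat {
    len <- max(cfg$min_length, round(rnorm(1, cfg$length_mean, cfg$length_sd)))
    seq <- paste0(simulate_sequence(len, cfg$gc), strrep("A", cfg$polya_len))
    tg <- extract_tag(seq)
    if (is.null(tg)) next
    if (trailing_a_run(tg$tag_seq) > 10L) next
    if (tg$tag_seq %in% taken) next
    as_tag <- NULL
    if (need_antisense) {
      rc <- extract_tag(reverse_complement(seq))
      if (is.null(rc)) next
      if (trailing_a_run(rc$tag_seq) > 10L) next
      if (rc$tag_seq %in% c(taken, tg$tag_seq)) next
      as_tag <- rc$tag_seq
    }
    return(list(seq = seq, tag = tg$tag_seq, as_tag = as_tag))
  }
}

#' Simulate a two-origin reference set with known tag truth
#'
#' Generates random plant and fungal transcripts, each rejection-sampled to
#' carry a QC-clean canonical tag (the appended poly(A) tail supplies
#' downstream bases, as on real cDNA); canonical tags are unique across the
#' reference. Fungal transcripts designated to carry antisense transcription
#' additionally carry an eligible tag site on the reverse complement.
#'
#' @param config a [simulation_config()].
#' @return list with
#'   \describe{
#'     \item{refset}{the [reference_set()]}
#'     \item{catalog}{truth tag catalog, equal to [digest_reference()] output}
#'     \item{antisense}{data.frame `transcript_id`, `tag_seq` of the true
#'       antisense tags (fungal transcripts ranked 1..k)}
#'   }
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sage_sim_config"))
  set.seed(config$seed)
  n_as <- length(config$antisense_ratios)
  ids <- c(sprintf("plant_%04d", seq_len(config$n_plant)),
           sprintf("fungal_%04d", seq_len(config$n_fungal)))
  origin <- rep(c("plant", "fungal"), c(config$n_plant, config$n_fungal))
  # fungal transcripts 1..n_as carry antisense transcription (by construction
  # they will also be the most abundant fungal transcripts)
  need_as <- origin == "fungal" &
    seq_along(ids) - config$n_plant <= n_as & seq_along(ids) > config$n_plant
  seqs <- character(length(ids))
  as_tags <- character(0)
  as_ids <- character(0)
  taken <- character(0)
  for (i in seq_along(ids)) {
    tr <- .simulate_transcript(config, taken, need_antisense = need_as[i])
    seqs[i] <- tr$seq
    taken <- c(taken, tr$tag, tr$as_tag)
    if (need_as[i]) {
      as_tags <- c(as_tags, tr$as_tag)
      as_ids <- c(as_ids, ids[i])
    }
  }
  refset <- reference_set(ids, seqs, origin = origin, oriented = TRUE,
                          provenance = sprintf("simulated (seed %d)", config$seed))
  list(refset = refset,
       catalog = digest_reference(refset),
       antisense = data.frame(transcript_id = as_ids, tag_seq = as_tags,
                              stringsAsFactors = FALSE))
}

# solve the Zipf exponent so rank 1 takes `share` of n items
.zipf_exponent <- function(n, share) {
  f <- function(s) 1 / sum(seq_len(n)^(-s)) - share
  uniroot(f, c(0.01, 5))$root
}

# mutate reads: given a character matrix of 27-base tags (rows = reads),
# substitute k >= 1 random non-anchor bases per read
.mutate_reads <- function(tags, error_rate) {
  n <- length(tags)
  if (n == 0L) return(character(0))
  k <- rbinom(n, .DOWNSTREAM, error_rate)
  while (any(k == 0L)) k[k == 0L] <- rbinom(sum(k == 0L), .DOWNSTREAM, error_rate)
  m <- .char_matrix(tags, .TAG_LEN)
  bases <- c("A", "C", "G", "T")
  one <- which(k == 1L)
  if (length(one)) {
    pos <- sample(5:.TAG_LEN, length(one), replace = TRUE)
    idx <- cbind(one, pos)
    cur <- m[idx]
    m[idx] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
  }
  for (i in which(k > 1L)) {
    pos <- sample(5:.TAG_LEN, k[i])
    for (p in pos) m[i, p] <- sample(setdiff(bases, m[i, p]), 1L)
  }
  apply(m, 1L, paste, collapse = "")
}

#' Simulate replicate tag libraries with known truth
#'
#' Builds per-sample tag abundance vectors (log-normal plant abundances,
#' Zipf-distributed fungal abundances with antisense tags at the configured
#' 1:R ratios, fungal tags only in the infected sample), applies per-replicate
#' multiplicative biological noise (log-normal, CV `de_cv`), samples each
#' library multinomially at fixed size, then injects substitution errors,
#' anchorless adaptor artifacts, and poly(A)-runoff tags.
#'
#' @param config a [simulation_config()].
#' @param reference result of [simulate_reference()] for the same config.
#' @param samples labels of the two samples; fungal tags appear only in the
#'   second (infected) sample.
#' @return list with
#'   \describe{
#'     \item{libraries}{list of `sage_library`, one per sample x replicate}
#'     \item{truth}{data.frame, one row per true tag: `tag`, `transcript_id`, `origin`,
#'       `strand`, `p_control`, `p_treatment` (within-partition proportions),
#'       `is_de`, `direction`, `true_fold`, `antisense_ratio`}
#'     \item{config}{the config echo}
#'   }
#' @export
simulate_libraries <- function(config, reference,
                               samples = c("Eminus", "Eplus")) {
  stopifnot(inherits(config, "sage_sim_config"))
  set.seed(config$seed + 1L)
  cat_ <- reference$catalog$catalog
  plant <- cat_[cat_$origin == "plant", ]
  fungal <- cat_[cat_$origin == "fungal", ]
  n_as <- nrow(reference$antisense)

  # plant abundance and DE truth (proportions within the plant partition)
  p_plant <- rlnorm(nrow(plant), config$plant_meanlog, config$plant_sdlog)
  p_plant <- p_plant / sum(p_plant)
  mappable <- 1 - config$no_anchor_rate - config$polya_runoff_rate
  expected <- p_plant * config$library_size * mappable
  eligible <- which(expected >= config$de_min_expected_count)
  if (length(eligible) < config$n_de) {
    stop("not enough sufficiently abundant plant tags for the requested DE set",
         call. = FALSE)
  }
  de_idx <- sample(eligible, config$n_de)
  n_up <- ceiling(config$n_de / 2)
  de_dir <- rep(c("up", "down"), c(n_up, config$n_de - n_up))
  mult <- rep(1, nrow(plant))
  mult[de_idx[de_dir == "up"]] <- config$de_fold
  mult[de_idx[de_dir == "down"]] <- 1 / config$de_fold
  p_plant_trt <- p_plant * mult / sum(p_plant * mult)

  # fungal abundance: Zipf over sense tags, antisense added at 1:R
  s <- .zipf_exponent(nrow(fungal), config$fungal_top_share)
  p_fungal <- seq_len(nrow(fungal))^(-s)
  p_fungal <- p_fungal / sum(p_fungal)
  as_p <- if (n_as > 0) p_fungal[seq_len(n_as)] / config$antisense_ratios else numeric(0)
  fungal_tags <- c(fungal$tag_seq, reference$antisense$tag_seq)
  fungal_trs <- c(fungal$transcript_id, reference$antisense$transcript_id)
  fungal_strand <- rep(c("sense", "antisense"), c(nrow(fungal), n_as))
  p_fungal_all <- c(p_fungal, as_p)
  p_fungal_all <- p_fungal_all / sum(p_fungal_all)

  truth <- data.frame(
    tag = c(plant$tag_seq, fungal_tags),
    transcript_id = c(plant$transcript_id, fungal_trs),
    origin = rep(c("plant", "fungal"), c(nrow(plant), length(fungal_tags))),
    strand = c(rep("sense", nrow(plant)), fungal_strand),
    p_control = c(p_plant, rep(0, length(fungal_tags))),
    p_treatment = c(p_plant_trt, p_fungal_all),
    is_de = c(seq_len(nrow(plant)) %in% de_idx, rep(FALSE, length(fungal_tags))),
    direction = NA_character_,
    true_fold = 1,
    antisense_ratio = NA_real_,
    stringsAsFactors = FALSE
  )
  truth$direction[de_idx] <- de_dir
  truth$true_fold[de_idx] <- ifelse(de_dir == "up", config$de_fold,
                                    -config$de_fold)
  if (n_as > 0) {
    truth$antisense_ratio[truth$strand == "antisense"] <- config$antisense_ratios
  }

  noise_sd <- sqrt(log(1 + config$de_cv^2))
  p_read_err <- 1 - (1 - config$error_rate)^.DOWNSTREAM
  libs <- list()
  for (g in 1:2) {
    ff <- if (g == 2L) config$fungal_fraction else 0
    base_p <- c((if (g == 2L) p_plant_trt else p_plant) * (1 - ff),
                p_fungal_all * ff)
    all_tags <- c(plant$tag_seq, fungal_tags)
    for (r in seq_len(config$replicates)) {
      # biological replicate noise applies to the plant transcriptome (the
      # DE arm); the fungal composition is fixed so that fungal ranking and
      # antisense ratios are governed by counting noise alone
      noise <- c(rlnorm(nrow(plant), -noise_sd^2 / 2, noise_sd),
                 rep(1, length(fungal_tags)))
      lam <- base_p * noise
      lam <- lam / sum(lam)
      alloc <- as.integer(rmultinom(1, config$library_size,
                                    c(config$no_anchor_rate,
                                      config$polya_runoff_rate, mappable)))
      counts <- as.integer(rmultinom(1, alloc[3L], lam))
      # substitution errors move reads from a tag to a mutated copy
      n_err <- rbinom(length(counts), counts, p_read_err)
      err_src <- rep(all_tags, n_err)
      err_tags <- .mutate_reads(err_src, config$error_rate)
      # poly(A) runoff: anchored tags whose 3' end reads into the tail
      runoff <- if (alloc[2L] > 0) {
        src <- sample(all_tags, alloc[2L], replace = TRUE, prob = lam)
        paste0(substr(src, 1L, .TAG_LEN - 11L), strrep("A", 11L))
      } else character(0)
      # adaptor artifacts: random 27-mers without the CATG prefix
      noanchor <- if (alloc[1L] > 0) {
        x <- vapply(seq_len(alloc[1L]),
                    function(i) simulate_sequence(.TAG_LEN, config$gc),
                    character(1))
        bad <- startsWith(x, .ANCHOR)
        x[bad] <- paste0("T", substr(x[bad], 2L, .TAG_LEN))
        x
      } else character(0)
      keep <- counts - n_err > 0
      libs[[length(libs) + 1L]] <- tag_library(
        c(all_tags[keep], err_tags, runoff, noanchor),
        c((counts - n_err)[keep], rep(1L, length(err_tags) + length(runoff) +
                                        length(noanchor))),
        sample = samples[g], replicate = r
      )
    }
  }
  list(libraries = libs, truth = truth, config = config)
}

#' Write / read a simulation truth table
#'
#' Lossless TSV round-trip of the truth table from [simulate_libraries()].
#'
#' @param truth the truth data.frame.
#' @param path file path.
#' @return `path` invisibly (write); the truth data.frame (read).
#' @export
export_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(tag = "character", transcript_id = "character",
                            origin = "character", strand = "character",
                            direction = "character"))
}
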