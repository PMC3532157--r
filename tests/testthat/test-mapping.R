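test_that("candidate sites enumerate both strands correctly", {
  # single sense site at 0; the reverse complement has CATG at its very end,
  # with no room for 23 downstream bases
  s <- paste0("CATG", strrep("C", 23))
  cs <- candidate_sites(s)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$position, 0L)
  expect_equal(cs$strand, "sense")
  expect_equal(cs$window, s)

  # two eligible sense sites
  s2 <- paste0("CATG", strrep("C", 23), "CATG", strrep("C", 23))
  expect_equal(sum(candidate_sites(s2)$strand == "sense"), 2L)

  # an antisense site: embed revcomp(CATG + 23 G) = 23 C + CATG
  s3 <- paste0(strrep("C", 23), "CATG", strrep("C", 30))
  cs3 <- candidate_sites(s3)
  expect_true(any(cs3$strand == "antisense"))

  # site count equals a brute-force regex count on both strands
  set.seed(11)
  for (i in 1:10) {
    sq <- rand_seq(1000)
    n_brute <- 0L
    for (str in c(sq, rc(sq))) {
      pos <- gregexpr("CATG", str, fixed = TRUE)[[1]]
      if (pos[1] != -1) n_brute <- n_brute + sum(pos + 26 <= nchar(str))
    }
    expect_equal(nrow(candidate_sites(sq)), n_brute)
  }
})

test_that("match_tag counts mismatches over the 23 non-anchor bases", {
  w <- paste0("CATG", strrep("A", 23))
  expect_equal(match_tag(w, w), 0L)
  t2 <- paste0("CATG", "CC", strrep("A", 21))
  expect_equal(match_tag(t2, w), 2L)
  t3 <- paste0("CATG", "CCC", strrep("A", 20))
  expect_true(is.na(match_tag(t3, w)))
  expect_equal(match_tag(t3, w, budget = 3), 3L)
  expect_error(match_tag("CATG", w), "27")
})

test_that("map_library resolves exact, mismatched, antisense and ambiguous tags", {
  plant_seq <- paste0(rand_seq(50), "CATG", strrep("G", 23))
  fungal_seq <- paste0(rand_seq(50), "CATG", strrep("T", 23))
  shared <- paste0("CATG", strrep("C", 23))
  refset <- reference_set(
    c("p1", "f1", "p2", "f2"),
    c(plant_seq, fungal_seq,
      paste0(rand_seq(40), shared), paste0(rand_seq(40), shared)),
    origin = c("plant", "fungal", "plant", "fungal"))

  p_tag <- extract_tag(plant_seq)$tag_seq
  f_anti <- extract_tag(rc(fungal_seq))$tag_seq # antisense tag of f1
  near_f <- mutate_tag(extract_tag(fungal_seq)$tag_seq, 1)
  lib <- tag_library(c(p_tag, f_anti, shared, near_f, rand_tag()),
                     counts = c(10, 4, 6, 2, 1))
  m <- map_library(lib, refset, budget = 2)

  asn <- m$assignments
  expect_equal(asn$partition[asn$tag == p_tag], "plant")
  expect_equal(asn$best_mismatches[asn$tag == p_tag], 0L)
  expect_equal(asn$partition[asn$tag == f_anti], "fungal")
  expect_equal(m$hits$strand[m$hits$tag == f_anti][1], "antisense")
  # equal best distance in both partitions -> ambiguous
  expect_equal(asn$partition[asn$tag == shared], "ambiguous")
  # 1 mismatch from fungal only -> fungal wins at best distance
  expect_equal(asn$partition[asn$tag == near_f], "fungal")
  expect_equal(asn$best_mismatches[asn$tag == near_f], 1L)
  # tallies conserve the library total
  expect_equal(sum(m$tally), sum(lib$count))
})

test_that("best-distance wins across partitions", {
  # same window in a plant transcript (mutated by 1) and a fungal one (exact)
  w <- paste0("CATG", rand_seq(23))
  refset <- reference_set(
    c("p", "f"),
    c(paste0(rand_seq(30), mutate_tag(w, 1)), paste0(rand_seq(30), w)),
    origin = c("plant", "fungal"))
  m <- map_library(tag_library(w), refset)
  expect_equal(m$assignments$partition, "fungal")
  expect_equal(m$assignments$best_mismatches, 0L)
})

test_that("non-oriented references give strand-unknown hits", {
  s <- paste0(rand_seq(30), "CATG", strrep("G", 23))
  refset <- reference_set("u1", s, origin = "plant", oriented = FALSE)
  m <- map_library(tag_library(extract_tag(s)$tag_seq), refset)
  expect_true(all(m$hits$strand == "unknown"))
  expect_equal(m$assignments$partition, "plant")
})

test_that("mapper agrees with the exhaustive window-scan oracle", {
  set.seed(404)
  n_instances <- 40
  for (i in seq_len(n_instances)) {
    inst <- random_instance(sample(3:10, 1), sample(10:30, 1))
    m <- map_library(tag_library(inst$tags), inst$refset, budget = 2)
    orc <- oracle_map(inst$tags, inst$refset, budget = 2)
    asn <- m$assignments
    for (tg in inst$tags) {
      o <- orc[[tg]]
      expect_equal(asn$partition[asn$tag == tg], o$partition,
                   label = paste("partition of", tg))
      if (o$partition != "unmapped") {
        expect_equal(asn$best_mismatches[asn$tag == tg], o$best,
                     label = paste("best distance of", tg))
        got <- m$hits[m$hits$tag == tg,
                      c("transcript_id", "position", "strand", "mismatches")]
        want <- o$hits[, c("transcript_id", "position", "strand", "mismatches")]
        got <- got[do.call(order, got), ]; want <- want[do.call(order, want), ]
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want, label = paste("hit set of", tg))
      }
    }
  }
})

test_that("mapping is invariant to tag input order", {
  set.seed(505)
  inst <- random_instance(6, 25)
  lib1 <- tag_library(inst$tags)
  lib2 <- tag_library(rev(inst$tags))
  m1 <- map_library(lib1, inst$refset)
  m2 <- map_library(lib2, inst$refset)
  a1 <- m1$assignments[order(m1$assignments$tag), ]
  a2 <- m2$assignments[order(m2$assignments$tag), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
  expect_equal(m1$tally, m2$tally)
})

test_that("mapping_rates reproduces the accounting-table percentages", {
  set.seed(606)
  refset <- random_refset(5)
  cat_ <- digest_reference(refset)$catalog
  raw <- tag_library(
    c(cat_$tag_seq, paste0("TTTT", rand_seq(23))),
    counts = c(rep(20, nrow(cat_)), 10))
  q <- filter_library(raw)
  m <- map_library(q$library, refset)
  row <- mapping_rates(m, q$report)
  expect_equal(row$total, sum(raw$count))
  expect_equal(row$plant_pct,
               mapped_fraction(row$plant_mapped, row$after_polyA, 0))
  expect_equal(row$fungal_pct,
               mapped_fraction(row$fungal_mapped, row$after_polyA, 1))
})
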