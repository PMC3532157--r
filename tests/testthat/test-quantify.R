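test_that("per-million and percent normalizations are exact and error on zero totals", {
  expect_equal(normalize_tpm(0, 1e6), 0)
  expect_equal(normalize_tpm(50, 2e6), 25)
  expect_error(normalize_tpm(1, 0), "positive")
  expect_equal(percent_of_mapped(43199, 43199), 100)
  expect_equal(percent_of_mapped(1012, 10000), 10.12)
  expect_error(percent_of_mapped(1, 0), "positive")
  # percents over a whole partition sum to 100
  x <- c(5, 20, 75)
  expect_equal(sum(percent_of_mapped(x, sum(x))), 100)
})

test_that("a sampled abundant tag recovers its true proportion in TMM units", {
  set.seed(21)
  p <- 0.012; n <- 2e5
  count <- rbinom(1, n, p)
  tmm <- normalize_tpm(count, n)
  sd3 <- 3 * 1e6 * sqrt(p * (1 - p) / n)
  expect_lt(abs(tmm - 12000), sd3)
})

test_that("unpaired t matches the textbook pooled formula", {
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    list(t = t, p = 2 * pt(-abs(t), length(a) + length(b) - 2))
  }
  r <- unpaired_t(c(10, 11, 12), c(20, 21, 22))
  o <- pooled_t(c(10, 11, 12), c(20, 21, 22))
  expect_equal(r$t, o$t)
  expect_equal(r$p, o$p)
  expect_equal(abs(r$t), 12.2474, tolerance = 1e-4)
  expect_equal(r$p, 2.56e-4, tolerance = 0.01)
  expect_equal(r$df, 4L)

  set.seed(22)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1), 10, 3); b <- rnorm(sample(2:6, 1), 12, 2)
    r <- unpaired_t(a, b); o <- pooled_t(a, b)
    expect_equal(r$t, o$t); expect_equal(r$p, o$p)
  }

  # degenerate cases
  same <- unpaired_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_false(same$degenerate)
  diff <- unpaired_t(c(5, 5, 5), c(7, 7, 7))
  expect_equal(diff$p, 0); expect_true(diff$degenerate)
})

test_that("t-test keeps its nominal size under the null", {
  set.seed(23)
  n_tags <- 1000
  pvals <- vapply(seq_len(n_tags), function(i) {
    unpaired_t(rlnorm(3, 5, 0.2), rlnorm(3, 5, 0.2))$p
  }, numeric(1))
  expect_true(abs(mean(pvals < 0.05) - 0.05) <= 0.02) # 5% +/- 2% absolute
})

test_that("signed fold change follows the +up/-down convention and is antisymmetric", {
  expect_equal(fold_change(10, 10), 1)
  expect_equal(fold_change(10, 74), 7.4)
  expect_equal(fold_change(72, 10), -7.2)
  expect_true(is.na(fold_change(0, 0)))
  expect_equal(fold_change(0, 10, pseudo = 2), 5)
  expect_true(is.na(fold_change(0, 10))) # no pseudo floor supplied
  set.seed(24)
  a <- runif(50, 0.1, 100); b <- runif(50, 0.1, 100)
  expect_equal(fold_change(a, b), -fold_change(b, a))
  expect_true(all(abs(fold_change(a, b)) >= 1))
})

make_expr <- function(norm, origin = "plant",
                      samples = rep(c("Eminus", "Eplus"), each = 3)) {
  tags <- sprintf("tag%04d", seq_len(nrow(norm)))
  rownames(norm) <- tags
  colnames(norm) <- paste0(samples, "_", c(1:3, 1:3))
  structure(list(
    counts = norm, norm = norm,
    tags = data.frame(tag = tags, origin = rep_len(origin, nrow(norm)),
                      stringsAsFactors = FALSE),
    samples = data.frame(column = colnames(norm), sample = samples,
                         replicate = c(1:3, 1:3),
                         plant_total = 1e6, fungal_total = 1e4,
                         stringsAsFactors = FALSE)
  ), class = "sage_expr")
}

test_that("de_scan flags known effects and keeps the false-positive rate near alpha", {
  set.seed(25)
  n_null <- 400; n_de <- 40
  base <- rlnorm(n_null + n_de, 5, 1)
  fold <- c(rep(1, n_null), rep(c(4, 1 / 4), each = n_de / 2))
  noise <- function(mu) mu * rlnorm(3, -0.5 * log(1.04), sqrt(log(1.04))) # CV 20%
  norm <- t(vapply(seq_along(base), function(i) {
    c(noise(base[i]), noise(base[i] * fold[i]))
  }, numeric(6)))
  expr <- make_expr(norm)
  de <- de_scan(expr)
  expect_s3_class(de, "sage_de")
  expect_true(all(c("tag", "mean_ctrl", "mean_trt", "fold_change", "t", "p",
                    "significant") %in% names(de)))
  expect_true(!is.unsorted(de$p))
  truth_de <- sprintf("tag%04d", n_null + seq_len(n_de))
  power <- mean(truth_de %in% de$tag[de$significant])
  fpr <- mean(sprintf("tag%04d", seq_len(n_null)) %in% de$tag[de$significant])
  expect_gte(power, 0.8)
  expect_lte(abs(fpr - 0.05), 0.03)
  # directions agree with the truth
  sig <- de[de$significant & de$tag %in% truth_de, ]
  up <- sprintf("tag%04d", n_null + seq_len(n_de / 2))
  expect_true(all(sig$fold_change[sig$tag %in% up] > 0))
  expect_true(all(sig$fold_change[!sig$tag %in% up] < 0))
})

test_that("de_scan handles constant tags and optional correction", {
  norm <- rbind(rep(7, 6))
  expr <- make_expr(norm)
  de <- de_scan(expr)
  expect_false(de$significant)
  expect_equal(de$p, 1)

  set.seed(26)
  norm2 <- matrix(rlnorm(600, 5, 0.5), ncol = 6)
  raw <- de_scan(make_expr(norm2))
  adj <- de_scan(make_expr(norm2), correct = "BH")
  expect_true(sum(adj$significant) <= sum(raw$significant))
  expect_equal(adj$p_used, p.adjust(adj$p, "BH"))
})

test_that("abundance ranking applies the threshold and accumulates shares", {
  pct <- c(A = 10.12, B = 6.34, C = 4.60, D = 2.60, E = 2.58, F = 0.005)
  r <- abundance_rank(pct, threshold = 0.01)
  expect_equal(r$ranking$tag, c("A", "B", "C", "D", "E"))
  expect_equal(r$n, 5L)
  expect_equal(top_share(r, 5), 26.24)
  expect_equal(r$share, 26.24)
  r0 <- abundance_rank(pct, threshold = 0)
  expect_equal(r0$n, 6L)
  expect_equal(abundance_rank(numeric(0))$n, 0L)
})

test_that("gene capture and coverage arithmetic reproduce the published estimates", {
  expect_equal(gene_capture(6298, 9440), 67)
  expect_equal(gene_capture(9440, 9440), 100)
  expect_equal(gene_capture(0, 9440), 0)
  expect_equal(estimate_gene_content(41000, 3), 123000)
  expect_equal(coverage_estimate(68817, 41000, 3), 56)
  expect_equal(coverage_estimate(123000, 41000, 3), 100)
  expect_equal(coverage_estimate(10000, 41000, 3), 8)
})

test_that("category summary computes per-direction percents with half-away rounding", {
  labels <- data.frame(
    category = c(rep("Photosynthesis", 9), rep("Other", 63),
                 rep("Other", 100)),
    direction = c(rep("up", 72), rep("down", 100)))
  cs <- category_summary(labels)
  expect_equal(cs$totals[["up"]], 72)
  ph <- cs$table[cs$table$category == "Photosynthesis", ]
  expect_equal(ph$up_pct, 13) # 9/72 = 12.5 -> 13, half away from zero
  expect_equal(ph$up_n, 9)

  one <- category_summary(data.frame(category = "x", direction = "up"))
  expect_equal(one$table$up_pct, 100)

  na_lab <- category_summary(data.frame(category = c("x", NA),
                                        direction = c("up", "down")))
  expect_true("no match" %in% na_lab$table$category)
  expect_error(category_summary(data.frame(category = "x", direction = "sideways")))
})

test_that("expression matrix splits normalization by partition", {
  set.seed(27)
  p1 <- paste0(rand_seq(40), "CATG", strrep("G", 23))
  p2 <- paste0(rand_seq(40), "CATG", strrep("C", 23))
  f1 <- paste0(rand_seq(40), "CATG", strrep("T", 23))
  refset <- reference_set(c("p1", "p2", "f1"), c(p1, p2, f1),
                          origin = c("plant", "plant", "fungal"))
  tags <- vapply(c(p1, p2, f1), function(s) extract_tag(s)$tag_seq, character(1))
  libA <- tag_library(tags, counts = c(60, 30, 10), sample = "A", replicate = 1L)
  libB <- tag_library(tags, counts = c(10, 80, 10), sample = "A", replicate = 2L)
  mp <- map_libraries(list(libA, libB), refset)
  expr <- expression_matrix(list(libA, libB), mp$mapping)
  expect_equal(dim(expr$counts), c(3L, 2L))
  expect_equal(expr$samples$plant_total, c(90, 90))
  expect_equal(expr$samples$fungal_total, c(10, 10))
  plant_rows <- expr$tags$origin == "plant"
  expect_equal(expr$norm[plant_rows, 1],
               normalize_tpm(expr$counts[plant_rows, 1], 90))
  expect_equal(unname(expr$norm[!plant_rows, 1]), 100)
  expect_equal(sum(expr$norm[!plant_rows, 2]), 100)
  expect_true(all(colSums(expr$norm[plant_rows, , drop = FALSE]) <= 1e6 + 1e-6))
})
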