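test_that("target calling groups above-threshold probes and keeps one peak", {
  z <- toy_ztrack(c(0, 4, 5, 4, 0)) # midpoints 125, 225, ...
  t1 <- call_targets(z, threshold = 3, merge_distance = 300L)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$peak_z, 5)
  expect_equal(t1$peak_position, probe_midpoints(z$track)[3])
  expect_equal(t1$region_start, z$track$start[2])
  expect_equal(t1$region_end, z$track$end[4])

  expect_equal(nrow(call_targets(toy_ztrack(c(1, 2, 1)), 3, 300L)), 0L)

  # spacing beyond merge_distance splits regions
  z2 <- toy_ztrack(c(4, 0, 0, 0, 4), spacing = 200L)
  t2 <- call_targets(z2, threshold = 3, merge_distance = 500L)
  expect_equal(nrow(t2), 2L)

  # leftmost probe wins exact z ties
  z3 <- toy_ztrack(c(4, 4))
  expect_equal(call_targets(z3, 3, 300L)$peak_position,
               probe_midpoints(z3$track)[1])
})

test_that("target calling matches the brute-force oracle on random tracks", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:50, 1L)
    spacing <- sample(c(50L, 100L, 300L), 1L)
    zvals <- round(rnorm(n, 1, 2), 2)
    z <- toy_ztrack(zvals, spacing = spacing, probe_len = 40L)
    thr <- runif(1, 0.5, 3)
    merge <- sample(c(0L, 100L, 400L), 1L)
    got <- call_targets(z, thr, merge)
    want <- oracle_call_targets(probe_midpoints(z$track), zvals, thr, merge)
    expect_equal(got$peak_position, want$peak_position)
    expect_equal(got$peak_z, want$peak_z)
  }
})

test_that("nearest probe mapping uses midpoints with leftmost tie-break", {
  z <- toy_ztrack(c(1, 2, 3), spacing = 100L) # midpoints 125, 225, 325
  expect_equal(nearest_probe(z, 225)$index, 2L)
  expect_equal(nearest_probe(z, 225)$distance, 0L)
  expect_equal(nearest_probe(z, 175)$index, 1L) # equidistant: leftmost
  hit <- nearest_probe(z, 10000)
  expect_equal(hit$index, 3L) # beyond last probe
  expect_equal(hit$z, 3)
})

test_that("cross-study comparison partitions targets and honours exclusions", {
  mk <- function(pos, z, prefix) {
    df <- data.frame(sequence_id = rep("chr", length(pos)),
                     name = sprintf("%s%d", prefix, seq_along(pos)),
                     region_start = pos - 50L, region_end = pos + 50L,
                     peak_position = pos, peak_z = z,
                     context = rep("unclassified", length(pos)),
                     stringsAsFactors = FALSE)
    class(df) <- c("target_table", "data.frame"); df
  }
  a <- mk(c(1000L, 5000L, 9000L), c(5, 4, 6), "a")
  b <- mk(c(1100L, 8000L), c(5, 5), "b")
  cmp <- compare_studies(a, b, tolerance = 500L)
  expect_equal(cmp$matched$name_a, "a1")
  expect_equal(cmp$matched$distance, 100L)
  expect_equal(cmp$disputed$name, c("a2", "a3"))

  # empty B: everything non-excluded is disputed
  cmp2 <- compare_studies(a, b[0, ], tolerance = 500L, exclude = "a2")
  expect_equal(cmp2$disputed$name, c("a1", "a3"))
  expect_equal(cmp2$excluded, "a2")
  expect_equal(nrow(cmp2$matched), 0L)

  expect_error(compare_studies(rbind(a, a), b, 500L), "duplicate")

  # partition property on random instances
  set.seed(13)
  for (i in 1:50) {
    pa <- sort(sample.int(50000L, sample(1:12, 1L)))
    pb <- sort(sample.int(50000L, sample(0:8, 1L)))
    a <- mk(pa, runif(length(pa), 3, 9), "a")
    b <- mk(pb, runif(length(pb), 3, 9), "b")
    ex <- sample(a$name, sample(0:min(2, nrow(a)), 1L))
    cmp <- compare_studies(a, b, tolerance = 1000L, exclude = ex)
    parts <- c(cmp$matched$name_a, cmp$disputed$name, cmp$excluded)
    expect_setequal(parts, a$name)
    expect_equal(anyDuplicated(parts), 0L)
    if (nrow(cmp$matched)) expect_true(all(cmp$matched$distance <= 1000L))
  }
})

test_that("genomic context classification distinguishes convergent gaps", {
  ann <- gene_annotation(data.frame(
    sequence_id = "chr", start = c(0L, 200L), end = c(100L, 300L),
    strand = c("+", "-"), name = c("gL", "gR"), stringsAsFactors = FALSE), 1000L)
  expect_equal(classify_position(ann, 50L), "genic")
  expect_equal(classify_position(ann, 150L), "intergenic_convergent")
  expect_equal(classify_position(ann, 500L), "intergenic") # trailing gap

  tandem <- gene_annotation(data.frame(
    sequence_id = "chr", start = c(0L, 200L), end = c(100L, 300L),
    strand = c("+", "+"), name = c("gL", "gR"), stringsAsFactors = FALSE), 1000L)
  expect_equal(classify_position(tandem, 150L), "intergenic")
  divergent <- gene_annotation(data.frame(
    sequence_id = "chr", start = c(0L, 200L), end = c(100L, 300L),
    strand = c("-", "+"), name = c("gL", "gR"), stringsAsFactors = FALSE), 1000L)
  expect_equal(classify_position(divergent, 150L), "intergenic")

  expect_error(classify_position(ann, 1000L), "genome_length")
  expect_error(classify_position(ann, -1L), "genome_length")
})

test_that("genic fraction equals the interval-union measure", {
  ann <- gene_annotation(data.frame(
    sequence_id = "chr", start = c(0L, 200L), end = c(400L, 600L),
    strand = c("+", "+"), name = c("g1", "g2"), stringsAsFactors = FALSE), 1000L)
  expect_equal(genic_fraction(ann), 0.6) # union of overlapping genes

  empty <- gene_annotation(data.frame(sequence_id = character(),
                                      start = integer(), end = integer(),
                                      strand = character(), name = character()),
                           1000L)
  expect_equal(genic_fraction(empty), 0)
  full <- gene_annotation(data.frame(sequence_id = "chr", start = 0L,
                                     end = 1000L, strand = "+", name = "g"),
                          1000L)
  expect_equal(genic_fraction(full), 1)

  set.seed(17)
  for (i in 1:40) {
    ann <- random_annotation(sample(2000:10000, 1L), sample(1:8, 1L))
    expect_equal(genic_fraction(ann),
                 oracle_genic_fraction(ann$genes, ann$genome_length),
                 tolerance = 1e-12)
  }
})

test_that("positional enrichment test equals exact binomial summation", {
  expect_equal(positional_enrichment_test(0L, 10L, 0.12)$p_value, 1)
  expect_equal(positional_enrichment_test(2L, 3L, 0.5)$p_value, 0.5) # (3+1)/8

  # enumeration oracle for small n, high-precision tail for larger n
  set.seed(19)
  for (i in 1:40) {
    n <- sample(1:25, 1L); k <- sample(0:n, 1L); p0 <- runif(1, 0.05, 0.95)
    want <- sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
    got <- positional_enrichment_test(k, n, p0)$p_value
    expect_equal(got, want, tolerance = 1e-12)
  }
  r <- positional_enrichment_test(15L, 46L, 0.12)
  expect_equal(r$p_value, pbinom(14, 46, 0.12, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$expected, 46 * 0.12)

  expect_error(positional_enrichment_test(5L, 3L, 0.5), "k <= n")
  expect_error(positional_enrichment_test(1L, 3L, 0), "p0")
})

test_that("rank analysis counts disputed targets among the weakest calls", {
  df <- data.frame(sequence_id = "chr", name = c("t1", "t2", "t3", "t4"),
                   region_start = 1:4 * 100L, region_end = 1:4 * 100L + 50L,
                   peak_position = 1:4 * 100L + 25L, peak_z = c(1, 2, 3, 4),
                   context = "unclassified", stringsAsFactors = FALSE)
  expect_equal(rank_analysis(df, c("t1", "t2"), 2L)$disputed_in_bottom, 2L)
  expect_equal(rank_analysis(df, character(), 3L)$disputed_in_bottom, 0L)
  expect_equal(rank_analysis(df, df$name, 3L)$disputed_in_bottom, 3L)
  expect_warning(r <- rank_analysis(df, c("t1", "zzz"), 2L), "unknown")
  expect_equal(r$disputed_in_bottom, 1L)
  expect_error(rank_analysis(df, "t1", 9L), "exceeds")
})
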