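test_that("bedGraph tracks parse, sort, and drop missing values", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t0\t50\t1.5", "chr\t200\t250\t2.5", "chr\t400\t450\t3.5"), f)
  tr <- read_probe_track(f, label = "r1")
  expect_s3_class(tr, "probe_track")
  expect_equal(tr$start, c(0L, 200L, 400L))
  expect_equal(tr$value, c(1.5, 2.5, 3.5))
  expect_equal(attr(tr, "n_dropped"), 0L)

  # shuffled lines give the identical (sorted) track, with a warning
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t400\t450\t3.5", "chr\t0\t50\t1.5", "chr\t200\t250\t2.5"), f2)
  expect_warning(tr2 <- read_probe_track(f2, label = "r1"), "sort")
  expect_equal(tr2$start, tr$start)
  expect_equal(tr2$value, tr$value)

  # NA values dropped with a count
  f3 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t0\t50\t1.5", "chr\t200\t250\tNA", "chr\t400\t450\t3.5"), f3)
  expect_message(tr3 <- read_probe_track(f3), "dropped 1")
  expect_equal(length(tr3$value), 2L)
  expect_equal(attr(tr3, "n_dropped"), 1L)
})

test_that("malformed bedGraph input fails with informative errors", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t0\t50\t1.5", "chr\t200\t250"), f)
  expect_error(read_probe_track(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr\t0\t100\t1.5", "chr\t50\t150\t2.5"), f2)
  expect_error(read_probe_track(f2), "overlap")

  f3 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(character(), f3)
  expect_error(read_probe_track(f3), "empty")

  f4 <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t50\t1", "chr2\t0\t50\t2"), f4)
  expect_error(read_probe_track(f4), "sequences")
  expect_length(split_by_sequence(f4), 2L)
})

test_that("annotation coordinates convert to 0-based half-open at the boundary", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 1000",
               "chr\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;Name=gA"), f)
  ann <- read_annotation(f)
  expect_equal(ann$genome_length, 1000L)
  expect_equal(ann$genes$start, 100L)
  expect_equal(ann$genes$end, 200L)

  fb <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr\t100\t200\tgB\t0\t+", fb)
  annb <- read_annotation(fb, genome_length = 1000L)
  expect_equal(annb$genes$start, 100L)
  expect_equal(annb$genes$end, 200L)

  # feature extending past the genome end is rejected
  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr 1 150",
               "chr\tsrc\tgene\t101\t200\t.\t+\t.\tID=gA;Name=gA"), f2)
  expect_error(read_annotation(f2), "genome_length")
  # unknown strand is rejected
  expect_error(gene_annotation(data.frame(
    sequence_id = "chr", start = 0L, end = 10L, strand = "?", name = "g"),
    100L), "strand")
})

test_that("annotation writer round-trips through the reader", {
  set.seed(42)
  ann <- random_annotation(5000L, 4L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, f)
  back <- read_annotation(f)
  expect_equal(back$genome_length, ann$genome_length)
  expect_equal(back$genes$start, ann$genes$start)
  expect_equal(back$genes$end, ann$genes$end)
  expect_equal(back$genes$strand, ann$genes$strand)
})

test_that("write_table round-trips records and handles empty tables", {
  df <- data.frame(name = c("a", "b"), position = c(10L, 20L),
                   score = c(1.234567891, 6543.21098), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, f)
  expect_length(readLines(f), 3L) # header + 2 records
  back <- read_table_tsv(f)
  expect_equal(back$name, df$name)
  expect_equal(back$position, df$position)
  expect_equal(back$score, df$score, tolerance = 1e-5)

  write_table(df[0, ], f)
  expect_length(readLines(f), 1L) # header only
})

test_that("probe track writer emits bedGraph the reader accepts", {
  tr <- probe_track("chr", c(0L, 200L), c(50L, 250L), c(1.25, -0.5), "w")
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_probe_track(tr, f)
  back <- read_probe_track(f, label = "w")
  expect_equal(back$start, tr$start)
  expect_equal(back$value, tr$value, tolerance = 1e-5)
})
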