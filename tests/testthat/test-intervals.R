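test_that("read_peaks handles empty, unsorted and malformed input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_warning(ps <- read_peaks(f, "GATA1"), "empty")
  expect_length(ps, 0)

  writeLines(c("track name=x", "chr2\t100\t200", "chr1\t500\t600", "chr1\t10\t20"), f)
  ps <- read_peaks(f, "GATA1")
  df <- as.data.frame(ps)
  expect_equal(nrow(df), 3)
  expect_identical(df$chrom, c("chr1", "chr1", "chr2"))
  expect_true(all(diff(df$start[df$chrom == "chr1"]) > 0))

  writeLines(c("chr1\t10\t20", "chr1\t500\t400"), f)
  expect_error(read_peaks(f, "GATA1"), "line 2.*start >= end")
  writeLines("chr1\tabc\t20", f)
  expect_error(read_peaks(f, "GATA1"), "line 1.*non-integer")
})

test_that("overlapping same-factor records are merged at load with a message", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t150\t250", "chr1\t400\t500"), f)
  expect_message(ps <- read_peaks(f, "SCL"), "merged away 1")
  df <- as.data.frame(ps)
  expect_equal(df$start, c(100, 400))
  expect_equal(df$end, c(250, 500))
})

test_that("merge_union forms transitive unions annotated with all contributing factors", {
  a <- peak_set("GATA1", data.frame(chrom = "chr1", start = 100, end = 200))
  b <- peak_set("FLI1", data.frame(chrom = "chr1", start = 150, end = 250))
  u <- merge_union(list(a, b))
  expect_length(u, 1)
  expect_equal(GenomicRanges::start(u) - 1L, 100)
  expect_equal(GenomicRanges::end(u), 250)
  expect_setequal(unlist(S4Vectors::mcols(u)$factors), c("GATA1", "FLI1"))

  d <- peak_set("SCL", data.frame(chrom = "chr1", start = c(0, 100), end = c(50, 150)))
  u2 <- merge_union(list(d))
  expect_length(u2, 2)

  # chain A-B-C collapses into one region carrying all three factors
  chain <- list(peak_set("A", data.frame(chrom = "c", start = 0, end = 10)),
                peak_set("B", data.frame(chrom = "c", start = 9, end = 20)),
                peak_set("C", data.frame(chrom = "c", start = 19, end = 30)))
  u3 <- merge_union(chain)
  expect_length(u3, 1)
  expect_setequal(unlist(S4Vectors::mcols(u3)$factors), c("A", "B", "C"))
  orc <- oracle_union_patterns(chain, c(c = 40))
  expect_equal(orc$start, 0)
  expect_equal(orc$end, 30)
  expect_equal(orc$pattern, 7L)
})

test_that("union regions match the per-base oracle and conserve covered bp on random landscapes", {
  set.seed(41)
  for (rep in 1:8) {
    sets <- lapply(c("F1", "F2", "F3"), function(f)
      suppressMessages(peak_set(f, random_peak_df(30, max_pos = 20000))))
    u <- merge_union(sets)
    orc <- oracle_union_patterns(sets, c(chr1 = 21000, chr2 = 21000))
    udf <- data.frame(chrom = as.character(GenomicRanges::seqnames(u)),
                      start = GenomicRanges::start(u) - 1L,
                      end = GenomicRanges::end(u))
    udf <- udf[order(udf$chrom, udf$start), ]
    expect_equal(udf$start, orc$start)
    expect_equal(udf$end, orc$end)
    # conservation: union bp equals per-base covered bp
    expect_equal(sum(udf$end - udf$start), sum(orc$end - orc$start))
  }
})

test_that("BED write/read round-trip is the identity on coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = character(), start = integer(), end = integer()), f)
  expect_identical(readLines(f), character(0))

  set.seed(7)
  df <- random_peak_df(100)
  df <- df[order(df$chrom, df$start), ]
  ps <- suppressMessages(peak_set("X", df))
  write_bed(ps, f)
  back <- suppressMessages(read_peaks(f, "X"))
  expect_identical(as.data.frame(back)[, c("chrom", "start", "end")],
                   as.data.frame(ps)[, c("chrom", "start", "end")])
})

test_that("gene models round-trip through GTF and BED12", {
  cfg <- make_tiny_config(3)
  genes <- generate_gene_models(cfg)
  fg <- withr::local_tempfile(fileext = ".gtf")
  fb <- withr::local_tempfile(fileext = ".bed12")
  write_gene_models_gtf(genes, fg)
  write_gene_models_bed12(genes, fb)
  for (path in c(fg, fb)) {
    back <- read_gene_models(path)
    expect_identical(back$gene_id, genes$gene_id)
    expect_identical(back$start, genes$start)
    expect_identical(back$end, genes$end)
    expect_identical(back$strand, genes$strand)
    expect_identical(back$tss, genes$tss)
  }
})
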