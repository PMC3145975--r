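test_that("assign_patterns encodes bound factors as bitmasks over the factor order", {
  a <- peak_set("A", data.frame(chrom = "chr1", start = c(0, 100, 200),
                                end = c(50, 150, 250)))
  b <- peak_set("B", data.frame(chrom = "chr1", start = 300, end = 400))
  occ <- assign_patterns(list(a, b))
  expect_equal(length(occ$regions), 4)
  expect_equal(sort(unique(S4Vectors::mcols(occ$regions)$pattern)), c(1L, 2L))

  # full overlap at one locus sets both bits
  c1 <- peak_set("A", data.frame(chrom = "chr1", start = 100, end = 200))
  c2 <- peak_set("B", data.frame(chrom = "chr1", start = 100, end = 200))
  occ2 <- assign_patterns(list(c1, c2))
  expect_equal(S4Vectors::mcols(occ2$regions)$pattern, 3L)

  expect_error(assign_patterns(list(c1, c1)), "duplicate")
})

test_that("five-factor synthetic patterns equal the per-base oracle region by region", {
  for (s in 1:5) {
    cfg <- make_tiny_config(s)
    genes <- generate_gene_models(cfg)
    land <- generate_peak_landscape(cfg, genes)
    occ <- assign_patterns(land$peaksets)
    orc <- oracle_union_patterns(land$peaksets, cfg$chrom_sizes)
    got <- data.frame(chrom = as.character(GenomicRanges::seqnames(occ$regions)),
                      start = GenomicRanges::start(occ$regions) - 1L,
                      pattern = S4Vectors::mcols(occ$regions)$pattern)
    got <- got[order(got$chrom, got$start), ]
    expect_equal(nrow(got), nrow(orc))
    expect_equal(got$pattern, orc$pattern)
  }
})

test_that("exact counts partition the regions and report zero-count patterns", {
  cfg <- make_small_config(11)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  occ <- assign_patterns(land$peaksets)
  tab <- count_exact_patterns(occ)
  expect_equal(nrow(tab), 31)
  expect_equal(sum(tab$count), attr(tab, "n_regions"))
  expect_equal(sum(tab$count), length(occ$regions))
})

test_that("at-least counts equal explicit superset enumeration and marginals agree across routes", {
  cfg <- make_small_config(12)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  occ <- assign_patterns(land$peaksets)
  tab <- count_exact_patterns(occ)
  fo <- attr(tab, "factor_order")

  ab <- pattern_mask(c("GATA1", "FLI1"), fo)
  supersets <- tab$pattern[bitwAnd(tab$pattern, ab) == ab]
  expect_length(supersets, 8)  # 2^3 supersets of a pair among 5 factors
  expect_equal(count_at_least(tab, c("GATA1", "FLI1")),
               sum(tab$count[tab$pattern %in% supersets]))

  # subset = all five has itself as only superset
  expect_equal(count_at_least(tab, fo), tab$count[tab$pattern == 31L])

  # marginal via at-least equals direct bit counting on the regions
  pats <- S4Vectors::mcols(occ$regions)$pattern
  for (i in seq_along(fo)) {
    expect_equal(count_at_least(tab, bitwShiftL(1L, i - 1L)),
                 sum(bitwAnd(pats, bitwShiftL(1L, i - 1L)) != 0L))
  }
  expect_equal(unname(marginal_counts(tab)["SCL"]), count_at_least(tab, "SCL"))
  expect_error(count_at_least(tab, 32L), "out of range")
})

test_that("exact counts are invariant under factor reordering up to label", {
  cfg <- make_small_config(13)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  occ1 <- assign_patterns(land$peaksets)
  occ2 <- assign_patterns(rev(land$peaksets))
  t1 <- count_exact_patterns(occ1)
  t2 <- count_exact_patterns(occ2)
  canon <- function(tab) {
    key <- vapply(strsplit(tab$label, "+", fixed = TRUE),
                  function(x) paste(sort(x), collapse = "+"), character(1))
    stats::setNames(tab$count, key)[order(key)]
  }
  expect_identical(canon(t1), canon(t2))
})

test_that("pattern tables serialize to TSV and JSON", {
  cfg <- make_tiny_config(14)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  tab <- count_exact_patterns(assign_patterns(land$peaksets))
  ftsv <- withr::local_tempfile(fileext = ".tsv")
  fjson <- withr::local_tempfile(fileext = ".json")
  write_pattern_table(tab, ftsv)
  write_pattern_table(tab, fjson)
  back <- utils::read.delim(ftsv)
  expect_equal(nrow(back), 31)
  expect_equal(sum(back$count), attr(tab, "n_regions"))
  js <- jsonlite::read_json(fjson, simplifyVector = TRUE)
  expect_equal(js$n_regions, attr(tab, "n_regions"))
})
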