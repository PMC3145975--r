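simple_genes <- function() {
  gene_models(data.frame(
    gene_id = c("GA", "GB", "GC"),
    chrom = "chr1",
    start = c(10000, 50000, 120000),
    end = c(20000, 60000, 130000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

test_that("location classification follows promoter > intragenic > intergenic precedence", {
  g <- simple_genes()
  regions <- data.frame(chrom = "chr1",
                        start = c(9500, 15000, 59900, 150000),
                        end = c(9700, 15200, 60100, 150200))
  # region 1 overlaps GA's upstream promoter; region 2 sits inside GA's body;
  # region 3 overlaps GB's TSS (minus strand, TSS at end); region 4 is intergenic
  expect_equal(classify_location(regions, g),
               c("promoter", "intragenic", "promoter", "intergenic"))
})

test_that("intergenic regions map to the nearest gene on each side within 100 kb", {
  g <- simple_genes()
  # TSSs: GA at 10000 (+), GB at 59999 (-), GC at 120000 (+)
  r <- data.frame(chrom = "chr1", start = 100000, end = 100200)
  asg <- map_region_to_genes(r, g)
  expect_setequal(asg$gene_id, c("GB", "GC"))  # ~40 kb left, ~20 kb right
  expect_equal(asg$distance[asg$gene_id == "GB"], 100000 - 59999)
  expect_equal(asg$distance[asg$gene_id == "GC"], 120000 - 100199)

  far <- data.frame(chrom = "chr1", start = 260000, end = 260100)
  asg2 <- map_region_to_genes(far, g, max_distance = 100000)
  # nearest TSS 140 kb to the left, none to the right: beyond the cap
  expect_equal(nrow(asg2), 0)
})

test_that("assignments equal the exhaustive oracle on random fixtures and respect the cap", {
  set.seed(55)
  for (rep in 1:4) {
    cfg <- make_small_config(rep + 60)
    genes <- generate_gene_models(cfg)
    regions <- random_peak_df(120, chroms = names(cfg$chrom_sizes),
                              max_pos = cfg$chrom_sizes[[1]] - 500)
    asg <- map_region_to_genes(regions, genes)
    gr <- combind:::as_region_gr(regions)
    ids <- S4Vectors::mcols(gr)$name
    for (i in seq_len(nrow(regions))) {
      want <- oracle_assign(regions$chrom[i], regions$start[i], regions$end[i], genes)
      got <- asg[asg$region_id == ids[i], c("gene_id", "category", "distance")]
      rownames(got) <- rownames(want) <- NULL
      got <- got[order(got$gene_id), , drop = FALSE]
      want <- want[order(want$gene_id), , drop = FALSE]
      expect_equal(got$gene_id, want$gene_id)
      expect_equal(got$category, want$category)
      expect_equal(got$distance, as.integer(want$distance))
    }
    expect_true(all(asg$distance <= 100000))
    # location categories partition the regions
    loc <- classify_location(regions, genes)
    expect_length(loc, nrow(regions))
    expect_true(all(loc %in% c("promoter", "intragenic", "intergenic")))
    # recomputation is bit-identical
    expect_identical(classify_location(regions, genes), loc)
  }
})

test_that("target gene lists collect genes per exact pattern and match an independent join", {
  cfg <- make_small_config(66)
  genes <- generate_gene_models(cfg)
  land <- generate_peak_landscape(cfg, genes)
  occ <- assign_patterns(land$peaksets)
  lists <- build_target_gene_lists(occ, genes)

  # independent recomputation: per-region assignment joined to patterns
  gr <- combind:::as_region_gr(occ)
  asg <- map_region_to_genes(gr, genes)
  pat <- stats::setNames(S4Vectors::mcols(gr)$pattern, S4Vectors::mcols(gr)$name)
  for (m in unique(lists$pattern)) {
    rids <- names(pat)[pat == m]
    want <- sort(unique(asg$gene_id[asg$region_id %in% rids]))
    expect_identical(target_list(lists, m), want)
  }
  # every listed gene traces back to a region with that exact pattern
  expect_true(all(lists$pattern %in% pat))
})

test_that("a single all-five region near one gene puts that gene only in the all-five list", {
  g <- gene_models(data.frame(gene_id = "TG", chrom = "chr1", start = 5000,
                              end = 9000, strand = "+", stringsAsFactors = FALSE))
  sets <- lapply(c("A", "B", "C", "D", "E"), function(f)
    peak_set(f, data.frame(chrom = "chr1", start = 4500, end = 4800)))
  occ <- assign_patterns(sets)
  lists <- build_target_gene_lists(occ, g)
  expect_equal(nrow(lists), 1)
  expect_equal(lists$pattern, 31L)
  expect_equal(lists$gene_id, "TG")
})
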