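test_that("reproducible_regions keeps reference intervals seen in all reps", {
  reps <- list(data.frame(chrom = "chr1", start = 100, end = 200),
               data.frame(chrom = "chr1", start = 150, end = 250),
               data.frame(chrom = "chr1", start = 180, end = 300))
  out <- reproducible_regions(reps)
  expect_equal(out, data.frame(chrom = "chr1", start = 100, end = 200))

  # a region absent from one replicate is dropped
  reps2 <- list(data.frame(chrom = "chr1", start = c(100, 1000),
                           end = c(200, 1100)),
                data.frame(chrom = "chr1", start = 150, end = 250),
                data.frame(chrom = "chr1", start = 120, end = 220))
  out2 <- reproducible_regions(reps2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$start, 100)

  # identical replicates are the identity
  r <- data.frame(chrom = c("chr1", "chr2"), start = c(10, 50),
                  end = c(40, 90))
  expect_equal(reproducible_regions(list(r, r, r)), r)

  # chromosomes never overlap across names
  repsx <- list(data.frame(chrom = "chr1", start = 100, end = 200),
                data.frame(chrom = "chr2", start = 100, end = 200))
  expect_equal(nrow(reproducible_regions(repsx)), 0)
})

test_that("extend_to_length grows short regions symmetrically", {
  r <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  out <- extend_to_length(r, 450)
  expect_equal(out$start, 825)
  expect_equal(out$end, 1275)

  # clipping at zero preserves the target length
  r0 <- data.frame(chrom = "chr1", start = 0, end = 50)
  out0 <- extend_to_length(r0, 450)
  expect_equal(c(out0$start, out0$end), c(0, 450))

  # long regions are untouched
  rl <- data.frame(chrom = "chr1", start = 5000, end = 5600)
  expect_equal(extend_to_length(rl, 450), rl)

  # odd deficit: the extra base goes to the end side
  rodd <- data.frame(chrom = "chr1", start = 1000, end = 1101)
  oo <- extend_to_length(rodd, 450)
  expect_equal(oo$end - oo$start, 450)
  expect_equal(1000 - oo$start, 174)
  expect_equal(oo$end - 1101, 175)

  # output length >= min(input length, target)
  set.seed(2)
  rr <- data.frame(chrom = "chr1", start = s <- sample(1e5, 50),
                   end = s + sample(c(50, 400, 600), 50, replace = TRUE))
  ee <- extend_to_length(rr, 450)
  expect_true(all(ee$end - ee$start >= pmin(rr$end - rr$start, 450)))
})

test_that("assign_nearest_gene respects the distance cap and breaks ties", {
  tss <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    tss = c(5000, 600000), strand = "+")
  r <- data.frame(chrom = "chr1", start = 9900, end = 10100)
  out <- assign_nearest_gene(r, tss)
  expect_equal(out$gene, "gA")

  far <- data.frame(chrom = "chr1", start = 2e6, end = 2e6 + 200)
  expect_true(is.na(assign_nearest_gene(far, tss)$gene))

  # never assigned beyond the cap even when it is the nearest gene
  lone <- data.frame(chrom = "chr1", start = 510000 + 5000 - 100,
                     end = 510000 + 5000 + 100)
  expect_true(is.na(assign_nearest_gene(lone,
    data.frame(gene_id = "gA", chrom = "chr1", tss = 5000,
               strand = "+"))$gene))

  tie_tss <- data.frame(gene_id = c("gZ", "gA"), chrom = "chr1",
                        tss = c(900, 1100), strand = "+")
  mid <- data.frame(chrom = "chr1", start = 950, end = 1050)  # midpoint 1000
  expect_warning(ass <- assign_nearest_gene(mid, tie_tss), "equidistant")
  expect_equal(ass$gene, "gA")   # lexicographic winner
})

test_that("regulatory load counts, ranks and HRL selection work together", {
  ass <- data.frame(chrom = "chr1", start = 1:10, end = 2:11,
                    gene = c(rep("gA", 5), rep("gB", 2), rep("gC", 2), NA),
                    distance = 0)
  tab <- regulatory_load(ass)
  expect_equal(tab$gene, c("gA", "gB", "gC"))
  expect_equal(tab$count, c(5, 2, 2))
  expect_equal(tab$rank, c(1, 2.5, 2.5))

  # ten genes with counts 10..1: the top decile is the single top gene
  tab10 <- data.frame(gene = paste0("g", 1:10), count = 10:1,
                      rank = 1:10)
  expect_equal(select_hrl(tab10, 0.10, min_count = 7), "g1")

  # nothing qualifies when every count is below the minimum
  low <- data.frame(gene = paste0("g", 1:10), count = rep(6, 10),
                    rank = rep(5.5, 10))
  expect_length(select_hrl(low, 0.10, min_count = 7), 0)

  # both conditions must hold: top decile AND >= 7
  mix <- data.frame(gene = paste0("g", sprintf("%02d", 1:20)),
                    count = c(59, 30, 12, 9, 7, 7, rep(6, 14)),
                    rank = seq_len(20))
  got <- select_hrl(mix, 0.10, min_count = 7)
  expect_setequal(got, c("g01", "g02"))

  # monotone: raising a selected gene's count keeps it selected
  mix2 <- mix
  mix2$count[2] <- 60
  expect_true("g02" %in% select_hrl(mix2, 0.10, min_count = 7))
})

test_that("expression_shift detects a planted location shift", {
  same <- expression_shift(1:30, 1:30)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  sep <- expression_shift(101:150, 1:50)
  expect_equal(sep$D, 1)

  set.seed(11)
  shifted <- expression_shift(stats::rnorm(500, 1), stats::rnorm(500, 0))
  expect_lt(shifted$p, 0.01)
})

test_that("BED round trip preserves 0-based half-open intervals", {
  r <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 150),
                  end = c(450, 400))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, f)
  expect_equal(read_bed(f), r)
})
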