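mk_lnc <- function(chrom, start, end, biotype = "lincRNA",
                   id = sprintf("l_%s_%d", chrom, start)) {
  data.frame(transcript_id = id, gene_id = paste0(id, "_g"), chrom = chrom,
             start = start, end = end, strand = "+", biotype = biotype,
             stringsAsFactors = FALSE)
}
mk_genes <- function(chrom, start, end, id = sprintf("g_%s_%d", chrom, start)) {
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

test_that("genic calls use >=1 bp span overlap on half-open intervals", {
  lnc <- rbind(mk_lnc("c1", 100, 200, id = "a"),
               mk_lnc("c1", 100, 200, id = "b"))
  genes <- rbind(mk_genes("c1", 150, 500, id = "gx"),
                 mk_genes("c2", 0, 1000, id = "gy"))
  ctx <- classify_genic_intergenic(lnc, genes)
  expect_equal(ctx$category, c("genic", "genic"))
  expect_equal(ctx$overlapping_genes[[1]], "gx")
  # touching intervals under the half-open convention do not overlap
  ctx2 <- classify_genic_intergenic(mk_lnc("c1", 100, 200), mk_genes("c1", 200, 500))
  expect_equal(ctx2$category, "intergenic")
  expect_equal(ctx2$subcategory, "intergenic")
  # biotype drives the genic subcategory
  ctx3 <- classify_genic_intergenic(
    mk_lnc("c1", 100, 200, biotype = "antisense"), mk_genes("c1", 150, 300))
  expect_equal(ctx3$subcategory, "antisense")
  expect_warning(
    classify_genic_intergenic(mk_lnc("cX", 1, 10), mk_genes("c1", 1, 10)),
    "cX")
})

test_that("genic/intergenic equals the quadratic all-pairs oracle", {
  for (seed in c(1, 7, 42)) {
    set.seed(seed)
    lnc <- random_intervals(300, "lnc")
    genes <- random_intervals(200, "pc")[, c("gene_id", "chrom", "start", "end")]
    ctx <- classify_genic_intergenic(lnc, genes)
    oracle <- oracle_overlap_calls(lnc, genes)
    expect_identical(unname(ctx$overlapping_genes), oracle)
    expect_identical(ctx$category, ifelse(lengths(oracle) > 0, "genic", "intergenic"))
    # genic + intergenic == total on every input
    expect_equal(sum(ctx$category == "genic") + sum(ctx$category == "intergenic"),
                 nrow(lnc))
  }
})

test_that("flanking genes are the nearest non-overlapping neighbors in order", {
  genes <- rbind(mk_genes("c1", 650, 900, id = "near"),
                 mk_genes("c1", 500, 800, id = "mid"),
                 mk_genes("c1", 100, 700, id = "far"),
                 mk_genes("c1", 1200, 1300, id = "dn1"),
                 mk_genes("c1", 990, 1500, id = "ovl"))
  fl <- get_flanking_genes(mk_lnc("c1", 1000, 1100), genes)
  expect_equal(fl$flank_up[[1]], c("near", "mid", "far"))
  expect_equal(fl$flank_down[[1]], "dn1")  # "ovl" overlaps, excluded
  # first transcript on a chromosome has an empty upstream flank
  fl2 <- get_flanking_genes(mk_lnc("c1", 0, 50), genes)
  expect_length(fl2$flank_up[[1]], 0)
  expect_length(fl2$flank_down[[1]], 5)
})

test_that("flank extraction equals the exhaustive distance-sort oracle", {
  for (seed in c(3, 19)) {
    set.seed(seed)
    lnc <- random_intervals(60, "lnc")
    genes <- random_intervals(120, "pc")[, c("gene_id", "chrom", "start", "end")]
    fl <- get_flanking_genes(lnc, genes)
    for (i in seq_len(nrow(lnc))) {
      o <- oracle_flanks(lnc[i, ], genes)
      expect_identical(fl$flank_up[[i]], o$up)
      expect_identical(fl$flank_down[[i]], o$down)
    }
  }
})

test_that("enrichment export takes overlapping genes or the two nearest flanks", {
  lnc <- rbind(mk_lnc("c1", 150, 250, id = "genic1"),
               mk_lnc("c1", 1000, 1100, id = "inter1"),
               mk_lnc("c1", 160, 260, id = "genic2"))
  genes <- rbind(mk_genes("c1", 100, 300, id = "geneX"),
                 mk_genes("c1", 400, 500, id = "geneA"),
                 mk_genes("c1", 1200, 1400, id = "geneB"))
  ctx <- classify_genic_intergenic(lnc, genes)
  fl <- get_flanking_genes(lnc, genes)
  out <- neighbor_genes_for_enrichment(ctx, fl)
  # geneX shared by two genic lncRNAs appears once; intergenic contributes
  # its nearest upstream (geneA) and downstream (geneB) genes
  expect_equal(out, c("geneA", "geneB", "geneX"))
})

test_that("scaled density maps midpoints to [0,1000] and conserves counts", {
  tx <- data.frame(transcript_id = c("t1", "t2"), chrom = "c1",
                   start = c(450, 900), end = c(550, 1000),
                   stringsAsFactors = FALSE)
  d <- scaled_density(tx, c(c1 = 1000), n_bins = 10)
  expect_equal(unname(d$positions["t1"]), 500)
  expect_equal(unname(d$positions["t2"]), 950)
  expect_equal(sum(d$bin_counts), 2)
  # position exactly 1000 goes to the last bin
  tx2 <- data.frame(transcript_id = "t3", chrom = "c1", start = 999, end = 1001)
  d2 <- scaled_density(tx2, c(c1 = 1001), n_bins = 10)
  expect_equal(d2$bin_counts[10], 1)
  expect_error(scaled_density(
    data.frame(transcript_id = "t", chrom = "c1", start = 0, end = 2000),
    c(c1 = 1000)), "beyond")
})

test_that("scaled density equals a direct recount and is scale-covariant", {
  set.seed(8)
  n <- 200
  start <- sample.int(9000, n)
  tx <- data.frame(transcript_id = paste0("t", 1:n), chrom = "c1",
                   start = start, end = start + sample(50:500, n, TRUE),
                   stringsAsFactors = FALSE)
  lens <- c(c1 = 10000)
  d <- scaled_density(tx, lens, n_bins = 50)
  mid <- (tx$start + tx$end) / 2
  recount <- tabulate(pmin(floor((1000 * mid / lens) / 20) + 1, 50), 50)
  expect_equal(d$bin_counts, recount)
  # doubling all coordinates and the chromosome length changes nothing
  tx2 <- transform(tx, start = start * 2, end = end * 2)
  d2 <- scaled_density(tx2, c(c1 = 20000), n_bins = 50)
  expect_equal(d2$positions, d$positions)
  expect_equal(d2$bin_counts, d$bin_counts)
})

test_that("tissue breadth counts tissues at threshold and separates planted groups", {
  n_tis <- 14
  meta <- data.frame(
    sample_id = paste0("ad", 1:(2 * n_tis)),
    study_id = "stA", species = "zebrafish", sample_type = "adult_tissue",
    tissue_name = rep(paste0("tis", 1:n_tis), each = 2),
    stringsAsFactors = FALSE
  )
  set.seed(12)
  broad <- matrix(runif(20 * 2 * n_tis, 1, 5), nrow = 20)       # all tissues
  specific <- matrix(runif(20 * 2 * n_tis, 0, 0.04), nrow = 20) # none by default
  specific[, 1:4] <- runif(20 * 4, 1, 5)                        # 2 tissues
  expr <- rbind(broad, specific)
  rownames(expr) <- c(paste0("b", 1:20), paste0("s", 1:20))
  colnames(expr) <- meta$sample_id
  tb <- tissue_breadth(expr, meta)
  expect_equal(unname(tb$breadth[paste0("b", 1:20)]), rep(n_tis, 20))
  expect_equal(unname(tb$breadth[paste0("s", 1:20)]), rep(2, 20))
  expect_true(min(tb$breadth[1:20]) > max(tb$breadth[21:40]))
  expect_setequal(tb$order, seq_len(40))
  # all-zero transcript has breadth 0
  expr0 <- rbind(expr, z1 = 0)
  expect_equal(unname(tissue_breadth(expr0, meta)$breadth["z1"]), 0)
  expect_error(tissue_breadth(expr, transform(meta, sample_type = "zygote")),
               "adult")
})
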