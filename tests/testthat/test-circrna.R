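mk_junc <- function(chrom, start0, end0, sample, reads, ratio) {
  data.frame(chrom = chrom, bs_start = start0, bs_end = end0, strand = "+",
             sample_id = sample, junction_reads = as.integer(reads),
             junction_ratio = ratio,
             circ_id = sprintf("%s:%d-%d", chrom, start0 + 1, end0),
             stringsAsFactors = FALSE)
}

test_that("candidate filter is inclusive at both thresholds and per sample", {
  j <- rbind(mk_junc("c1", 100, 500, "zy1", 2, 0.05),
             mk_junc("c1", 100, 500, "oo1", 1, 0.90),
             mk_junc("c2", 100, 500, "oo1", 10, 0.04))
  f <- filter_circ_candidates(j)
  expect_equal(f$junctions$pass, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(f$candidates), 1)
  expect_equal(f$candidates$passing_samples[[1]], "zy1")
})

test_that("tightening either filter never grows the candidate set", {
  ann <- generate_genome_annotation(2, 15, 6, seed = 31)
  jt <- generate_junction_tables(ann, paper_sample_layout(), seed = 32)
  grid <- expand.grid(reads = c(1, 2, 4, 25), ratio = c(0.01, 0.05, 0.2, 0.95))
  sets <- lapply(seq_len(nrow(grid)), function(i) {
    filter_circ_candidates(jt$junctions, grid$reads[i], grid$ratio[i])$candidates$circ_id
  })
  for (i in seq_len(nrow(grid))) {
    for (k in seq_len(nrow(grid))) {
      if (grid$reads[k] >= grid$reads[i] && grid$ratio[k] >= grid$ratio[i]) {
        expect_true(all(sets[[k]] %in% sets[[i]]))
      }
    }
  }
})

test_that("circRNA inheritance requires a zygote plus a gamete sample", {
  meta <- toy_meta(zygote_studies = c(A = 1), n_sperm = 1, n_oocyte = 2)
  j <- rbind(mk_junc("c1", 10, 200, "zyA_1", 5, 0.5),
             mk_junc("c1", 10, 200, "oo_1", 5, 0.5),
             mk_junc("c2", 10, 200, "oo_1", 5, 0.5),
             mk_junc("c3", 10, 200, "zyA_1", 5, 0.5),
             mk_junc("c4", 10, 200, "zyA_1", 5, 0.5),
             mk_junc("c4", 10, 200, "sp_1", 5, 0.5),
             mk_junc("c4", 10, 200, "oo_2", 5, 0.5))
  cand <- classify_circ_inherited(filter_circ_candidates(j)$candidates, meta)
  got <- setNames(cand$origin, cand$chrom)
  expect_equal(cand$inherited, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(got[["c1"]], "oocyte_only")
  expect_equal(got[["c2"]], "none")   # gamete only, no zygote
  expect_equal(got[["c3"]], "none")   # zygote only
  expect_equal(got[["c4"]], "both_gametes")
})

test_that("category follows the two junction points against exons and spans", {
  # geneX: exons [100,200) and [400,500); geneY: exon [800,900)
  ann <- data.frame(
    transcript_id = c("tx", "ty"), gene_id = c("geneX", "geneY"),
    chrom = "c1", start = c(100, 800), end = c(500, 900), strand = "+",
    biotype = "protein_coding", stringsAsFactors = FALSE)
  ann$exons <- list(cbind(start = c(100, 400), end = c(200, 500)),
                    cbind(start = 800, end = 900))
  cand <- rbind(mk_junc("c1", 150, 450, "s", 5, 0.5),   # both points exonic
                mk_junc("c1", 250, 320, "s", 5, 0.5),   # both points intronic
                mk_junc("c1", 250, 650, "s", 5, 0.5),   # intron + intergenic
                mk_junc("c1", 600, 700, "s", 5, 0.5),   # fully intergenic
                mk_junc("c1", 150, 850, "s", 5, 0.5))   # spans geneX and geneY
  cand$passing_samples <- as.list(cand$sample_id)
  got <- annotate_circ_category(cand, ann)
  expect_equal(got$category,
               c("exonic", "intronic", "intronic", "intergenic", "exonic"))
  expect_equal(got$host_genes[[1]], "geneX")
  expect_equal(got$host_genes[[3]], "geneX")
  expect_equal(got$host_genes[[4]], character(0))
  expect_equal(got$host_genes[[5]], c("geneX", "geneY"))
  # categories partition the candidates and intergenic <=> no host
  expect_equal(sum(got$category %in% c("exonic", "intronic", "intergenic")),
               nrow(got))
  expect_equal(got$category == "intergenic", lengths(got$host_genes) == 0)
  # annotating with shuffled gene order yields identical categories
  got_rev <- annotate_circ_category(cand, ann[2:1, ])
  expect_equal(got_rev$category, got$category)
  expect_equal(got_rev$host_genes, got$host_genes)
})

test_that("circular vs linear comparison normalizes reads per million", {
  meta <- toy_meta(zygote_studies = c(A = 1), n_sperm = 1, n_oocyte = 1)
  # zygote sample has 50 total backsplice reads, 5 from the candidate
  j <- rbind(mk_junc("c1", 150, 450, "zyA_1", 5, 0.5),
             mk_junc("c2", 10, 90, "zyA_1", 45, 0.5),
             mk_junc("c1", 150, 450, "oo_1", 4, 0.5))
  ann <- data.frame(transcript_id = "tx", gene_id = "geneX", chrom = "c1",
                    start = 100, end = 500, strand = "+",
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  ann$exons <- list(cbind(start = c(100, 400), end = c(200, 500)))
  f <- filter_circ_candidates(j)
  cand <- annotate_circ_category(classify_circ_inherited(f$candidates, meta), ann)
  expr <- matrix(c(2, 0, 0), nrow = 1,
                 dimnames = list("tx", c("zyA_1", "sp_1", "oo_1")))
  cmp <- circ_vs_linear(cand, j, expr, meta,
                        data.frame(transcript_id = "tx", gene_id = "geneX"))
  row1 <- cmp[cmp$circ_id == "c1:151-450", ]
  expect_equal(row1$circ_norm, 1e6 * 5 / 50)  # 100000 per million
  expect_equal(row1$linear_fpkm, 2)
  expect_equal(row1$flag, "circ_exceeds_linear")
  row2 <- cmp[cmp$circ_id == "c2:11-90", ]
  expect_equal(row2$flag, "no_host")
  expect_true(is.na(row2$linear_fpkm))
  # zero-expression host with a present circle is an infinite ratio
  expr0 <- matrix(0, 1, 3, dimnames = dimnames(expr))
  cmp0 <- circ_vs_linear(cand, j, expr0, meta,
                         data.frame(transcript_id = "tx", gene_id = "geneX"))
  expect_true(is.infinite(cmp0$ratio[cmp0$circ_id == "c1:151-450"]))
  expect_equal(cmp0$flag[cmp0$circ_id == "c1:151-450"], "circ_exceeds_linear")
})

test_that("planted circ-exceeds-linear cases are exactly the flagged ones", {
  meta <- toy_meta(zygote_studies = c(A = 1))
  ann <- data.frame(
    transcript_id = paste0("t", 1:10), gene_id = paste0("g", 1:10),
    chrom = "c1", start = seq(0, 9000, by = 1000),
    end = seq(0, 9000, by = 1000) + 500, strand = "+",
    biotype = "protein_coding", stringsAsFactors = FALSE)
  ann$exons <- lapply(seq_len(10), function(i)
    cbind(start = ann$start[i], end = ann$end[i]))
  j <- do.call(rbind, lapply(1:10, function(i)
    mk_junc("c1", ann$start[i] + 50, ann$start[i] + 400, "zyA_1", 10, 0.5)))
  # total 100 reads -> each circ_norm = 1e5; hosts 1:5 weak, 6:10 strong
  expr <- matrix(c(rep(1e4, 5), rep(1e6, 5)), ncol = 1,
                 dimnames = list(paste0("t", 1:10), "zyA_1"))
  expr <- cbind(expr, sp_1 = 0, oo_1 = 0)
  f <- filter_circ_candidates(j)
  cand <- annotate_circ_category(classify_circ_inherited(f$candidates, meta), ann)
  cmp <- circ_vs_linear(cand, j, expr, meta,
                        data.frame(transcript_id = paste0("t", 1:10),
                                   gene_id = paste0("g", 1:10)))
  flagged <- cmp$host_genes[cmp$flag == "circ_exceeds_linear"]
  expect_setequal(flagged, paste0("g", 1:5))
})

test_that("chromosome distribution reports counts and per-Mb density", {
  cand <- data.frame(
    circ_id = paste0("c", 1:40),
    chrom = rep(c("chrA", "chrB"), c(34, 6)),
    bs_start = seq(1000, length.out = 40, by = 1500),
    bs_end = seq(1400, length.out = 40, by = 1500),
    stringsAsFactors = FALSE)
  d <- circ_chromosome_distribution(cand, c(chrA = 60e6, chrB = 10e6))
  expect_equal(d$per_chrom$count, c(34, 6))
  expect_equal(d$per_chrom$density_per_mb[1], 34 / 60, tolerance = 1e-12)
  expect_equal(sum(d$per_chrom$count), nrow(cand))
  expect_equal(sum(d$scaled$bin_counts), nrow(cand))
  expect_error(circ_chromosome_distribution(cand, c(chrA = 60e6)), "chrB")
})
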