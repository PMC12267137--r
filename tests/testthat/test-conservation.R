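mk_hits <- function(query, subject, e) {
  data.frame(query_id = query, subject_id = subject, percent_identity = 90,
             alignment_length = 50, mismatches = 5, gap_opens = 0,
             q_start = 1, q_end = 50, s_start = 1, s_end = 50,
             e_value = e, bit_score = 40, stringsAsFactors = FALSE)
}

test_that("sequence conservation needs passing hits in both target species", {
  q <- c("z1", "z2", "z3")
  hm <- mk_hits(c("z1", "z2", "z3"), c("m1", "m2", "m3"), c(1e-6, 1e-6, 1e-5))
  hh <- mk_hits(c("z1", "z3"), c("h1", "h3"), c(1e-7, 2e-5))
  sc <- sequence_conserved(hm, hh, q)
  got <- setNames(sc$seq_conserved, sc$lncrna_id)
  expect_true(got[["z1"]])            # passes in both
  expect_false(got[["z2"]])           # mouse only
  expect_false(got[["z3"]])           # human hit above cutoff
  # e-value boundary is inclusive
  sc2 <- sequence_conserved(mk_hits("z3", "m3", 1e-5), mk_hits("z3", "h3", 1e-5), "z3")
  expect_true(sc2$seq_conserved)
  # hits outside the target inherited set are ignored with a warning
  expect_warning(
    sc3 <- sequence_conserved(hm, hh, q, mouse_inherited = c("m1"),
                              human_inherited = c("h1", "h3")),
    "mouse")
  expect_equal(sum(sc3$seq_conserved), 1)
  expect_equal(sc3$counterparts_mouse[[1]], "m1")
})

test_that("seeded search finds planted segments and the identity case", {
  set.seed(101)
  seg <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  q <- paste0(rnd(150), seg, rnd(150))
  s <- paste0(rnd(80), seg, rnd(200))
  hits <- seeded_similarity_search(c(q1 = q), c(s1 = s))
  planted <- hits[hits$percent_identity == 100 & hits$alignment_length >= 60, ]
  expect_gte(nrow(planted), 1)

  # identical sequences align end to end at 100% identity
  self <- rnd(100)
  h2 <- seeded_similarity_search(c(a = self), c(b = self))
  expect_true(any(h2$alignment_length == 100 & h2$percent_identity == 100))

  # two unrelated random sequences share no 20-mer: no hit
  a <- rnd(500); b <- rnd(500)
  kmers <- function(x) substring(x, 1:(nchar(x) - 19), 20:nchar(x))
  expect_length(intersect(kmers(a), kmers(b)), 0)  # fixture is clean
  expect_equal(nrow(seeded_similarity_search(c(a = a), c(b = b))), 0)

  expect_error(seeded_similarity_search(c(a = a), c(b = b), word_size = 3),
               "word_size")
})

test_that("overlap conservation equals the cubic triplet-scan oracle", {
  for (seed in c(4, 15, 23)) {
    set.seed(seed)
    zf_g <- paste0("zg", 1:30); m_g <- paste0("mg", 1:30); h_g <- paste0("hg", 1:30)
    ortho <- data.frame(zebrafish = sample(zf_g, 15), mouse = sample(m_g, 15),
                        human = sample(h_g, 15), stringsAsFactors = FALSE)
    zc <- rand_context(paste0("zl", 1:20), zf_g)
    mc <- rand_context(paste0("ml", 1:15), m_g)
    hc <- rand_context(paste0("hl", 1:15), h_g)
    got <- overlap_conserved(zc, mc, hc, ortho)
    expect_equal(got$overlap_conserved,
                 oracle_overlap_conserved(zc$overlapping_genes,
                                          mc$overlapping_genes,
                                          hc$overlapping_genes, ortho))
    # a true flag always comes with counterparts in both species
    for (i in which(got$overlap_conserved)) {
      expect_gt(length(got$counterparts_mouse[[i]]), 0)
      expect_gt(length(got$counterparts_human[[i]]), 0)
    }
  }
})

test_that("loci conservation matches the exhaustive candidate scan", {
  for (seed in c(6, 31)) {
    set.seed(seed)
    zf_g <- paste0("zg", 1:40)
    ortho <- data.frame(zebrafish = zf_g, mouse = paste0("mg", 1:40),
                        human = paste0("hg", 1:40), stringsAsFactors = FALSE)
    zf <- rand_flanks(paste0("zl", 1:12), zf_g)
    # target flank pools drawn from the ortholog images to create sharing
    mf <- rand_flanks(paste0("ml", 1:10), c(ortho$mouse, paste0("mx", 1:20)))
    hf <- rand_flanks(paste0("hl", 1:10), c(ortho$human, paste0("hx", 1:20)))
    for (ms in c(3, 5)) {
      got <- loci_conserved(zf, mf, hf, ortho, min_shared = ms)
      sets <- function(fl) lapply(seq_len(nrow(fl)), function(i)
        unique(c(fl$flank_up[[i]], fl$flank_down[[i]])))
      expect_equal(got$loci_conserved,
                   oracle_loci_conserved(sets(zf), sets(mf), sets(hf), ortho, ms))
    }
  }
})

test_that("loci conservation thresholds behave at the boundary", {
  zf <- data.frame(transcript_id = "zl1", stringsAsFactors = FALSE)
  zf$flank_up <- list(paste0("zg", 1:5))
  zf$flank_down <- list(paste0("zg", 6:10))
  ortho <- data.frame(zebrafish = paste0("zg", 1:10),
                      mouse = paste0("mg", 1:10),
                      human = paste0("hg", 1:10), stringsAsFactors = FALSE)
  mk_target <- function(id, genes) {
    out <- data.frame(transcript_id = id, stringsAsFactors = FALSE)
    out$flank_up <- list(genes[seq_len(min(5, length(genes)))])
    out$flank_down <- list(genes[-seq_len(min(5, length(genes)))])
    out
  }
  m5 <- mk_target("ml1", c(paste0("mg", 1:5), paste0("mzz", 1:5)))
  h7 <- mk_target("hl1", c(paste0("hg", 1:7), paste0("hzz", 1:3)))
  expect_true(loci_conserved(zf, m5, h7, ortho)$loci_conserved)
  m4 <- mk_target("ml1", c(paste0("mg", 1:4), paste0("mzz", 1:6)))
  expect_false(loci_conserved(zf, m4, h7, ortho)$loci_conserved)
  # a reference lncRNA with < min_shared flank genes can never qualify
  zf_small <- data.frame(transcript_id = "zl2", stringsAsFactors = FALSE)
  zf_small$flank_up <- list(paste0("zg", 1:2))
  zf_small$flank_down <- list(character(0))
  expect_false(loci_conserved(zf_small, m5, h7, ortho)$loci_conserved)
})

test_that("raising min_shared never adds loci-conserved calls", {
  sy <- generate_three_species_synteny(seed = 13)
  fl <- lapply(sy[c("zf", "mouse", "human")], function(s)
    get_flanking_genes(s$lnc, gene_spans(s$genes)))
  prev <- NULL
  for (ms in 3:7) {
    cur <- loci_conserved(fl$zf, fl$mouse, fl$human, sy$ortho, min_shared = ms)
    cur_set <- cur$lncrna_id[cur$loci_conserved]
    if (!is.null(prev)) expect_true(all(cur_set %in% prev))
    prev <- cur_set
  }
})

test_that("Venn decomposition partitions the conserved set", {
  calls <- data.frame(
    seq_conserved = c(TRUE, TRUE, FALSE),
    overlap_conserved = c(FALSE, FALSE, TRUE),
    loci_conserved = c(FALSE, TRUE, FALSE)
  )
  v <- combine_conservation(calls)
  expect_equal(v$regions[["seq_only"]], 1)
  expect_equal(v$regions[["seq_loci"]], 1)
  expect_equal(v$regions[["overlap_only"]], 1)
  expect_equal(v$n_conserved, 3)
  expect_equal(v$exclusively_syntenic, 1)
  # all-false input gives all-zero regions
  none <- combine_conservation(data.frame(seq_conserved = logical(3),
                                          overlap_conserved = logical(3),
                                          loci_conserved = logical(3)))
  expect_true(all(none$regions == 0))
  # random flag fixtures agree with direct set algebra
  for (seed in c(2, 77)) {
    set.seed(seed)
    s <- sample(c(TRUE, FALSE), 50, TRUE)
    o <- sample(c(TRUE, FALSE), 50, TRUE)
    l <- sample(c(TRUE, FALSE), 50, TRUE)
    v2 <- combine_conservation(data.frame(seq_conserved = s,
                                          overlap_conserved = o,
                                          loci_conserved = l))
    expect_equal(v2$regions, oracle_venn(s, o, l))
    expect_equal(sum(v2$regions), v2$n_conserved)
  }
})
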