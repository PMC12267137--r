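# Independent brute-force oracles and small fixture builders.  The oracles
# deliberately use naive all-pairs / all-candidates loops so that they share
# no code with the package implementations they check.

# quadratic all-pairs interval intersection (half-open intervals)
oracle_overlap_calls <- function(lnc, genes) {
  lapply(seq_len(nrow(lnc)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(genes))) {
      if (lnc$chrom[i] == genes$chrom[j] &&
          lnc$start[i] < genes$end[j] && genes$start[j] < lnc$end[i]) {
        hits <- c(hits, genes$gene_id[j])
      }
    }
    sort(hits)
  })
}

# distance-sorted flank sets by exhaustive scan
oracle_flanks <- function(lnc_row, genes, n_up = 5, n_down = 5) {
  up <- list(); dn <- list()
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != lnc_row$chrom) next
    if (genes$end[j] <= lnc_row$start) {
      up[[length(up) + 1]] <- list(id = genes$gene_id[j],
                                   d = lnc_row$start - genes$end[j],
                                   s = genes$start[j])
    } else if (genes$start[j] >= lnc_row$end) {
      dn[[length(dn) + 1]] <- list(id = genes$gene_id[j],
                                   d = genes$start[j] - lnc_row$end,
                                   s = genes$start[j])
    }
  }
  pick <- function(l, n) {
    if (!length(l)) return(character(0))
    d <- vapply(l, `[[`, numeric(1), "d")
    s <- vapply(l, `[[`, numeric(1), "s")
    id <- vapply(l, `[[`, character(1), "id")
    ord <- order(d, s, id)
    utils::head(id[ord], n)
  }
  list(up = pick(up, n_up), down = pick(dn, n_down))
}

# cubic scan over ortholog triplets for overlap conservation
oracle_overlap_conserved <- function(zf_ov, mouse_ov, human_ov, ortho) {
  # *_ov: list of overlapping-gene character vectors per lncRNA
  vapply(zf_ov, function(zgenes) {
    for (t in seq_len(nrow(ortho))) {
      if (!(ortho$zebrafish[t] %in% zgenes)) next
      m_hit <- any(vapply(mouse_ov, function(g) ortho$mouse[t] %in% g, logical(1)))
      h_hit <- any(vapply(human_ov, function(g) ortho$human[t] %in% g, logical(1)))
      if (m_hit && h_hit) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# exhaustive all-candidate scan for loci conservation
oracle_loci_conserved <- function(zf_sets, m_sets, h_sets, ortho, min_shared = 5) {
  shared_count <- function(zf_set, target_set, from, to) {
    cnt <- 0
    for (g in zf_set) {
      orth <- ortho[[to]][ortho[[from]] == g]
      if (length(orth) && any(orth %in% target_set)) cnt <- cnt + 1
    }
    cnt
  }
  vapply(zf_sets, function(zf_set) {
    if (length(zf_set) < min_shared) return(FALSE)
    best_m <- if (length(m_sets))
      max(vapply(m_sets, shared_count, numeric(1), zf_set = zf_set,
                 from = "zebrafish", to = "mouse")) else 0
    best_h <- if (length(h_sets))
      max(vapply(h_sets, shared_count, numeric(1), zf_set = zf_set,
                 from = "zebrafish", to = "human")) else 0
    best_m >= min_shared && best_h >= min_shared
  }, logical(1))
}

oracle_venn <- function(s, o, l) {
  ids <- seq_along(s)
  S <- ids[s]; O <- ids[o]; L <- ids[l]
  only <- function(a, b, c) length(setdiff(setdiff(a, b), c))
  pair <- function(a, b, c) length(setdiff(intersect(a, b), c))
  c(seq_only = only(S, O, L), overlap_only = only(O, S, L),
    loci_only = only(L, S, O), seq_overlap = pair(S, O, L),
    seq_loci = pair(S, L, O), overlap_loci = pair(O, L, S),
    all_three = length(intersect(intersect(S, O), L)))
}

# random interval fixtures on a small chromosome set
random_intervals <- function(n, prefix, n_chrom = 3, max_pos = 10000,
                             min_w = 50, max_w = 800) {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  data.frame(
    gene_id = sprintf("%s_g%d", prefix, seq_len(n)),
    transcript_id = sprintf("%s_t%d", prefix, seq_len(n)),
    chrom = sample(paste0("c", seq_len(n_chrom)), n, replace = TRUE),
    start = start, end = start + w,
    strand = sample(c("+", "-"), n, replace = TRUE),
    biotype = "lincRNA",
    stringsAsFactors = FALSE
  )
}

# tiny expression fixture: explicit per-sample values for hand examples
toy_meta <- function(zygote_studies = c(A = 2, B = 1), n_sperm = 1,
                     n_oocyte = 1) {
  rows <- list()
  for (s in names(zygote_studies)) {
    for (i in seq_len(zygote_studies[[s]])) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("zy%s_%d", s, i), study_id = paste0("st", s),
        species = "zebrafish", sample_type = "zygote",
        tissue_name = NA_character_, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(n_sperm)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = paste0("sp_", i), study_id = "st_sp", species = "zebrafish",
      sample_type = "sperm", tissue_name = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_oocyte)) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = paste0("oo_", i), study_id = "st_oo", species = "zebrafish",
      sample_type = "oocyte", tissue_name = NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

expr_matrix <- function(meta, ...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- meta$sample_id
  rownames(m) <- names(rows)
  m
}

# random abstract context/flank fixtures for oracle comparisons
rand_context <- function(ids, gene_pool, max_genes = 2) {
  ov <- lapply(ids, function(i) {
    k <- sample(0:max_genes, 1)
    sort(sample(gene_pool, k))
  })
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  out$overlapping_genes <- ov
  out$category <- ifelse(lengths(ov) > 0, "genic", "intergenic")
  out
}

rand_flanks <- function(ids, gene_pool, n_flank = 10) {
  up <- lapply(ids, function(i) sample(gene_pool, n_flank %/% 2))
  dn <- lapply(ids, function(i) sample(gene_pool, n_flank - n_flank %/% 2))
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  out$flank_up <- up
  out$flank_down <- dn
  out
}

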