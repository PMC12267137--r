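# Cross-species conservation of inherited lncRNAs under three definitions:
# by sequence similarity, by overlap with orthologous protein-coding genes,
# and by flanking-gene synteny.  All three require a counterpart in BOTH
# target species (mouse and human in the reference application).

#' Sequence conservation from tabular alignment hits
#'
#' A query lncRNA is sequence-conserved iff it has at least one hit with
#' e-value <= `e_cutoff` against the inherited lncRNA set of *each* target
#' species.  The cutoff is inclusive.  Hits whose subject is not in the
#' supplied target inherited set are ignored with a warning.  Hits with an
#' unset (NA) e-value — as produced by the internal
#' [seeded_similarity_search()], which cannot compute database-dependent
#' e-values — count as passing: there, presence of a seed-extended hit is
#' the evidence.
#'
#' @param hits_mouse,hits_human Alignment-hit data frames (see
#'   [read_alignment_hits()]); queries are lncRNAs of the reference species.
#' @param query_ids lncRNA ids to flag.
#' @param mouse_inherited,human_inherited Optional subject id whitelists.
#' @param e_cutoff Inclusive e-value cutoff, default 1e-5.
#' @return Data frame: `lncrna_id`, `seq_conserved`, per-species flags
#'   `seq_mouse`/`seq_human`, list-columns `counterparts_mouse`,
#'   `counterparts_human`.
#' @export
sequence_conserved <- function(hits_mouse, hits_human, query_ids,
                               mouse_inherited = NULL, human_inherited = NULL,
                               e_cutoff = 1e-5) {
  screen <- function(hits, subjects, species) {
    if (!is.null(subjects)) {
      drop <- !(hits$subject_id %in% subjects)
      if (any(drop)) {
        warning(sum(drop), " ", species,
                " hit(s) with subject outside the inherited set ignored")
        hits <- hits[!drop, , drop = FALSE]
      }
    }
    hits[is.na(hits$e_value) | hits$e_value <= e_cutoff, , drop = FALSE]
  }
  hm <- screen(hits_mouse, mouse_inherited, "mouse")
  hh <- screen(hits_human, human_inherited, "human")
  cp <- function(hits) {
    lapply(query_ids, function(q) sort(unique(hits$subject_id[hits$query_id == q])))
  }
  cm <- cp(hm)
  ch <- cp(hh)
  out <- data.frame(
    lncrna_id = query_ids,
    seq_mouse = lengths(cm) > 0,
    seq_human = lengths(ch) > 0,
    stringsAsFactors = FALSE
  )
  out$seq_conserved <- out$seq_mouse & out$seq_human
  out$counterparts_mouse <- cm
  out$counterparts_human <- ch
  out[, c("lncrna_id", "seq_conserved", "seq_mouse", "seq_human",
          "counterparts_mouse", "counterparts_human")]
}

# best ungapped segment (Kadane, match +1 / mismatch -2) on a match vector;
# returns c(from, to, score) in local indices or NULL
best_segment <- function(m) {
  sc <- ifelse(m, 1, -2)
  best <- c(0L, 0L, -Inf)
  cur_from <- 1L; cur <- 0
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_from <- i }
    cur <- cur + sc[i]
    if (cur > best[3]) best <- c(cur_from, i, cur)
  }
  if (best[3] <= 0) return(NULL)
  best
}

#' Seeded ungapped similarity search
#'
#' Minimal word-seeded search used by the synthetic test harness: for every
#' exact shared `word_size`-mer between a query and a subject, the diagonal
#' through the seed is scored (+1 match, -2 mismatch) and the maximal
#' ungapped segment on that diagonal is reported as one hit.  Percent
#' identity and alignment length are populated; the e-value is left NA
#' (it depends on database statistics this oracle does not model).
#'
#' @param query_seqs,subject_seqs Named character vectors of A/C/G/T/N
#'   sequences.
#' @param word_size Exact seed length, default 20; must be >= 4.
#' @return Alignment-hit data frame in the standard 12-column layout.
#' @export
seeded_similarity_search <- function(query_seqs, subject_seqs, word_size = 20) {
  if (word_size < 4) stop("word_size must be >= 4")
  hit_rows <- list()
  for (qn in names(query_seqs)) {
    q <- strsplit(query_seqs[[qn]], "")[[1]]
    lq <- length(q)
    if (lq < word_size) next
    qk <- vapply(seq_len(lq - word_size + 1),
                 function(i) paste(q[i:(i + word_size - 1)], collapse = ""),
                 character(1))
    for (sn in names(subject_seqs)) {
      s <- strsplit(subject_seqs[[sn]], "")[[1]]
      ls <- length(s)
      if (ls < word_size) next
      sk <- vapply(seq_len(ls - word_size + 1),
                   function(i) paste(s[i:(i + word_size - 1)], collapse = ""),
                   character(1))
      sk_index <- split(seq_along(sk), sk)
      diags <- integer(0)
      for (qi in seq_along(qk)) {
        si <- sk_index[[qk[qi]]]
        if (!is.null(si)) diags <- c(diags, qi - si)
      }
      for (d in unique(diags)) {
        # overlap of the two sequences on diagonal d (query index = subject + d)
        q_from <- max(1L, 1L + d)
        q_to <- min(lq, ls + d)
        qi <- q_from:q_to
        m <- q[qi] == s[qi - d] & q[qi] != "N"
        seg <- best_segment(m)
        if (is.null(seg)) next
        len <- seg[2] - seg[1] + 1
        nmatch <- sum(m[seg[1]:seg[2]])
        if (nmatch < word_size) next
        qs <- q_from + seg[1] - 1L
        qe <- q_from + seg[2] - 1L
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          query_id = qn, subject_id = sn,
          percent_identity = 100 * nmatch / len,
          alignment_length = len,
          mismatches = len - nmatch, gap_opens = 0L,
          q_start = qs, q_end = qe,
          s_start = qs - d, s_end = qe - d,
          e_value = NA_real_, bit_score = seg[3],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hit_rows)) {
    out <- data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- alignment_hit_columns()
    return(out)
  }
  out <- do.call(rbind, hit_rows)
  rownames(out) <- NULL
  out
}

#' Conservation by overlap with orthologous protein-coding genes
#'
#' A reference lncRNA is overlap-conserved iff some ortholog triplet
#' (gZ, gM, gH) exists with gZ among the lncRNA's overlapping genes, gM
#' overlapped by at least one mouse inherited lncRNA and gH by at least one
#' human inherited lncRNA.
#'
#' @param zf_context,mouse_context,human_context Results of
#'   [classify_genic_intergenic()] for the inherited lncRNAs of each
#'   species (against that species' conserved protein-coding genes).
#' @param ortho Ortholog map (columns `zebrafish`, `mouse`, `human`).
#' @return Data frame: `lncrna_id`, `overlap_conserved`, list-columns
#'   `counterparts_mouse`, `counterparts_human`, `evidence_genes`
#'   (the zebrafish genes of the supporting triplets).
#' @export
overlap_conserved <- function(zf_context, mouse_context, human_context, ortho) {
  gene_to_lnc <- function(context) {
    pairs <- data.frame(
      gene = unlist(context$overlapping_genes),
      lnc = rep(context$transcript_id, lengths(context$overlapping_genes)),
      stringsAsFactors = FALSE
    )
    split(pairs$lnc, pairs$gene)
  }
  m_map <- gene_to_lnc(mouse_context)
  h_map <- gene_to_lnc(human_context)
  good <- ortho$mouse %in% names(m_map) & ortho$human %in% names(h_map)
  good_tri <- ortho[good, , drop = FALSE]

  n <- nrow(zf_context)
  flag <- logical(n)
  cm <- ch <- ev <- vector("list", n)
  for (i in seq_len(n)) {
    tri <- good_tri[good_tri$zebrafish %in% zf_context$overlapping_genes[[i]], ,
                    drop = FALSE]
    flag[i] <- nrow(tri) > 0
    ev[[i]] <- as.character(unique(tri$zebrafish))
    cm[[i]] <- as.character(sort(unique(unlist(m_map[tri$mouse]))))
    ch[[i]] <- as.character(sort(unique(unlist(h_map[tri$human]))))
  }
  out <- data.frame(lncrna_id = zf_context$transcript_id,
                    overlap_conserved = flag, stringsAsFactors = FALSE)
  out$counterparts_mouse <- cm
  out$counterparts_human <- ch
  out$evidence_genes <- ev
  out
}

#' Conservation by flanking-gene synteny (loci conservation)
#'
#' For each reference lncRNA the flank set is the union of its up- and
#' downstream flanking protein-coding genes (at most 10).  The lncRNA is
#' loci-conserved iff some mouse inherited lncRNA's flank set contains
#' orthologs of at least `min_shared` distinct reference flank genes AND
#' some human inherited lncRNA's flank set does likewise.  Sharing is
#' counted by set membership, ignoring up/down orientation and order.  A
#' reference lncRNA with fewer than `min_shared` flank genes in total
#' cannot reach the threshold and is flagged FALSE.
#'
#' @param zf_flanks,mouse_flanks,human_flanks Results of
#'   [get_flanking_genes()] per species.
#' @param ortho Ortholog map.
#' @param min_shared Minimum number of shared orthologous flank genes,
#'   default 5.
#' @return Data frame: `lncrna_id`, `loci_conserved`, best shared counts
#'   `best_shared_mouse`/`best_shared_human`, list-columns
#'   `counterparts_mouse`, `counterparts_human` (candidates reaching the
#'   threshold).
#' @export
loci_conserved <- function(zf_flanks, mouse_flanks, human_flanks, ortho,
                           min_shared = 5) {
  flank_sets <- function(fl) {
    stats::setNames(
      lapply(seq_len(nrow(fl)), function(i) {
        unique(c(fl$flank_up[[i]], fl$flank_down[[i]]))
      }),
      fl$transcript_id
    )
  }
  zf_sets <- flank_sets(zf_flanks)
  m_sets <- flank_sets(mouse_flanks)
  h_sets <- flank_sets(human_flanks)
  z2m <- stats::setNames(ortho$mouse, ortho$zebrafish)
  z2h <- stats::setNames(ortho$human, ortho$zebrafish)

  score_species <- function(zf_set, target_sets, z2x) {
    orthos <- z2x[zf_set]  # NA where the flank gene has no ortholog
    shared <- vapply(target_sets, function(ts) sum(orthos %in% ts), integer(1))
    shared
  }

  n <- length(zf_sets)
  flag <- logical(n)
  best_m <- best_h <- integer(n)
  cm <- ch <- vector("list", n)
  for (i in seq_len(n)) {
    zf_set <- zf_sets[[i]]
    if (length(zf_set) < min_shared) {
      best_m[i] <- best_h[i] <- 0L
      cm[[i]] <- ch[[i]] <- character(0)
      next
    }
    sm <- score_species(zf_set, m_sets, z2m)
    sh <- score_species(zf_set, h_sets, z2h)
    best_m[i] <- if (length(sm)) max(sm) else 0L
    best_h[i] <- if (length(sh)) max(sh) else 0L
    cm[[i]] <- names(sm)[sm >= min_shared]
    ch[[i]] <- names(sh)[sh >= min_shared]
    flag[i] <- best_m[i] >= min_shared && best_h[i] >= min_shared
  }
  out <- data.frame(
    lncrna_id = names(zf_sets),
    loci_conserved = flag,
    best_shared_mouse = best_m,
    best_shared_human = best_h,
    stringsAsFactors = FALSE
  )
  out$counterparts_mouse <- cm
  out$counterparts_human <- ch
  out
}

#' Combine the three conservation flags into Venn regions
#'
#' @param calls Data frame with logical columns `seq_conserved`,
#'   `overlap_conserved`, `loci_conserved` (one row per lncRNA).
#' @return List with `regions` (named counts of the 7 Venn regions),
#'   `n_conserved` (lncRNAs with >= 1 flag) and `exclusively_syntenic`
#'   (conserved by overlap or loci but not by sequence).
#' @export
combine_conservation <- function(calls) {
  s <- calls$seq_conserved
  o <- calls$overlap_conserved
  l <- calls$loci_conserved
  regions <- c(
    seq_only = sum(s & !o & !l),
    overlap_only = sum(!s & o & !l),
    loci_only = sum(!s & !o & l),
    seq_overlap = sum(s & o & !l),
    seq_loci = sum(s & !o & l),
    overlap_loci = sum(!s & o & l),
    all_three = sum(s & o & l)
  )
  list(
    regions = regions,
    n_conserved = sum(s | o | l),
    exclusively_syntenic = sum((o | l) & !s)
  )
}
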