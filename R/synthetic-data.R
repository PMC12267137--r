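# Deterministic generators for every pipeline input, with planted ground
# truth.  All decision-relevant values keep a 2x margin around the
# corresponding thresholds (expressed cells >= 0.2 vs absent <= 0.05 around
# the 0.1 FPKM cutoff; candidate junctions reads >= 3 / ratio >= 0.1 vs
# non-candidates reads <= 1 or ratio <= 0.02), so rule-correctness tests are
# separated from noise-robustness concerns.

#' Sample layout mirroring the reference zebrafish study design
#'
#' Two sperm samples from two studies, seven oocyte samples from four
#' studies, ten zygote samples from four studies.
#'
#' @return Sample metadata data frame.
#' @export
paper_sample_layout <- function() {
  mk <- function(type, study_sizes, prefix) {
    do.call(rbind, lapply(seq_along(study_sizes), function(s) {
      data.frame(
        sample_id = sprintf("%s%d_s%d", prefix, s, seq_len(study_sizes[s])),
        study_id = sprintf("study_%s%d", prefix, s),
        species = "zebrafish",
        sample_type = type,
        tissue_name = NA_character_,
        stringsAsFactors = FALSE
      )
    }))
  }
  rbind(
    mk("sperm", c(1, 1), "sp"),
    mk("oocyte", c(2, 2, 2, 1), "oo"),
    mk("zygote", c(3, 3, 2, 2), "zy")
  )
}

#' Generate a synthetic genome annotation
#'
#' Plants non-overlapping protein-coding genes with 2-5 exons along each
#' chromosome, then lncRNAs of three positional classes: antisense (inside
#' a gene span, opposite strand), sense-overlapping (straddling a gene
#' boundary) and intergenic (inside a gene-free gap), with biotypes drawn
#' from the lncRNA whitelist.
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Protein-coding genes per chromosome.
#' @param lnc_per_chrom lncRNAs per chromosome.
#' @param seed RNG seed; the same seed reproduces the annotation exactly.
#' @param lnc_mix Named proportions for classes `antisense`,
#'   `sense_overlapping`, `intergenic`.
#' @return List with `transcripts` (records as from [parse_gtf()]),
#'   `chrom_sizes` (named vector) and `truth` (per-lncRNA planted labels:
#'   `planted_category`, `planted_subclass`, `host_gene`).
#' @export
generate_genome_annotation <- function(n_chrom = 1, genes_per_chrom = 20,
                                       lnc_per_chrom = 10, seed = 1,
                                       lnc_mix = c(antisense = 0.3,
                                                   sense_overlapping = 0.3,
                                                   intergenic = 0.4)) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 1, lnc_per_chrom >= 0)
  set.seed(seed)
  rec <- function(tid, gid, chrom, start, end, strand, biotype, exons) {
    list(transcript_id = tid, gene_id = gid, chrom = chrom, start = start,
         end = end, strand = strand, biotype = biotype, exons = exons)
  }
  all_recs <- list()
  truth <- list()
  chrom_sizes <- numeric(0)

  n_as <- round(lnc_mix[["antisense"]] * lnc_per_chrom)
  n_so <- round(lnc_mix[["sense_overlapping"]] * lnc_per_chrom)
  n_ig <- lnc_per_chrom - n_as - n_so
  if (n_ig < 0) stop("lnc_mix proportions exceed 1")
  if (n_ig > genes_per_chrom) {
    stop("requested lncRNA density exceeds chromosome capacity (",
         n_ig, " intergenic lncRNAs but only ", genes_per_chrom, " gaps)")
  }
  if (n_as + n_so > 0 && genes_per_chrom < max(n_as, n_so)) {
    stop("requested lncRNA density exceeds chromosome capacity (not enough ",
         "host genes)")
  }

  for (ci in seq_len(n_chrom)) {
    chrom <- paste0("chr", ci)
    cur <- 3000
    g_start <- g_end <- numeric(genes_per_chrom)
    g_exons <- vector("list", genes_per_chrom)
    g_strand <- character(genes_per_chrom)
    for (g in seq_len(genes_per_chrom)) {
      n_ex <- sample(2:5, 1)
      ex_w <- sample(100:300, n_ex, replace = TRUE)
      int_w <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE) else integer(0)
      offs <- cumsum(c(0, as.vector(rbind(ex_w[-n_ex], int_w))))
      ex_start <- cur + offs[seq(1, length(offs), by = 2)]
      ex <- cbind(start = ex_start, end = ex_start + ex_w)
      g_start[g] <- cur
      g_end[g] <- max(ex[, 2])
      g_exons[[g]] <- ex
      g_strand[g] <- sample(c("+", "-"), 1)
      cur <- g_end[g] + sample(2500:5000, 1)
    }
    for (g in seq_len(genes_per_chrom)) {
      gid <- sprintf("g_%d_%d", ci, g)
      all_recs[[length(all_recs) + 1]] <- rec(
        paste0(gid, "_t1"), gid, chrom, g_start[g], g_end[g],
        g_strand[g], "protein_coding", g_exons[[g]])
    }
    chrom_sizes[chrom] <- cur + 3000

    add_lnc <- function(idx, start, end, strand, biotype, subclass, host) {
      tid <- sprintf("lnc_%d_%d", ci, idx)
      ex <- cbind(start = start, end = end)
      all_recs[[length(all_recs) + 1]] <<- rec(
        tid, paste0(tid, "_g"), chrom, start, end, strand, biotype, ex)
      truth[[length(truth) + 1]] <<- data.frame(
        transcript_id = tid,
        planted_category = if (subclass == "intergenic") "intergenic" else "genic",
        planted_subclass = subclass,
        host_gene = host,
        stringsAsFactors = FALSE
      )
    }
    lnc_idx <- 0
    as_hosts <- sample(seq_len(genes_per_chrom), n_as)
    for (g in as_hosts) {
      lnc_idx <- lnc_idx + 1
      span <- g_end[g] - g_start[g]
      len <- min(400, span - 100)
      start <- g_start[g] + 50
      add_lnc(lnc_idx, start, start + len,
              if (g_strand[g] == "+") "-" else "+",
              "antisense", "antisense", sprintf("g_%d_%d", ci, g))
    }
    so_hosts <- sample(seq_len(genes_per_chrom), n_so)
    so_bios <- c("sense_overlapping", "sense_intronic", "retained_intron",
                 "processed_transcript")
    for (g in so_hosts) {
      lnc_idx <- lnc_idx + 1
      add_lnc(lnc_idx, g_end[g] - 200, g_end[g] + 400, g_strand[g],
              sample(so_bios, 1), "sense_overlapping", sprintf("g_%d_%d", ci, g))
    }
    ig_gaps <- sample(seq_len(genes_per_chrom), n_ig)
    for (g in ig_gaps) {
      lnc_idx <- lnc_idx + 1
      start <- g_end[g] + 1000
      add_lnc(lnc_idx, start, start + 400, sample(c("+", "-"), 1),
              sample(c("lincRNA", "lncRNA"), 1), "intergenic", NA_character_)
    }
  }

  transcripts <- data.frame(
    transcript_id = vapply(all_recs, `[[`, character(1), "transcript_id"),
    gene_id = vapply(all_recs, `[[`, character(1), "gene_id"),
    chrom = vapply(all_recs, `[[`, character(1), "chrom"),
    start = vapply(all_recs, `[[`, numeric(1), "start"),
    end = vapply(all_recs, `[[`, numeric(1), "end"),
    strand = vapply(all_recs, `[[`, character(1), "strand"),
    biotype = vapply(all_recs, `[[`, character(1), "biotype"),
    stringsAsFactors = FALSE
  )
  transcripts$exons <- lapply(all_recs, `[[`, "exons")
  transcripts <- transcripts[order(transcripts$chrom, transcripts$start,
                                   transcripts$transcript_id), ]
  rownames(transcripts) <- NULL
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(0), planted_category = character(0),
               planted_subclass = character(0), host_gene = character(0))
  list(transcripts = transcripts, chrom_sizes = chrom_sizes, truth = truth)
}

#' Plant per-transcript inheritance truth labels
#'
#' Assigns each transcript one of six expression classes:
#' `stringent` (inherited under both rules), `lenient_only` (inherited
#' under the lenient rule only), `zygote_only`, `partial_zygote` (detected
#' in some but not all zygote studies), `gamete_only`, `absent`.  Inherited
#' transcripts additionally get a gamete origin.
#'
#' @param transcript_ids Character vector.
#' @param seed RNG seed for the label shuffle.
#' @param class_fractions Named fractions over the six classes (summing
#'   to 1); defaults approximate the reference study (20% inherited).
#' @param origin_fractions Named fractions over `both_gametes`,
#'   `oocyte_specific`, `sperm_specific` within the inherited classes.
#' @return Data frame: `transcript_id`, `class`, `origin`,
#'   `inherited_lenient`, `inherited_stringent`.
#' @export
make_inheritance_truth <- function(transcript_ids, seed = 1,
                                   class_fractions = c(
                                     stringent = 0.08, lenient_only = 0.12,
                                     zygote_only = 0.05, partial_zygote = 0.10,
                                     gamete_only = 0.25, absent = 0.40),
                                   origin_fractions = c(
                                     both_gametes = 0.90,
                                     oocyte_specific = 0.08,
                                     sperm_specific = 0.02)) {
  n <- length(transcript_ids)
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8)
  set.seed(seed)
  counts <- diff(round(cumsum(c(0, class_fractions)) * n))
  classes <- sample(rep(names(class_fractions), counts))
  inherited <- classes %in% c("stringent", "lenient_only")
  origin <- rep("none", n)
  n_inh <- sum(inherited)
  if (n_inh > 0) {
    oc <- diff(round(cumsum(c(0, origin_fractions)) * n_inh))
    origin[inherited] <- sample(rep(names(origin_fractions), oc))
  }
  data.frame(
    transcript_id = transcript_ids,
    class = classes,
    origin = origin,
    inherited_lenient = inherited,
    inherited_stringent = classes == "stringent",
    stringsAsFactors = FALSE
  )
}

# expression mask (transcript x sample) realizing a truth table on a layout
build_expression_mask <- function(truth, meta) {
  sp <- which(meta$sample_type == "sperm")
  oo <- which(meta$sample_type == "oocyte")
  zy <- which(meta$sample_type == "zygote")
  zy_by_study <- split(zy, meta$study_id[zy])
  zy_first <- vapply(zy_by_study, `[`, integer(1), 1)
  m <- matrix(FALSE, nrow(truth), nrow(meta),
              dimnames = list(truth$transcript_id, meta$sample_id))
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    org <- truth$origin[i]
    if (cls %in% c("stringent", "zygote_only")) m[i, zy] <- TRUE
    if (cls == "lenient_only") m[i, zy_first] <- TRUE
    if (cls == "partial_zygote") m[i, zy_by_study[[1]]] <- TRUE
    if (cls == "stringent") {
      if (org %in% c("both_gametes", "oocyte_specific")) m[i, oo] <- TRUE
      if (org %in% c("both_gametes", "sperm_specific")) m[i, sp] <- TRUE
    }
    if (cls == "lenient_only") {
      if (org %in% c("both_gametes", "oocyte_specific")) m[i, oo[1]] <- TRUE
      if (org %in% c("both_gametes", "sperm_specific")) m[i, sp[1]] <- TRUE
    }
    if (cls %in% c("partial_zygote", "gamete_only")) m[i, oo[1]] <- TRUE
  }
  m
}

#' Generate multi-study gamete/zygote expression tables with planted truth
#'
#' FPKM values are drawn with class-dependent location keeping a 2x margin
#' around the detection threshold: planted-expressed cells are
#' `>= expressed_min`, planted-absent cells `<= absent_max`.
#'
#' @param transcript_ids Transcripts to simulate.
#' @param truth Optional truth from [make_inheritance_truth()]; generated
#'   from `seed` when NULL.
#' @param seed RNG seed.
#' @param layout Sample metadata layout, default [paper_sample_layout()].
#' @param threshold Detection threshold the margins are built around.
#' @param expressed_min Minimum FPKM of a planted-expressed cell (must be
#'   > threshold).
#' @param absent_max Maximum FPKM of a planted-absent cell (must be
#'   < threshold).
#' @return List with `expr` (matrix), `meta`, `truth`.
#' @export
generate_expression_studies <- function(transcript_ids, truth = NULL, seed = 1,
                                        layout = paper_sample_layout(),
                                        threshold = 0.1,
                                        expressed_min = 0.2,
                                        absent_max = 0.05) {
  if (absent_max >= threshold || expressed_min <= threshold) {
    stop("margin parameters straddle the detection threshold")
  }
  meta <- validate_meta(layout)
  if (is.null(truth)) truth <- make_inheritance_truth(transcript_ids, seed = seed)
  stopifnot(identical(truth$transcript_id, transcript_ids))
  mask <- build_expression_mask(truth, meta)
  set.seed(seed + 1)
  n <- length(transcript_ids) * nrow(meta)
  lo <- matrix(stats::runif(n, 0, absent_max), nrow = length(transcript_ids))
  hi <- matrix(expressed_min + stats::rlnorm(n, meanlog = 0, sdlog = 1),
               nrow = length(transcript_ids))
  expr <- ifelse(mask, hi, lo)
  dimnames(expr) <- dimnames(mask)
  list(expr = expr, meta = meta, truth = truth)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate three-species synteny blocks with planted conservation labels
#'
#' Builds one genomic block per reference (zebrafish-surrogate) lncRNA in
#' each species: the lncRNA sits in a central gap with five protein-coding
#' genes upstream and five downstream.  Loci-conserved lncRNAs get mouse
#' and human counterpart blocks sharing `5, 6, 7, ...` orthologous flank
#' genes; decoys share `0..4`.  Overlap-conserved lncRNAs overlap an extra
#' gene whose ortholog is overlapped by the counterpart lncRNA in both
#' target species.  Sequence-conserved lncRNAs carry an exact planted
#' 60-mer shared with one mouse and one human counterpart sequence.
#'
#' @param n_loci,n_overlap,n_seq,n_decoys Class sizes.
#' @param seed RNG seed.
#' @param sequence_length Length of each lncRNA sequence (nt).
#' @return List with per-species `lnc` and `genes` transcript records
#'   (`zf`, `mouse`, `human`), `ortho` map, `sequences` (named vectors per
#'   species), and `truth` (`lncrna_id`, `class`, `shared_flanks`).
#' @export
generate_three_species_synteny <- function(n_loci = 5, n_overlap = 5,
                                           n_seq = 3, n_decoys = 10,
                                           seed = 1, sequence_length = 500) {
  set.seed(seed)
  classes <- rep(c("loci", "overlap", "seq", "decoy"),
                 c(n_loci, n_overlap, n_seq, n_decoys))
  n <- length(classes)
  shared <- integer(n)
  shared[classes == "loci"] <- 5 + (seq_len(n_loci) - 1) %% 6
  shared[classes == "decoy"] <- (seq_len(n_decoys) - 1) %% 5

  gene_start <- function(j) (j - 1) * 1500 + 1000 + if (j > 5) 1500 else 0
  mk_rec <- function(tid, gid, chrom, start, end, biotype) {
    data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
               start = start, end = end, strand = "+", biotype = biotype,
               stringsAsFactors = FALSE)
  }
  species <- c(zf = "z", mouse = "m", human = "h")
  lnc <- genes <- stats::setNames(vector("list", 3), names(species))
  seqs <- stats::setNames(vector("list", 3), names(species))
  ortho_rows <- list()

  for (sp in names(species)) {
    pre <- species[[sp]]
    lnc_rows <- list(); gene_rows <- list(); seq_vec <- character(0)
    for (i in seq_len(n)) {
      chrom <- sprintf("%s_chr%d", pre, i)
      lnc_id <- sprintf("%slnc%d", pre, i)
      for (j in 1:10) {
        st <- gene_start(j)
        # shared flank positions carry ortholog-linked genes; the rest are
        # species-private fillers absent from the ortholog map
        is_shared <- sp == "zf" || j <= shared[i]
        gid <- if (sp == "zf") sprintf("zg_%d_%d", i, j)
        else if (is_shared) sprintf("%sg_%d_%d", pre, i, j)
        else sprintf("%sf_%d_%d", pre, i, j)
        gene_rows[[length(gene_rows) + 1]] <-
          mk_rec(paste0(gid, "_t1"), gid, chrom, st, st + 1000, "protein_coding")
      }
      lnc_rows[[length(lnc_rows) + 1]] <-
        mk_rec(lnc_id, paste0(lnc_id, "_g"), chrom, 8600, 9200, "lincRNA")
      if (classes[i] == "overlap") {
        gid <- sprintf("%sgo%d", pre, i)
        gene_rows[[length(gene_rows) + 1]] <-
          mk_rec(paste0(gid, "_t1"), gid, chrom, 8900, 9600, "protein_coding")
      }
      seq_vec[lnc_id] <- random_seq(sequence_length)
    }
    lnc[[sp]] <- do.call(rbind, lnc_rows)
    genes[[sp]] <- do.call(rbind, gene_rows)
    seqs[[sp]] <- seq_vec
  }
  for (df_name in names(species)) {
    lnc[[df_name]]$exons <- lapply(seq_len(nrow(lnc[[df_name]])), function(i)
      cbind(start = lnc[[df_name]]$start[i], end = lnc[[df_name]]$end[i]))
    genes[[df_name]]$exons <- lapply(seq_len(nrow(genes[[df_name]])), function(i)
      cbind(start = genes[[df_name]]$start[i], end = genes[[df_name]]$end[i]))
  }

  for (i in seq_len(n)) {
    for (j in seq_len(shared[i])) {
      ortho_rows[[length(ortho_rows) + 1]] <- data.frame(
        zebrafish = sprintf("zg_%d_%d", i, j),
        mouse = sprintf("mg_%d_%d", i, j),
        human = sprintf("hg_%d_%d", i, j),
        stringsAsFactors = FALSE
      )
    }
    if (classes[i] == "overlap") {
      ortho_rows[[length(ortho_rows) + 1]] <- data.frame(
        zebrafish = sprintf("zgo%d", i), mouse = sprintf("mgo%d", i),
        human = sprintf("hgo%d", i), stringsAsFactors = FALSE)
    }
  }
  ortho <- if (length(ortho_rows)) do.call(rbind, ortho_rows) else
    data.frame(zebrafish = character(0), mouse = character(0),
               human = character(0))

  # plant exact shared 60-mers for the sequence-conserved class
  for (i in which(classes == "seq")) {
    segment <- random_seq(60)
    plant <- function(s, at) {
      paste0(substr(s, 1, at - 1), segment,
             substr(s, at + 60, nchar(s)))
    }
    seqs$zf[[sprintf("zlnc%d", i)]] <- plant(seqs$zf[[sprintf("zlnc%d", i)]], 201)
    seqs$mouse[[sprintf("mlnc%d", i)]] <- plant(seqs$mouse[[sprintf("mlnc%d", i)]], 101)
    seqs$human[[sprintf("hlnc%d", i)]] <- plant(seqs$human[[sprintf("hlnc%d", i)]], 301)
  }

  truth <- data.frame(
    lncrna_id = sprintf("zlnc%d", seq_len(n)),
    class = classes,
    shared_flanks = shared,
    stringsAsFactors = FALSE
  )
  list(zf = list(lnc = lnc$zf, genes = genes$zf),
       mouse = list(lnc = lnc$mouse, genes = genes$mouse),
       human = list(lnc = lnc$human, genes = genes$human),
       ortho = ortho, sequences = seqs, truth = truth)
}

#' Generate backsplice-junction tables with planted circRNA truth
#'
#' Plants inherited candidates (passing reads/ratio in designated zygote
#' and gamete samples), gamete-only and zygote-only candidates (not
#' inherited) and non-candidates (reads <= 1 or ratio <= 0.02 everywhere),
#' with backsplice coordinates realizing the requested
#' exonic/intronic/intergenic categories against the protein-coding genes
#' of `annotation`.
#'
#' @param annotation Result of [generate_genome_annotation()] (its
#'   protein-coding records are the gene space).
#' @param meta Sample metadata with zygote, oocyte and sperm samples.
#' @param inherited_categories Named counts (`exonic`, `intronic`,
#'   `intergenic`) of inherited circRNAs.
#' @param inherited_origins Named counts (`both_gametes`, `oocyte_only`,
#'   `sperm_only`) summing to the inherited total.
#' @param n_gamete_only,n_zygote_only,n_noncandidate Other planted classes.
#' @param seed RNG seed.
#' @return List with `junctions` (internal-format junction records) and
#'   `truth` (`circ_id`, `candidate`, `inherited`, `category`, `origin`,
#'   `host_genes`).
#' @export
generate_junction_tables <- function(annotation, meta,
                                     inherited_categories = c(exonic = 10,
                                                              intronic = 5,
                                                              intergenic = 5),
                                     inherited_origins = c(both_gametes = 9,
                                                           oocyte_only = 9,
                                                           sperm_only = 2),
                                     n_gamete_only = 10, n_zygote_only = 5,
                                     n_noncandidate = 15, seed = 1) {
  stopifnot(sum(inherited_categories) == sum(inherited_origins))
  set.seed(seed)
  meta <- validate_meta(meta)
  pc <- annotation$transcripts[annotation$transcripts$biotype == "protein_coding", ]
  gs <- gene_spans(pc)
  multi_exon <- pc[vapply(pc$exons, nrow, integer(1)) >= 2, ]

  n_genic <- inherited_categories[["exonic"]] + inherited_categories[["intronic"]]
  if (nrow(multi_exon) < n_genic) {
    stop("category unrealizable: annotation has too few multi-exon genes")
  }
  # gap slots after each gene (sorted within chromosome), up to 4 per gap
  gs <- gs[order(gs$chrom, gs$start), ]
  nxt <- c(gs$start[-1], Inf)
  same_chrom <- c(gs$chrom[-1] == gs$chrom[-nrow(gs)], FALSE)
  gap_width <- ifelse(same_chrom, nxt - gs$end, 3000)
  gap_slots <- expand.grid(gap = seq_len(nrow(gs)), k = 0:3)
  gap_slots <- gap_slots[gap_width[gap_slots$gap] >= 2300, ]
  n_inter <- inherited_categories[["intergenic"]] + n_gamete_only +
    n_zygote_only + n_noncandidate
  if (nrow(gap_slots) < n_inter) {
    stop("category unrealizable: annotation has too few intergenic gaps")
  }

  zy <- meta$sample_id[meta$sample_type == "zygote"]
  oo <- meta$sample_id[meta$sample_type == "oocyte"]
  sp <- meta$sample_id[meta$sample_type == "sperm"]
  rotate <- function(pool, i) pool[(i - 1) %% length(pool) + 1]

  genic_coords <- function(g, kind) {
    ex <- multi_exon$exons[[g]]
    if (kind == "exonic") {
      p1 <- ex[1, 1] + 5
      p2 <- ex[nrow(ex), 2] - 6
    } else {
      p1 <- ex[1, 2] + 5
      p2 <- ex[2, 1] - 6
    }
    list(chrom = multi_exon$chrom[g], bs_start = p1, bs_end = p2 + 1,
         host = multi_exon$gene_id[g])
  }
  gap_coords <- function(slot_i) {
    g <- gap_slots$gap[slot_i]; k <- gap_slots$k[slot_i]
    p1 <- gs$end[g] + 100 + 550 * k
    list(chrom = gs$chrom[g], bs_start = p1, bs_end = p1 + 201,
         host = NA_character_)
  }

  junc <- list(); truth <- list()
  gene_i <- 0; slot_i <- 0; circ_i <- 0
  emit <- function(coords, samples, reads, ratios, candidate, inherited,
                   category, origin) {
    circ_i <<- circ_i + 1
    circ_id <- sprintf("%s:%d-%d", coords$chrom, coords$bs_start + 1,
                       coords$bs_end)
    for (s in seq_along(samples)) {
      junc[[length(junc) + 1]] <<- data.frame(
        chrom = coords$chrom, bs_start = coords$bs_start,
        bs_end = coords$bs_end, strand = "+", sample_id = samples[s],
        junction_reads = reads[s], junction_ratio = ratios[s],
        circ_id = circ_id, stringsAsFactors = FALSE)
    }
    truth[[length(truth) + 1]] <<- data.frame(
      circ_id = circ_id, candidate = candidate, inherited = inherited,
      category = category,
      origin = origin, host_genes = coords$host %||% NA_character_,
      stringsAsFactors = FALSE)
  }

  origins <- rep(names(inherited_origins), inherited_origins)
  cat_seq <- rep(names(inherited_categories), inherited_categories)
  for (i in seq_along(cat_seq)) {
    kind <- cat_seq[i]
    if (kind == "intergenic") {
      slot_i <- slot_i + 1
      coords <- gap_coords(slot_i)
    } else {
      gene_i <- gene_i + 1
      coords <- genic_coords(gene_i, kind)
    }
    org <- origins[i]
    samples <- rotate(zy, i)
    if (org %in% c("both_gametes", "oocyte_only")) samples <- c(samples, rotate(oo, i))
    if (org %in% c("both_gametes", "sperm_only")) samples <- c(samples, rotate(sp, i))
    nr <- length(samples)
    emit(coords, samples, sample(3:20, nr, replace = TRUE),
         stats::runif(nr, 0.1, 0.9), TRUE, TRUE, kind, org)
  }
  for (i in seq_len(n_gamete_only)) {
    slot_i <- slot_i + 1
    samples <- c(rotate(oo, i), rotate(sp, i))
    emit(gap_coords(slot_i), samples, sample(3:20, 2, replace = TRUE),
         stats::runif(2, 0.1, 0.9), TRUE, FALSE, "intergenic", "none")
  }
  for (i in seq_len(n_zygote_only)) {
    slot_i <- slot_i + 1
    emit(gap_coords(slot_i), rotate(zy, i), sample(3:20, 1),
         stats::runif(1, 0.1, 0.9), TRUE, FALSE, "intergenic", "none")
  }
  for (i in seq_len(n_noncandidate)) {
    slot_i <- slot_i + 1
    samples <- c(rotate(zy, i), rotate(oo, i))
    emit(gap_coords(slot_i), samples, c(1L, sample(5:20, 1)),
         c(stats::runif(1, 0.1, 0.9), stats::runif(1, 0, 0.02)),
         FALSE, FALSE, "intergenic", "none")
  }

  junctions <- do.call(rbind, junc)
  rownames(junctions) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(junctions = junctions, truth = truth)
}

default_archetypes <- function() {
  list(
    flat_high = c(40, 40, 40, 40, 40),
    flat_low = c(1, 1, 1, 1, 1),
    falling = c(40, 4, 1, 0.6, 0.4),
    rising = c(0.4, 8, 12, 16, 20)
  )
}

#' Generate temporal profiles around planted archetypes
#'
#' Profiles are drawn in transformed space (`log2(FPKM + 1)` of the
#' archetype trajectory plus Gaussian noise) and back-transformed to FPKM.
#'
#' @param n_per_archetype Profiles per archetype.
#' @param archetypes Named list of length-5 raw trajectories; defaults to
#'   flat-high, flat-low, falling, rising.
#' @param noise_sd Noise standard deviation in transformed units; must be
#'   below half the minimum pairwise archetype separation (otherwise the
#'   planted labels are unrecoverable by design and an error is raised).
#' @param seed RNG seed.
#' @return List with `profiles` (matrix, columns `t0..t4`) and `truth`
#'   (`transcript_id`, `archetype`).
#' @export
generate_temporal_profiles <- function(n_per_archetype = 50,
                                       archetypes = default_archetypes(),
                                       noise_sd = 0.1, seed = 1) {
  if (length(archetypes) < 2) stop("need at least 2 archetypes")
  stopifnot(all(lengths(archetypes) == 5))
  tarch <- do.call(rbind, lapply(archetypes, function(a) log2(a + 1)))
  min_sep <- min(stats::dist(tarch))
  if (noise_sd >= min_sep / 2) {
    stop("noise_sd >= half the minimum archetype separation (", round(min_sep, 3),
         "); planted labels would be unrecoverable")
  }
  set.seed(seed)
  rows <- list(); labels <- character(0); ids <- character(0)
  for (an in names(archetypes)) {
    base <- log2(archetypes[[an]] + 1)
    for (i in seq_len(n_per_archetype)) {
      x <- base + stats::rnorm(5, 0, noise_sd)
      rows[[length(rows) + 1]] <- pmax(2^x - 1, 0)
      labels <- c(labels, an)
      ids <- c(ids, sprintf("tp_%s_%d", an, i))
    }
  }
  profiles <- do.call(rbind, rows)
  dimnames(profiles) <- list(ids, paste0("t", 0:4))
  list(profiles = profiles,
       truth = data.frame(transcript_id = ids, archetype = labels,
                          stringsAsFactors = FALSE))
}
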