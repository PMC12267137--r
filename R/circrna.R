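# circRNA candidate filtering from backsplice junctions, inheritance
# calling, genomic-category annotation, and circular-vs-linear comparison.
#
# Filters are applied PER SAMPLE; a candidate exists globally once it
# passes in at least one sample.  Candidate identity is the exact
# (chrom, bs_start, bs_end) triple; near-identical junctions are not merged.

#' Filter backsplice junctions into circRNA candidates
#'
#' A junction passes in a sample iff `junction_reads >= min_reads` and
#' `junction_ratio >= min_ratio` in that sample (both boundaries inclusive).
#'
#' @param junctions Junction records (see [read_junction_table()]).
#' @param min_reads Minimum backsplice reads per sample, default 2.
#' @param min_ratio Minimum junction ratio per sample, default 0.05.
#' @return List with `junctions` (input plus logical `pass`) and
#'   `candidates`: one row per junction coordinate passing in >= 1 sample,
#'   with list-column `passing_samples`.
#' @export
filter_circ_candidates <- function(junctions, min_reads = 2, min_ratio = 0.05) {
  pass <- junctions$junction_reads >= min_reads &
    junctions$junction_ratio >= min_ratio
  junctions$pass <- pass
  pj <- junctions[pass, , drop = FALSE]
  by_circ <- split(seq_len(nrow(pj)), pj$circ_id)
  ids <- names(by_circ)
  first <- vapply(by_circ, `[`, integer(1), 1)
  candidates <- data.frame(
    circ_id = ids,
    chrom = pj$chrom[first],
    bs_start = pj$bs_start[first],
    bs_end = pj$bs_end[first],
    strand = pj$strand[first],
    stringsAsFactors = FALSE
  )
  candidates$passing_samples <- lapply(by_circ, function(i) sort(unique(pj$sample_id[i])))
  candidates <- candidates[order(candidates$chrom, candidates$bs_start,
                                 candidates$bs_end), ]
  rownames(candidates) <- NULL
  list(junctions = junctions, candidates = candidates)
}

#' Inheritance call for circRNA candidates
#'
#' A candidate is inherited iff it passes the per-sample filter in at least
#' one zygote sample and in at least one gamete (sperm or oocyte) sample.
#' Origin: `oocyte_only` iff no sperm sample passes, `sperm_only` iff no
#' oocyte sample passes, otherwise `both_gametes`; `none` for
#' non-inherited candidates.
#'
#' @param candidates Candidate table from [filter_circ_candidates()].
#' @param meta Sample metadata.
#' @return `candidates` with added logical `inherited` and `origin`.
#' @export
classify_circ_inherited <- function(candidates, meta) {
  meta <- validate_meta(meta)
  type_of <- stats::setNames(meta$sample_type, meta$sample_id)
  n <- nrow(candidates)
  inherited <- logical(n)
  origin <- rep("none", n)
  for (i in seq_len(n)) {
    types <- type_of[candidates$passing_samples[[i]]]
    if (anyNA(types)) {
      stop("candidate ", candidates$circ_id[i],
           " passes in a sample without metadata")
    }
    zy <- any(types == "zygote")
    sp <- any(types == "sperm")
    oo <- any(types == "oocyte")
    inherited[i] <- zy && (sp || oo)
    if (inherited[i]) {
      origin[i] <- if (oo && !sp) "oocyte_only"
      else if (sp && !oo) "sperm_only"
      else "both_gametes"
    }
  }
  candidates$inherited <- inherited
  candidates$origin <- origin
  candidates
}

#' Genomic category and host genes of circRNA candidates
#'
#' The two backsplice coordinates are treated as point positions.  A
#' candidate is intergenic iff both points fall outside all gene spans;
#' exonic iff at least one point falls inside an annotated exon; intronic
#' iff at least one point falls inside a gene span but neither is in an
#' exon.  Host genes are all genes containing either point (a circRNA may
#' span more than one gene).
#'
#' @param candidates Candidate table.
#' @param annotation Transcript records to treat as the gene annotation
#'   (typically the protein-coding records; exon structure is used for the
#'   exonic/intronic distinction).
#' @return `candidates` with added `category`
#'   ("exonic"/"intronic"/"intergenic") and list-column `host_genes`.
#' @export
annotate_circ_category <- function(candidates, annotation) {
  genes <- gene_spans(annotation)
  ex_df <- data.frame(
    gene_id = rep(annotation$gene_id, vapply(annotation$exons, nrow, integer(1))),
    chrom = rep(annotation$chrom, vapply(annotation$exons, nrow, integer(1))),
    start = unlist(lapply(annotation$exons, function(m) m[, 1])),
    end = unlist(lapply(annotation$exons, function(m) m[, 2])),
    stringsAsFactors = FALSE
  )
  # the two junction points: first and last base of the circle (0-based)
  pts_chrom <- rep(candidates$chrom, 2)
  pts_pos <- c(candidates$bs_start, candidates$bs_end - 1)
  pr <- as_granges0(pts_chrom, pts_pos, pts_pos + 1)
  gr_gene <- as_granges0(genes$chrom, genes$start, genes$end)
  gr_exon <- as_granges0(ex_df$chrom, ex_df$start, ex_df$end)
  hg <- as.matrix(suppressWarnings(GenomicRanges::findOverlaps(pr, gr_gene)))
  he <- as.matrix(suppressWarnings(GenomicRanges::findOverlaps(pr, gr_exon)))

  n <- nrow(candidates)
  cand_of_pt <- rep(seq_len(n), 2)
  in_gene <- tabulate(cand_of_pt[hg[, 1]], nbins = n) > 0
  in_exon <- tabulate(cand_of_pt[he[, 1]], nbins = n) > 0
  hosts <- split(genes$gene_id[hg[, 2]],
                 factor(cand_of_pt[hg[, 1]], levels = seq_len(n)))
  hosts <- lapply(hosts, function(g) sort(unique(g)))

  candidates$category <- ifelse(in_exon, "exonic",
                                ifelse(in_gene, "intronic", "intergenic"))
  candidates$host_genes <- unname(hosts)
  candidates
}

#' Compare circular and linear expression of inherited circRNAs
#'
#' Circular abundance is normalized as junction reads per million total
#' backsplice reads in the sample, averaged over zygote samples (samples
#' without a record of the junction count as 0 reads).  Linear expression
#' of the host is the maximum, over the host genes' transcripts, of the
#' mean zygote FPKM.  A candidate whose normalized circular abundance
#' exceeds its linear host (ratio > 1, including a zero-expression host
#' with a present circle, reported as an infinite ratio) is flagged
#' `circ_exceeds_linear`.  Intergenic candidates have no host and get an
#' NA linear value with flag `no_host`.
#'
#' @param candidates Annotated candidate table (with `host_genes`).
#' @param junctions Full junction table (used for per-sample backsplice
#'   read totals).
#' @param linear_expr Transcript-level FPKM matrix.
#' @param meta Sample metadata for `linear_expr` and `junctions` samples.
#' @param transcript_gene Data frame mapping `transcript_id` to `gene_id`
#'   for `linear_expr` rows.
#' @return Data frame: `circ_id`, `category`, `host_genes`
#'   (semicolon-joined), `circ_norm`, `linear_fpkm`, `ratio`, `flag`.
#' @export
circ_vs_linear <- function(candidates, junctions, linear_expr, meta,
                           transcript_gene) {
  meta <- validate_meta(meta)
  totals <- tapply(junctions$junction_reads, junctions$sample_id, sum)
  zy_samples <- meta$sample_id[meta$sample_type == "zygote"]
  zy_j <- intersect(zy_samples, names(totals))
  if (!length(zy_j)) stop("no zygote samples in the junction table")

  reads_of <- function(circ_id, sample) {
    r <- junctions$junction_reads[junctions$circ_id == circ_id &
                                    junctions$sample_id == sample]
    if (length(r)) sum(r) else 0
  }
  zy_expr <- intersect(zy_samples, colnames(linear_expr))
  gene_of <- stats::setNames(transcript_gene$gene_id, transcript_gene$transcript_id)

  n <- nrow(candidates)
  circ_norm <- linear_fpkm <- ratio <- numeric(n)
  flag <- character(n)
  for (i in seq_len(n)) {
    rpm <- vapply(zy_j, function(s) {
      1e6 * reads_of(candidates$circ_id[i], s) / totals[[s]]
    }, numeric(1))
    circ_norm[i] <- mean(rpm)
    hosts <- candidates$host_genes[[i]]
    if (!length(hosts)) {
      linear_fpkm[i] <- NA_real_
      ratio[i] <- NA_real_
      flag[i] <- "no_host"
      next
    }
    tx <- names(gene_of)[gene_of %in% hosts]
    tx <- intersect(tx, rownames(linear_expr))
    linear_fpkm[i] <- if (length(tx) && length(zy_expr)) {
      max(rowMeans(linear_expr[tx, zy_expr, drop = FALSE]))
    } else 0
    ratio[i] <- if (linear_fpkm[i] == 0 && circ_norm[i] > 0) Inf
    else if (linear_fpkm[i] == 0) NA_real_
    else circ_norm[i] / linear_fpkm[i]
    flag[i] <- if (!is.na(ratio[i]) && ratio[i] > 1) "circ_exceeds_linear"
    else "linear_exceeds_circ"
  }
  data.frame(
    circ_id = candidates$circ_id,
    category = candidates$category,
    host_genes = join_ids(candidates$host_genes),
    circ_norm = circ_norm,
    linear_fpkm = linear_fpkm,
    ratio = ratio,
    flag = flag,
    stringsAsFactors = FALSE
  )
}

#' Chromosome distribution of circRNA candidates
#'
#' @param candidates Candidate table.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_bins Bins for the scaled positional histogram, default 100.
#' @return List with `per_chrom` (data frame: `chrom`, `count`,
#'   `density_per_mb`) and `scaled` (result of [scaled_density()] on the
#'   backsplice intervals).
#' @export
circ_chromosome_distribution <- function(candidates, chrom_lengths,
                                         n_bins = 100) {
  unknown <- setdiff(unique(candidates$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("no chromosome length for: ", paste(unknown, collapse = ", "))
  }
  counts <- table(factor(candidates$chrom, levels = names(chrom_lengths)))
  per_chrom <- data.frame(
    chrom = names(chrom_lengths),
    count = as.integer(counts),
    density_per_mb = as.integer(counts) / (chrom_lengths / 1e6),
    stringsAsFactors = FALSE
  )
  fake_tx <- data.frame(
    transcript_id = candidates$circ_id,
    chrom = candidates$chrom,
    start = candidates$bs_start,
    end = candidates$bs_end,
    stringsAsFactors = FALSE
  )
  list(per_chrom = per_chrom,
       scaled = scaled_density(fake_tx, chrom_lengths, n_bins = n_bins))
}
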