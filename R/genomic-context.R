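# Genomic context of lncRNAs: genic/intergenic classification by span
# overlap with protein-coding loci (strand-ignored, unstranded analysis),
# flanking-gene extraction, chromosome-scaled density, adult-tissue breadth.

#' Collapse transcript records to gene spans
#'
#' @param records Transcript records (as from [parse_gtf()]).
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (union span over the gene's transcripts), `biotype` (of the
#'   first transcript).
#' @export
gene_spans <- function(records) {
  by_gene <- split(seq_len(nrow(records)), records$gene_id)
  out <- data.frame(
    gene_id = names(by_gene),
    chrom = vapply(by_gene, function(i) records$chrom[i[1]], character(1)),
    start = vapply(by_gene, function(i) min(records$start[i]), numeric(1)),
    end = vapply(by_gene, function(i) max(records$end[i]), numeric(1)),
    biotype = vapply(by_gene, function(i) records$biotype[i[1]], character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$gene_id), ]
  rownames(out) <- NULL
  out
}

# GRanges from internal half-open intervals (1-based inclusive inside)
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Classify lncRNAs as genic or intergenic
#'
#' A lncRNA is genic iff its transcript span intersects at least one
#' protein-coding gene span by >= 1 bp, strand ignored (half-open intervals:
#' a lncRNA ending exactly where a gene starts does not overlap).  The
#' subcategory is biotype-driven for genic lncRNAs: biotype "antisense"
#' gives subcategory "antisense", any other overlapping biotype gives
#' "sense_overlapping"; non-overlapping lncRNAs are "intergenic" regardless
#' of biotype.
#'
#' @param lncrnas Transcript records of the lncRNAs.
#' @param genes Gene spans (data frame with `gene_id`, `chrom`, `start`,
#'   `end`), typically `gene_spans()` of the protein-coding annotation.
#' @return Data frame: `transcript_id`, `category` ("genic"/"intergenic"),
#'   `subcategory` ("antisense"/"sense_overlapping"/"intergenic"), and
#'   list-column `overlapping_genes`.
#' @export
classify_genic_intergenic <- function(lncrnas, genes) {
  unknown <- setdiff(unique(lncrnas$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("lncRNA chromosome(s) absent from gene annotation, classified ",
            "intergenic: ", paste(unknown, collapse = ", "))
  }
  q <- as_granges0(lncrnas$chrom, lncrnas$start, lncrnas$end)
  s <- as_granges0(genes$chrom, genes$start, genes$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE))
  hm <- as.matrix(hits)
  ov <- split(genes$gene_id[hm[, 2]], factor(hm[, 1], levels = seq_len(nrow(lncrnas))))
  ov <- lapply(ov, function(g) sort(unique(g)))
  genic <- lengths(ov) > 0
  subcat <- ifelse(!genic, "intergenic",
                   ifelse(lncrnas$biotype == "antisense", "antisense",
                          "sense_overlapping"))
  out <- data.frame(
    transcript_id = lncrnas$transcript_id,
    category = ifelse(genic, "genic", "intergenic"),
    subcategory = subcat,
    stringsAsFactors = FALSE
  )
  out$overlapping_genes <- unname(ov)
  out
}

#' Nearest flanking protein-coding genes
#'
#' For each lncRNA, up to `n_up` genes wholly upstream (gene end <= lncRNA
#' start, in reference orientation) and `n_down` wholly downstream (gene
#' start >= lncRNA end), ordered by increasing edge-to-edge distance.  Genes
#' overlapping the lncRNA are excluded from both flank lists.  Ties are
#' broken by lower gene start, then lexicographic gene id.
#'
#' @param lncrnas Transcript records of the lncRNAs.
#' @param genes Gene spans data frame.
#' @param n_up,n_down Maximum flank sizes, default 5 each.
#' @return Data frame with `transcript_id` and list-columns `flank_up`,
#'   `flank_down` of gene ids ordered by increasing distance.
#' @export
get_flanking_genes <- function(lncrnas, genes, n_up = 5, n_down = 5) {
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  flank_up <- vector("list", nrow(lncrnas))
  flank_down <- vector("list", nrow(lncrnas))
  for (i in seq_len(nrow(lncrnas))) {
    gi <- by_chrom[[lncrnas$chrom[i]]]
    if (is.null(gi)) {
      flank_up[[i]] <- character(0)
      flank_down[[i]] <- character(0)
      next
    }
    gs <- genes$start[gi]; ge <- genes$end[gi]; gid <- genes$gene_id[gi]
    up <- which(ge <= lncrnas$start[i])
    dn <- which(gs >= lncrnas$end[i])
    ord_up <- up[order(lncrnas$start[i] - ge[up], gs[up], gid[up])]
    ord_dn <- dn[order(gs[dn] - lncrnas$end[i], gs[dn], gid[dn])]
    flank_up[[i]] <- gid[utils::head(ord_up, n_up)]
    flank_down[[i]] <- gid[utils::head(ord_dn, n_down)]
  }
  out <- data.frame(
    transcript_id = lncrnas$transcript_id,
    stringsAsFactors = FALSE
  )
  out$flank_up <- flank_up
  out$flank_down <- flank_down
  out
}

#' Neighboring protein-coding genes for enrichment export
#'
#' Union of the overlapping genes of genic lncRNAs and the single nearest
#' upstream plus single nearest downstream gene of intergenic lncRNAs,
#' deduplicated; intended as input to external GO-enrichment tools.
#'
#' @param context Result of [classify_genic_intergenic()].
#' @param flanks Result of [get_flanking_genes()] for the same lncRNAs.
#' @return Sorted character vector of unique gene ids.
#' @export
neighbor_genes_for_enrichment <- function(context, flanks) {
  stopifnot(identical(context$transcript_id, flanks$transcript_id))
  genes <- character(0)
  for (i in seq_len(nrow(context))) {
    if (context$category[i] == "genic") {
      genes <- c(genes, context$overlapping_genes[[i]])
    } else {
      genes <- c(genes, utils::head(flanks$flank_up[[i]], 1),
                 utils::head(flanks$flank_down[[i]], 1))
    }
  }
  sort(unique(genes))
}

#' Chromosome-scaled positional density
#'
#' Each transcript is mapped to a scaled position
#' `1000 * midpoint / chromosome length` (0 = chromosome start, 1000 = end)
#' and histogrammed over `n_bins` equal-width bins on \[0, 1000\]; a position
#' of exactly 1000 falls in the last bin.
#'
#' @param transcripts Transcript records.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param n_bins Number of bins, default 100.
#' @param per_chromosome If TRUE, also return a chromosome x bin count table.
#' @return List with `n_bins`, `bin_counts` (integer vector summing to the
#'   transcript count), `positions` (scaled midpoints), and optionally
#'   `per_chromosome`.
#' @export
scaled_density <- function(transcripts, chrom_lengths, n_bins = 100,
                           per_chromosome = FALSE) {
  unknown <- setdiff(unique(transcripts$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("no chromosome length for: ", paste(unknown, collapse = ", "))
  }
  len <- chrom_lengths[transcripts$chrom]
  if (any(transcripts$end > len)) {
    stop("transcript beyond chromosome length: ",
         transcripts$transcript_id[which(transcripts$end > len)[1]])
  }
  pos <- 1000 * ((transcripts$start + transcripts$end) / 2) / len
  bin <- pmin(floor(pos / (1000 / n_bins)) + 1, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  out <- list(n_bins = n_bins, bin_counts = counts,
              positions = stats::setNames(pos, transcripts$transcript_id))
  if (per_chromosome) {
    out$per_chromosome <- as.matrix(table(
      factor(transcripts$chrom, levels = names(chrom_lengths)),
      factor(bin, levels = seq_len(n_bins))
    ))
  }
  out
}

#' Adult-tissue expression breadth and clustering order
#'
#' Replicate samples of the same tissue are averaged (arithmetic mean FPKM)
#' first; breadth is the number of distinct tissues whose mean FPKM reaches
#' the threshold (inclusive).  Transcripts are also ordered by hierarchical
#' clustering (average linkage, Euclidean distance) of their
#' `log2(mean FPKM + 1)` profiles.
#'
#' @param expr_adult FPKM matrix restricted (or restrictable) to
#'   adult-tissue samples.
#' @param meta Sample metadata; rows with `sample_type == "adult_tissue"`
#'   and a `tissue_name` are used.
#' @param threshold Inclusive FPKM threshold, default 0.1.
#' @return List with `breadth` (named integer vector), `tissue_means`
#'   (transcripts x tissues matrix), `order` (row order from clustering)
#'   and `hclust` (the tree, NULL for < 3 transcripts).
#' @export
tissue_breadth <- function(expr_adult, meta, threshold = 0.1) {
  meta <- validate_meta(meta)
  meta <- meta[match(colnames(expr_adult), meta$sample_id), ]
  keep <- meta$sample_type == "adult_tissue"
  if (!any(keep)) stop("no adult-tissue samples in metadata")
  expr <- expr_adult[, keep, drop = FALSE]
  tissue <- meta$tissue_name[keep]
  tissues <- unique(tissue)
  means <- vapply(tissues, function(tn) {
    rowMeans(expr[, tissue == tn, drop = FALSE])
  }, numeric(nrow(expr)))
  means <- matrix(means, nrow = nrow(expr),
                  dimnames = list(rownames(expr), tissues))
  breadth <- rowSums(is_expressed(means, threshold))
  ord <- seq_len(nrow(means))
  hc <- NULL
  if (nrow(means) >= 3) {
    hc <- stats::hclust(stats::dist(log2(means + 1)), method = "average")
    ord <- hc$order
  }
  list(breadth = breadth, tissue_means = means, order = ord, hclust = hc)
}
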