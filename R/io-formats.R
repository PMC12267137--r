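# Readers/writers for the external formats and the in-memory data model.
#
# Internal coordinate convention: 0-based, half-open [start, end).  GTF and
# junction tables are 1-based inclusive on disk; conversion happens only at
# the I/O boundary.  Strand is stored but never used in overlap tests (the
# analysis is unstranded throughout).

#' lncRNA biotype whitelist
#'
#' The seven Ensembl transcript biotypes treated as long non-coding RNA.
#'
#' @return Character vector of the seven biotypes.
#' @export
lncrna_biotypes <- function() {
  c("antisense", "lncRNA", "lincRNA", "retained_intron",
    "sense_intronic", "sense_overlapping", "processed_transcript")
}

# merge sorted possibly-overlapping intervals given as a 2-column matrix
merge_intervals <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' Parse an Ensembl-dialect GTF into transcript records
#'
#' Builds one record per transcript from its exon features.  GTF 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention.  The biotype is read from the `transcript_biotype` attribute,
#' falling back to `gene_biotype`, falling back to the GTF source column
#' (Ensembl releases differ in where they put it).
#'
#' @param path Path to a tab-separated 9-column GTF file.
#' @param biotype_whitelist Optional character vector; when given, only
#'   transcripts whose biotype is in the set are returned.
#' @return A data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open span over all exons), `strand`,
#'   `biotype`, and a list-column `exons` of 2-column matrices of sorted,
#'   merged exon intervals.
#' @export
parse_gtf <- function(path, biotype_whitelist = NULL) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- body[which(nfield < 9)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }

  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  get_attr <- function(name) {
    if (name %in% names(md)) as.character(md[[name]]) else rep(NA_character_, length(gr))
  }
  tid <- get_attr("transcript_id")
  gid <- get_attr("gene_id")
  t_bio <- get_attr("transcript_biotype")
  g_bio <- get_attr("gene_biotype")
  src <- as.character(md$source)
  biotype_row <- ifelse(!is.na(t_bio), t_bio, ifelse(!is.na(g_bio), g_bio, src))

  is_exon <- type == "exon"
  if (!any(is_exon)) {
    declared <- unique(tid[type == "transcript" & !is.na(tid)])
    if (length(declared)) stop("transcript ", declared[1], " has no exon features")
    stop("GTF contains no exon features: ", path)
  }
  declared <- unique(tid[type == "transcript" & !is.na(tid)])
  missing_ex <- setdiff(declared, unique(tid[is_exon]))
  if (length(missing_ex)) {
    stop("transcript ", missing_ex[1], " has no exon features")
  }

  ex <- data.frame(
    transcript_id = tid[is_exon],
    gene_id = gid[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    biotype = biotype_row[is_exon],
    stringsAsFactors = FALSE
  )
  ex$strand[!ex$strand %in% c("+", "-")] <- "."

  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  recs <- lapply(by_tx, function(i) {
    exons <- merge_intervals(cbind(ex$start[i], ex$end[i]))
    colnames(exons) <- c("start", "end")
    list(
      transcript_id = ex$transcript_id[i[1]],
      gene_id = ex$gene_id[i[1]],
      chrom = ex$chrom[i[1]],
      start = min(exons[, 1]),
      end = max(exons[, 2]),
      strand = ex$strand[i[1]],
      biotype = ex$biotype[i[1]],
      exons = exons
    )
  })
  out <- data.frame(
    transcript_id = vapply(recs, `[[`, character(1), "transcript_id"),
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, `[[`, numeric(1), "start"),
    end = vapply(recs, `[[`, numeric(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    biotype = vapply(recs, `[[`, character(1), "biotype"),
    stringsAsFactors = FALSE
  )
  out$exons <- lapply(recs, `[[`, "exons")
  out <- out[order(out$chrom, out$start, out$transcript_id), ]
  rownames(out) <- NULL
  if (!is.null(biotype_whitelist)) {
    out <- out[out$biotype %in% biotype_whitelist, ]
    rownames(out) <- NULL
  }
  out
}

#' Write transcript records as Ensembl-dialect GTF
#'
#' Emits one `transcript` line and one `exon` line per exon, converting the
#' internal 0-based half-open coordinates back to GTF 1-based inclusive.
#'
#' @param records Transcript records as returned by [parse_gtf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(records, path) {
  fmt_attrs <- function(gid, tid, bio) {
    sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
            gid, tid, bio)
  }
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    at <- fmt_attrs(r$gene_id, r$transcript_id, r$biotype)
    lines <- c(lines, paste(r$chrom, "inheritscan", "transcript",
                            format(r$start + 1, scientific = FALSE),
                            format(r$end, scientific = FALSE),
                            ".", r$strand, ".", at, sep = "\t"))
    ex <- records$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(r$chrom, "inheritscan", "exon",
                              format(ex[j, 1] + 1, scientific = FALSE),
                              format(ex[j, 2], scientific = FALSE),
                              ".", r$strand, ".", at, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Restrict transcript records to lncRNA biotypes
#'
#' Exact, case-sensitive match against the seven-member whitelist of
#' [lncrna_biotypes()] (or a caller-supplied set).
#'
#' @param records Transcript records.
#' @param whitelist Character vector of biotypes to keep.
#' @return The subset of `records` whose biotype is whitelisted.
#' @export
filter_lncrna_biotypes <- function(records, whitelist = lncrna_biotypes()) {
  out <- records[records$biotype %in% whitelist, ]
  rownames(out) <- NULL
  out
}

#' Read a transcript-by-sample FPKM table with sample metadata
#'
#' @param path TSV with a transcript-id first column and one column per
#'   sample.  Missing cells are treated as 0 FPKM (quantifiers emit explicit
#'   zeros; absence means the transcript was filtered) with a message.
#' @param meta_path TSV with one row per sample; must contain columns
#'   `sample_id`, `study_id`, `species`, `sample_type` (see [sample_types()]),
#'   optionally `tissue_name`.
#' @return A list with `expr` (numeric matrix, transcripts x samples) and
#'   `meta` (data frame, rows ordered as the expression columns).
#' @export
read_expression_table <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ID in expression table: ", ids[duplicated(ids)][1])
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (anyNA(mat)) {
    message("expression table: ", sum(is.na(mat)), " missing cell(s) set to 0 FPKM")
    mat[is.na(mat)] <- 0
  }
  if (any(mat < 0)) stop("negative FPKM value in expression table")

  meta <- utils::read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- validate_meta(meta)
  unmatched <- setdiff(colnames(mat), meta$sample_id)
  if (length(unmatched)) {
    stop("expression column(s) without sample metadata: ",
         paste(unmatched, collapse = ", "))
  }
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  rownames(meta) <- NULL
  list(expr = mat, meta = meta)
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with transcript row names and sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(transcript_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param meta Sample metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a three-species ortholog map
#'
#' Biomart-style table of one-to-one-to-one gene-id triplets.  Lookup is
#' symmetric: any species column can be used as key.
#'
#' @param path TSV with header columns `zebrafish`, `mouse`, `human`.
#' @return Data frame with those three character columns.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("zebrafish", "mouse", "human")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("ortholog map is missing column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[, req]
  empty <- !stats::complete.cases(tab) | tab$zebrafish == "" | tab$mouse == "" | tab$human == ""
  if (any(empty)) stop("ortholog map row ", which(empty)[1], " has an empty field")
  tab
}

#' Write an ortholog map as TSV
#' @param ortho Data frame with columns `zebrafish`, `mouse`, `human`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(ortho, path) {
  utils::write.table(ortho, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

alignment_hit_columns <- function() {
  c("query_id", "subject_id", "percent_identity", "alignment_length",
    "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
    "e_value", "bit_score")
}

#' Read tabular pairwise sequence-alignment hits
#'
#' Standard 12-column tabular hit format, with or without a header line.
#'
#' @param path TSV path.
#' @return Data frame with the 12 standard columns (see source for names).
#' @export
read_alignment_hits <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("query_id", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("alignment hit table must have 12 columns")
  tab <- tab[, 1:12]
  names(tab) <- alignment_hit_columns()
  if (any(tab$alignment_length < 1)) stop("alignment hit with length < 1")
  if (any(tab$e_value < 0)) stop("alignment hit with negative e-value")
  tab
}

#' Write alignment hits as headered TSV
#' @param hits Data frame as from [read_alignment_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a backsplice-junction table
#'
#' Accepts detection-tool style TSV with columns `chrom`, `start`, `end`
#' (1-based inclusive backsplice coordinates), `strand`, `sample_id`,
#' `junction_reads`, `junction_ratio`; extra columns are ignored.
#'
#' @param path TSV path.
#' @return Data frame with internal 0-based half-open `bs_start`/`bs_end`,
#'   plus `circ_id` (`chrom:start-end` in the external 1-based convention).
#' @export
read_junction_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "strand", "sample_id",
           "junction_reads", "junction_ratio")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("junction table is missing column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[, req]
  if (any(tab$start >= tab$end)) {
    stop("junction row ", which(tab$start >= tab$end)[1], ": start must be < end")
  }
  if (any(tab$junction_ratio < 0 | tab$junction_ratio > 1)) {
    bad <- which(tab$junction_ratio < 0 | tab$junction_ratio > 1)[1]
    stop("junction row ", bad, ": junction_ratio outside [0, 1]")
  }
  if (any(tab$junction_reads < 0)) stop("negative junction read count")
  data.frame(
    chrom = as.character(tab$chrom),
    bs_start = tab$start - 1L,
    bs_end = tab$end,
    strand = as.character(tab$strand),
    sample_id = as.character(tab$sample_id),
    junction_reads = as.integer(tab$junction_reads),
    junction_ratio = tab$junction_ratio,
    circ_id = paste0(tab$chrom, ":", tab$start, "-", tab$end),
    stringsAsFactors = FALSE
  )
}

#' Write junction records as TSV (external 1-based coordinates)
#' @param junctions Data frame as from [read_junction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path) {
  out <- data.frame(
    chrom = junctions$chrom,
    start = junctions$bs_start + 1L,
    end = junctions$bs_end,
    strand = junctions$strand,
    sample_id = junctions$sample_id,
    junction_reads = junctions$junction_reads,
    junction_ratio = junctions$junction_ratio,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export intervals as BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates are written unchanged.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `name`; optional
#'   `score` and `strand` default to 0 and ".".
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom,
    start = format(df$start, scientific = FALSE, trim = TRUE),
    end = format(df$end, scientific = FALSE, trim = TRUE),
    name = df$name,
    score = df$score %||% rep(0, nrow(df)),
    strand = df$strand %||% rep(".", nrow(df)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
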