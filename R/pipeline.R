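# End-to-end orchestration from a key=value config file: classify ->
# context -> conserve (optional) -> circ -> temporal, with summary tables
# whose percentage columns are always recomputable from the count columns
# in the same file.  Stage outputs are plain TSVs; there is no hidden state.

#' Read a key=value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values that
#' parse as numbers become numeric.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("config line not of the form key = value: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

default_config <- function() {
  list(threshold = 0.1, rule = "lenient", min_reads = 2, min_ratio = 0.05,
       k = 4, seed = 1, n_bins = 100)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the inheritance pipeline end-to-end
#'
#' Executes the configured stages on file inputs and writes per-stage
#' TSVs plus a summary table and a run log into `out_dir`.  Required config
#' keys: `expr`, `meta`, `gtf`, `out_dir`.  Optional: `junctions` (enables
#' the circRNA stage), `timecourse_expr`/`timecourse_meta` (temporal
#' stage), `chrom_sizes` (two-column TSV enabling density outputs), and
#' threshold overrides (`threshold`, `rule`, `min_reads`, `min_ratio`,
#' `k`, `seed`).  Any stage failure aborts with the stage name.
#'
#' @param config Named list or path to a key=value config file.
#' @return Invisibly, a list of the in-memory stage results plus `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- read_run_config(config)
  } else {
    config_path <- NULL
  }
  cfg <- utils::modifyList(default_config(), config)
  for (key in c("expr", "meta", "gtf", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("inheritscan version: ", as.character(utils::packageVersion("inheritscan"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", cfg$seed),
    vapply(setdiff(names(cfg), "out_dir"), function(k)
      paste0("param ", k, " = ", cfg[[k]]), character(1))
  )
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  summary_rows <- list()
  add_summary <- function(stage, metric, count, denominator = NA) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      stage = stage, metric = metric, count = count,
      denominator = denominator,
      percentage = if (!is.na(denominator) && denominator > 0)
        100 * count / denominator else NA_real_,
      stringsAsFactors = FALSE)
  }
  results <- list()

  ## classify ----
  io <- stage("load", function() read_expression_table(cfg$expr, cfg$meta))
  ann <- stage("annotation", function() parse_gtf(cfg$gtf))
  lnc <- filter_lncrna_biotypes(ann)
  lnc <- lnc[lnc$transcript_id %in% rownames(io$expr), , drop = FALSE]
  calls <- stage("classify", function() {
    expr_lnc <- io$expr[lnc$transcript_id, , drop = FALSE]
    classify_inheritance(expr_lnc, io$meta, rule = cfg$rule,
                         threshold = cfg$threshold)
  })
  results$calls <- calls
  write_tsv(calls, file.path(cfg$out_dir, "calls.tsv"))
  n_lnc <- nrow(calls)
  inh_ids <- calls$transcript_id[calls$status == "inherited"]
  add_summary("classify", "lncrna_total", n_lnc)
  add_summary("classify", "inherited", length(inh_ids), n_lnc)
  for (org in c("both_gametes", "oocyte_specific", "sperm_specific")) {
    add_summary("classify", paste0("origin_", org),
                sum(calls$origin == org), length(inh_ids))
  }

  ## context ----
  genes <- gene_spans(ann[ann$biotype == "protein_coding", , drop = FALSE])
  context <- stage("context", function() classify_genic_intergenic(lnc, genes))
  flanks <- stage("context", function() get_flanking_genes(lnc, genes))
  ctx_out <- data.frame(
    transcript_id = context$transcript_id,
    category = context$category,
    subcategory = context$subcategory,
    overlapping_genes = join_ids(context$overlapping_genes),
    flank_up = join_ids(flanks$flank_up),
    flank_down = join_ids(flanks$flank_down),
    stringsAsFactors = FALSE
  )
  results$context <- context
  results$flanks <- flanks
  write_tsv(ctx_out, file.path(cfg$out_dir, "context.tsv"))
  add_summary("context", "genic", sum(context$category == "genic"), n_lnc)
  add_summary("context", "intergenic", sum(context$category == "intergenic"), n_lnc)

  if (!is.null(cfg$chrom_sizes)) {
    cs <- utils::read.delim(cfg$chrom_sizes, header = FALSE,
                            stringsAsFactors = FALSE)
    chrom_lengths <- stats::setNames(cs[[2]], cs[[1]])
    dens <- stage("density", function()
      scaled_density(lnc, chrom_lengths, n_bins = cfg$n_bins))
    write_tsv(data.frame(bin = seq_len(dens$n_bins), count = dens$bin_counts),
              file.path(cfg$out_dir, "density.tsv"))
    results$density <- dens
  }

  ## circ ----
  if (!is.null(cfg$junctions)) {
    circ <- stage("circ", function() {
      j <- read_junction_table(cfg$junctions)
      f <- filter_circ_candidates(j, min_reads = cfg$min_reads,
                                  min_ratio = cfg$min_ratio)
      cand <- classify_circ_inherited(f$candidates, io$meta)
      annotate_circ_category(cand, ann[ann$biotype == "protein_coding", ,
                                       drop = FALSE])
    })
    circ_out <- data.frame(
      circ_id = circ$circ_id, chrom = circ$chrom,
      start = circ$bs_start + 1L, end = circ$bs_end,
      inherited = circ$inherited, origin = circ$origin,
      category = circ$category, host_genes = join_ids(circ$host_genes),
      passing_samples = join_ids(circ$passing_samples),
      stringsAsFactors = FALSE
    )
    results$circ <- circ
    write_tsv(circ_out, file.path(cfg$out_dir, "circ.tsv"))
    add_summary("circ", "candidates", nrow(circ))
    add_summary("circ", "inherited", sum(circ$inherited), nrow(circ))
    for (cat in c("exonic", "intronic", "intergenic")) {
      add_summary("circ", paste0("category_", cat),
                  sum(circ$category == cat), nrow(circ))
    }
  }

  ## temporal ----
  if (!is.null(cfg$timecourse_expr)) {
    groups <- stage("temporal", function() {
      ts <- read_expression_table(cfg$timecourse_expr,
                                  cfg$timecourse_meta %||% cfg$meta)
      prof <- average_timepoint_replicates(ts$expr, ts$meta)
      cl <- cluster_profiles(prof, k = cfg$k, seed = cfg$seed,
                             center = isTRUE(cfg$center %||% TRUE))
      labels <- label_stability(cl$group_means_raw)
      cl$assignment$stability_label <- labels[cl$assignment$group_rank]
      cl
    })
    results$temporal <- groups
    write_tsv(groups$assignment, file.path(cfg$out_dir, "groups.tsv"))
    write_tsv(data.frame(group = rownames(groups$group_means_raw),
                         groups$group_means_raw),
              file.path(cfg$out_dir, "centroids.tsv"))
    for (g in seq_along(groups$sizes)) {
      add_summary("temporal", paste0("group_", g), groups$sizes[g],
                  nrow(groups$assignment))
    }
  }

  summary <- do.call(rbind, summary_rows)
  results$summary <- summary
  write_tsv(summary, file.path(cfg$out_dir, "summary.tsv"))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  if (!is.null(config_path)) {
    file.copy(config_path, file.path(cfg$out_dir, "config_snapshot.cfg"),
              overwrite = TRUE)
  } else {
    writeLines(vapply(names(cfg), function(k) paste0(k, " = ", cfg[[k]]),
                      character(1)),
               file.path(cfg$out_dir, "config_snapshot.cfg"))
  }
  invisible(results)
}
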