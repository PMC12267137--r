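# Inheritance calling: a transcript detected in the (transcriptionally
# inactive) zygote and in at least one gamete is parentally deposited.
# Two rules are provided: a lenient multi-study consensus rule and a
# stringent all-samples rule for designs with few studies.

#' Expression test at a fixed FPKM threshold
#'
#' @param fpkm Numeric vector of FPKM values (>= 0).
#' @param threshold Detection threshold; the boundary is inclusive, so a
#'   value exactly at the threshold counts as expressed. Default 0.1 FPKM.
#' @return Logical vector.
#' @export
is_expressed <- function(fpkm, threshold = 0.1) {
  if (threshold < 0) stop("expression threshold must be non-negative")
  fpkm >= threshold
}

check_inheritance_inputs <- function(expr, meta, threshold) {
  meta <- validate_meta(meta)
  if (!all(colnames(expr) %in% meta$sample_id)) {
    stop("expression columns without metadata: ",
         paste(setdiff(colnames(expr), meta$sample_id), collapse = ", "))
  }
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  if (sum(meta$sample_type == "zygote") == 0 ||
      length(unique(meta$study_id[meta$sample_type == "zygote"])) == 0) {
    stop("inheritance calling requires at least one zygote study")
  }
  if (!any(meta$sample_type %in% gamete_types())) {
    stop("inheritance calling requires at least one gamete (sperm/oocyte) sample")
  }
  if (threshold < 0) stop("expression threshold must be non-negative")
  meta
}

#' Classify transcripts as inherited
#'
#' Under the **lenient** rule a transcript is inherited iff it is expressed
#' (>= threshold) in at least one sample of *every* zygote study and in at
#' least one sperm or oocyte sample of any study.  Under the **stringent**
#' rule it must be expressed in *all* zygote samples and in all samples of
#' at least one gamete type (all sperm samples, or all oocyte samples); a
#' gamete type with zero samples cannot satisfy the rule.
#'
#' Transcripts meeting the rule's zygote clause but detected in no gamete
#' are reported in the diagnostic column `zygote_only` (possible early
#' zygotic transcription) without being classified as inherited.
#'
#' @param expr FPKM matrix (transcripts x samples).
#' @param meta Sample metadata (see [read_expression_table()]).
#' @param rule `"lenient"` or `"stringent"`.
#' @param threshold Inclusive FPKM detection threshold, default 0.1.
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `status` ("inherited"/"not_inherited"), `rule`, `origin`
#'   ("both_gametes", "oocyte_specific", "sperm_specific" or "none"),
#'   `supporting_samples` (semicolon-joined ids of the zygote and gamete
#'   samples where the transcript is expressed; empty when not inherited)
#'   and logical `zygote_only`.
#' @export
classify_inheritance <- function(expr, meta, rule = c("lenient", "stringent"),
                                 threshold = 0.1) {
  rule <- match.arg(rule)
  meta <- check_inheritance_inputs(expr, meta, threshold)
  E <- is_expressed(expr, threshold)

  zy <- meta$sample_type == "zygote"
  sp <- meta$sample_type == "sperm"
  oo <- meta$sample_type == "oocyte"
  gam <- sp | oo

  if (rule == "lenient") {
    zy_studies <- unique(meta$study_id[zy])
    per_study <- vapply(zy_studies, function(s) {
      cols <- zy & meta$study_id == s
      rowSums(E[, cols, drop = FALSE]) >= 1
    }, logical(nrow(E)))
    zygote_ok <- rowSums(as.matrix(per_study)) == length(zy_studies)
  } else {
    zygote_ok <- rowSums(E[, zy, drop = FALSE]) == sum(zy)
  }

  sp_any <- rowSums(E[, sp, drop = FALSE]) >= 1
  oo_any <- rowSums(E[, oo, drop = FALSE]) >= 1
  if (rule == "lenient") {
    gamete_ok <- sp_any | oo_any
  } else {
    sp_all <- sum(sp) > 0 & rowSums(E[, sp, drop = FALSE]) == sum(sp)
    oo_all <- sum(oo) > 0 & rowSums(E[, oo, drop = FALSE]) == sum(oo)
    gamete_ok <- sp_all | oo_all
  }

  inherited <- zygote_ok & gamete_ok
  origin <- rep("none", nrow(E))
  origin[inherited & oo_any & !sp_any] <- "oocyte_specific"
  origin[inherited & sp_any & !oo_any] <- "sperm_specific"
  origin[inherited & sp_any & oo_any] <- "both_gametes"

  support <- rep("", nrow(E))
  idx <- which(inherited)
  if (length(idx)) {
    keep <- zy | gam
    sample_ids <- meta$sample_id[keep]
    Ek <- E[idx, keep, drop = FALSE]
    support[idx] <- vapply(seq_along(idx), function(i) {
      paste(sample_ids[Ek[i, ]], collapse = ";")
    }, character(1))
  }

  data.frame(
    transcript_id = rownames(expr),
    status = ifelse(inherited, "inherited", "not_inherited"),
    rule = rep(rule, length.out = nrow(E)),
    origin = origin,
    supporting_samples = support,
    zygote_only = zygote_ok & !(sp_any | oo_any),
    stringsAsFactors = FALSE
  )
}

#' Lenient (multi-study consensus) inheritance rule
#' @inheritParams classify_inheritance
#' @return See [classify_inheritance()].
#' @export
classify_inherited_lenient <- function(expr, meta, threshold = 0.1) {
  classify_inheritance(expr, meta, rule = "lenient", threshold = threshold)
}

#' Stringent (all-samples) inheritance rule
#' @inheritParams classify_inheritance
#' @return See [classify_inheritance()].
#' @export
classify_inherited_stringent <- function(expr, meta, threshold = 0.1) {
  classify_inheritance(expr, meta, rule = "stringent", threshold = threshold)
}

#' Gamete of origin for inherited transcripts
#'
#' A transcript is oocyte-specific iff expressed (>= threshold) in at least
#' one oocyte sample and in zero sperm samples; sperm-specific is the mirror
#' case; otherwise it is present in both gametes.  The boundary is inclusive
#' on both sides: a sperm FPKM exactly at the threshold makes the transcript
#' "both_gametes".
#'
#' @param expr FPKM matrix.
#' @param meta Sample metadata.
#' @param inherited_ids Transcript ids previously called inherited; an id
#'   absent from `expr` is an error.
#' @param threshold Inclusive FPKM threshold, default 0.1.
#' @return Named character vector of origins for `inherited_ids`.
#' @export
classify_gamete_origin <- function(expr, meta, inherited_ids, threshold = 0.1) {
  missing_id <- setdiff(inherited_ids, rownames(expr))
  if (length(missing_id)) {
    stop("transcript not in the inherited/expression set: ", missing_id[1])
  }
  meta <- validate_meta(meta)
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  E <- is_expressed(expr[inherited_ids, , drop = FALSE], threshold)
  sp_any <- rowSums(E[, meta$sample_type == "sperm", drop = FALSE]) >= 1
  oo_any <- rowSums(E[, meta$sample_type == "oocyte", drop = FALSE]) >= 1
  origin <- rep("both_gametes", length(inherited_ids))
  origin[oo_any & !sp_any] <- "oocyte_specific"
  origin[sp_any & !oo_any] <- "sperm_specific"
  origin[!sp_any & !oo_any] <- "none"
  stats::setNames(origin, inherited_ids)
}

#' Inherited fraction as a percentage
#'
#' @param n_inherited Number of inherited transcripts (<= `n_total`).
#' @param n_total Total number of transcripts (> 0).
#' @return `100 * n_inherited / n_total`.
#' @export
summarize_inheritance <- function(n_inherited, n_total) {
  if (n_total == 0) stop("n_total must be > 0")
  if (n_inherited < 0 || n_inherited > n_total) {
    stop("n_inherited must be in [0, n_total]")
  }
  100 * n_inherited / n_total
}
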