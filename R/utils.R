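#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample types recognised in sample metadata
#'
#' @return Character vector of valid `sample_type` values.
#' @export
sample_types <- function() {
  c("sperm", "oocyte", "zygote",
    paste0("timepoint_", 0:4, "h"),
    "adult_tissue")
}

timepoint_types <- function() paste0("timepoint_", 0:4, "h")
gamete_types <- function() c("sperm", "oocyte")

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted cluster labels.
#'
#' @param a,b Vectors of equal length; any label type.
#' @return Numeric scalar in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# collapse a list of character vectors to semicolon-joined strings
join_ids <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

split_ids <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

validate_meta <- function(meta) {
  req <- c("sample_id", "study_id", "species", "sample_type")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    stop("sample metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  }
  bad <- setdiff(unique(meta$sample_type), sample_types())
  if (length(bad)) {
    stop("unknown sample_type value(s): ", paste(bad, collapse = ", "))
  }
  if (!"tissue_name" %in% names(meta)) meta$tissue_name <- NA_character_
  meta
}
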