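# Post-fertilization (0-4 hpf) temporal clustering of inherited
# transcripts and stability labelling of the resulting groups.

#' Average timepoint replicates into a profile matrix
#'
#' @param expr FPKM matrix whose columns include timepoint samples.
#' @param meta Sample metadata; `sample_type` values `timepoint_0h` ..
#'   `timepoint_4h` define the five ordered timepoints.
#' @return Matrix (transcripts x 5) of mean FPKM per timepoint, columns
#'   `t0` .. `t4`.
#' @export
average_timepoint_replicates <- function(expr, meta) {
  meta <- validate_meta(meta)
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  tps <- timepoint_types()
  missing_tp <- tps[!tps %in% meta$sample_type]
  if (length(missing_tp)) {
    stop("no samples for timepoint(s): ", paste(missing_tp, collapse = ", "))
  }
  out <- vapply(tps, function(tp) {
    rowMeans(expr[, meta$sample_type == tp, drop = FALSE])
  }, numeric(nrow(expr)))
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr), paste0("t", 0:4)))
  out
}

#' K-means clustering of temporal profiles
#'
#' Profiles are transformed as `log2(FPKM + 1)` and optionally mean-centered
#' per profile before clustering.  Centering makes the clusters shape-driven
#' (amplitude differences vanish); leave `center = FALSE` when amplitude
#' classes (e.g. flat-high vs flat-low) must be distinguished.  Clusters are
#' relabelled by descending size (group 1 = largest; ties broken by lowest
#' original label), so the labelling is deterministic given the seed.
#'
#' @param profiles Matrix (transcripts x timepoints) of raw FPKM, no
#'   missing values.
#' @param k Number of clusters, default 4; must be in `[2, n]`.
#' @param seed RNG seed for k-means initialisation (required: no silent
#'   nondeterminism).
#' @param n_restarts Random restarts (`nstart`), default 10.
#' @param center Mean-center each transformed profile, default TRUE.
#' @return List with `assignment` (data frame: `transcript_id`, `cluster`
#'   = size rank, `group_rank` identical to cluster), `sizes` (descending),
#'   `centroids` (transformed space, rows in rank order),
#'   `group_means_raw` (raw mean trajectory per group, rank order).
#' @export
cluster_profiles <- function(profiles, k = 4, seed, n_restarts = 10,
                             center = TRUE) {
  if (missing(seed)) stop("a seed is required for reproducible clustering")
  n <- nrow(profiles)
  if (k < 2 || k > n) stop("k must be between 2 and the number of profiles")
  if (anyNA(profiles)) stop("profiles contain missing values")
  X <- log2(profiles + 1)
  if (center) X <- X - rowMeans(X)

  n_distinct <- nrow(unique(X))
  k_eff <- min(k, n_distinct)
  if (k_eff < k) {
    warning("only ", n_distinct, " distinct profiles; using k = ", k_eff)
  }
  set.seed(seed)
  if (k_eff == 1) {
    cl <- rep(1L, n)
    centers <- matrix(colMeans(X), nrow = 1)
  } else {
    # initial centers drawn from *distinct* profiles so restarts are always
    # valid even when many rows coincide
    du <- unique(X)
    best <- NULL
    for (r in seq_len(max(1, n_restarts))) {
      init <- du[sample.int(nrow(du), k_eff), , drop = FALSE]
      km_try <- tryCatch(
        stats::kmeans(X, centers = init, iter.max = 100),
        error = function(e) NULL
      )
      if (!is.null(km_try) &&
          (is.null(best) || km_try$tot.withinss < best$tot.withinss)) {
        best <- km_try
      }
    }
    if (is.null(best)) stop("k-means failed for every restart")
    cl <- best$cluster
    centers <- best$centers
  }
  sizes <- tabulate(cl, nbins = k_eff)
  rank_of <- order(-sizes, seq_len(k_eff))  # original label of rank r
  new_label <- integer(k_eff)
  new_label[rank_of] <- seq_len(k_eff)
  cl_ranked <- new_label[cl]

  group_means <- t(vapply(rank_of, function(lbl) {
    colMeans(profiles[cl == lbl, , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(group_means) <- paste0("group", seq_len(k_eff))
  centroids <- centers[rank_of, , drop = FALSE]
  rownames(centroids) <- paste0("group", seq_len(k_eff))

  list(
    assignment = data.frame(
      transcript_id = rownames(profiles) %||% as.character(seq_len(n)),
      cluster = cl_ranked,
      group_rank = cl_ranked,
      stringsAsFactors = FALSE
    ),
    sizes = sort(sizes, decreasing = TRUE),
    centroids = centroids,
    group_means_raw = group_means
  )
}

#' Stability label for clustered trajectories
#'
#' Labels each group's raw mean trajectory over the five timepoints:
#' **induced** if the 1 hpf mean exceeds `fold_induced` times the 0 hpf
#' mean (a zero 0 hpf mean with later expression is induced); **degraded**
#' if the 4 hpf mean falls below `fold_degraded` times the 0 hpf mean and
#' the trajectory is non-increasing within a `tol` relative tolerance at
#' every step; **stable** otherwise.  All criteria are ratios, so labels
#' are invariant to uniform positive scaling of the profiles.
#'
#' @param group_means_raw Matrix (groups x 5 timepoints) of raw mean FPKM.
#' @param fold_degraded Final/initial ratio below which a monotone decline
#'   is called degraded, default 0.5.
#' @param fold_induced 1 hpf / 0 hpf ratio above which a rise is called
#'   induced, default 2.
#' @param tol Relative tolerance for "non-increasing", default 0.1.
#' @return Character vector of labels, one per group (row).
#' @export
label_stability <- function(group_means_raw, fold_degraded = 0.5,
                            fold_induced = 2, tol = 0.1) {
  stopifnot(ncol(group_means_raw) == 5)
  apply(group_means_raw, 1, function(v) {
    if (v[1] == 0) {
      if (any(v[-1] > 0)) return("induced") else return("stable")
    }
    if (v[2] > fold_induced * v[1]) return("induced")
    non_increasing <- all(v[-1] <= v[-5] * (1 + tol))
    if (v[5] < fold_degraded * v[1] && non_increasing) return("degraded")
    "stable"
  })
}
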