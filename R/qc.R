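#' Pairwise run correlations on log2 intensities
#'
#' Pearson correlation between every pair of runs, computed on log2
#' intensities over the features co-observed (non-missing) in both runs.
#' Pairs sharing fewer than three features get `NA` rather than a fabricated
#' value. Within-line pairs quantify replicate reproducibility; between-line
#' pairs quantify cell-line similarity.
#'
#' @param im An [intensity_matrix()].
#' @param min_shared Minimum co-observed features (default 3).
#' @return Data frame `run_a`, `run_b`, `line_a`, `line_b`, `type`
#'   (`"replicate"` or `"between_line"`), `n_shared`, `r`.
#' @export
replicate_correlation <- function(im, min_shared = 3L) {
  x <- log2(im$intensity)
  nr <- ncol(x)
  if (nr < 2L) stop("need at least two runs")
  pairs <- utils::combn(nr, 2L)
  out <- data.frame(
    run_a = im$runs$run[pairs[1, ]], run_b = im$runs$run[pairs[2, ]],
    line_a = im$runs$cell_line[pairs[1, ]],
    line_b = im$runs$cell_line[pairs[2, ]],
    stringsAsFactors = FALSE)
  out$type <- ifelse(out$line_a == out$line_b, "replicate", "between_line")
  res <- apply(pairs, 2L, function(p) {
    ok <- !is.na(x[, p[1]]) & !is.na(x[, p[2]])
    if (sum(ok) < min_shared) return(c(sum(ok), NA_real_))
    c(sum(ok), stats::cor(x[ok, p[1]], x[ok, p[2]]))
  })
  out$n_shared <- as.integer(res[1, ])
  out$r <- res[2, ]
  out
}

#' Per-line replicate detection breakdown
#'
#' For each cell line, features detected in at least one of the line's
#' replicates are binned by how many replicates observed them; fractions
#' are over the line's detected features and sum to one.
#'
#' @param im An [intensity_matrix()].
#' @return Data frame `cell_line`, `detected_in` (replicate count),
#'   `n`, `fraction`.
#' @export
detection_breakdown <- function(im) {
  lines <- unique(im$runs$cell_line)
  do.call(rbind, lapply(lines, function(ln) {
    sub <- im$intensity[, line_run_idx(im, ln), drop = FALSE]
    counts <- rowSums(!is.na(sub))
    counts <- counts[counts > 0L]
    n_rep <- ncol(sub)
    n <- vapply(seq_len(n_rep), function(k) sum(counts == k), integer(1))
    data.frame(cell_line = ln, detected_in = seq_len(n_rep), n = n,
               fraction = if (sum(n)) n / sum(n) else rep(NA_real_, n_rep),
               stringsAsFactors = FALSE)
  }))
}

#' Coefficient-of-variation profile per cell line
#'
#' CV is the sample (n-1) standard deviation divided by the mean of a
#' feature's linear-scale replicate intensities within one line, defined
#' only where at least two replicates are non-missing (and the mean is
#' non-zero). The headline summary is the fraction of features, among those
#' with a defined CV, at or below the threshold (inclusive).
#'
#' @param im An [intensity_matrix()].
#' @param threshold CV gate (default 0.20).
#' @return List with `cv` (features x lines matrix, `NA` where undefined)
#'   and `fraction_le_threshold` (named vector per line).
#' @export
cv_profile <- function(im, threshold = 0.20) {
  lines <- unique(im$runs$cell_line)
  cv <- sapply(lines, function(ln) {
    sub <- im$intensity[, line_run_idx(im, ln), drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    out <- s / m
    out[n < 2L | !is.finite(out)] <- NA_real_
    out
  })
  cv <- matrix(cv, nrow = nrow(im$intensity),
               dimnames = list(rownames(im$intensity), lines))
  frac <- apply(cv, 2L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v <= threshold)
  })
  list(cv = cv, fraction_le_threshold = frac)
}

#' Hierarchical clustering of cell lines
#'
#' Average-linkage clustering of cell lines on the distance 1 - Pearson r
#' between their mean log2 intensity profiles (pairwise-complete features).
#' Lines are ordered lexicographically before clustering so the tree is
#' deterministic regardless of input order.
#'
#' @param im An [intensity_matrix()] with at least three cell lines.
#' @return An [stats::hclust] tree whose labels are cell-line names.
#' @export
cluster_cell_lines <- function(im) {
  prof <- line_profiles_log2(im)
  if (ncol(prof) < 3L) stop("need at least three cell lines to cluster")
  prof <- prof[, order(colnames(prof)), drop = FALSE]
  r <- stats::cor(prof, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = "average")
}
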