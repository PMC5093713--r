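#' Feature-by-run intensity matrix with run metadata
#'
#' The common quantitative container of the pipeline: a numeric matrix of
#' linear-scale intensities (features in rows, replicate runs in columns),
#' the run sheet (cell line, cell type, replicate index) and optional
#' feature metadata (protein, gene, site position, variable-modification
#' flag). Missing observations are `NA`, never zero.
#'
#' @param intensity Numeric matrix, features x runs; column names must equal
#'   `runs$run`.
#' @param runs Data frame with columns `run`, `cell_line`, `cell_type`,
#'   `replicate`.
#' @param features Optional data frame of per-feature metadata, one row per
#'   matrix row; must contain a `feature_id` column used as row names.
#'
#' @return An object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(intensity, runs, features = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  need <- c("run", "cell_line", "cell_type", "replicate")
  if (!all(need %in% names(runs)))
    stop("`runs` must contain columns: ", paste(need, collapse = ", "))
  if (!identical(colnames(intensity), as.character(runs$run)))
    stop("column names of `intensity` must equal `runs$run` (same order)")
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (!is.null(features)) {
    if (nrow(features) != nrow(intensity))
      stop("`features` must have one row per matrix row")
    if (!"feature_id" %in% names(features))
      stop("`features` must contain a `feature_id` column")
    rownames(intensity) <- features$feature_id
  }
  structure(list(intensity = intensity, runs = runs, features = features),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d features x %d runs (%d cell lines)\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$runs$cell_line))))
  cat(sprintf("  missing entries: %.1f%%\n",
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Build an intensity matrix from a parsed site (or proteome) table
#'
#' Collects the `intensity_<line>_<replicate>` columns of a tab-delimited
#' quantitation table into an [intensity_matrix()], attaching cell-type
#' metadata from the design. Works for glycosite tables (feature =
#' protein/site row) and for proteome tables (feature = protein).
#'
#' @param records Data frame with `intensity_*` columns, as returned by
#'   [parse_site_table()] or [simulate_proteome()].
#' @param design The [experiment_design()] the runs belong to.
#' @return An [intensity_matrix()].
#' @export
as_intensity_matrix <- function(records, design) {
  stopifnot(inherits(design, "experiment_design"))
  icols <- grep("^intensity_", names(records), value = TRUE)
  if (!length(icols)) stop("no `intensity_` columns found")
  runs_all <- design_runs(design)
  run_ids <- sub("^intensity_", "", icols)
  unknown <- setdiff(run_ids, runs_all$run)
  if (length(unknown))
    stop("intensity columns for runs absent from the design: ",
         paste(unknown, collapse = ", "))
  ord <- order(match(run_ids, runs_all$run))
  icols <- icols[ord]; run_ids <- run_ids[ord]
  mat <- as.matrix(records[, icols, drop = FALSE])
  storage.mode(mat) <- "double"
  colnames(mat) <- run_ids
  runs <- runs_all[match(run_ids, runs_all$run), , drop = FALSE]
  rownames(runs) <- NULL

  if ("site_id" %in% names(records)) {
    fid <- records$site_id
  } else if (all(c("protein_id", "position") %in% names(records))) {
    fid <- paste(records$protein_id, records$position, sep = "@")
  } else if ("protein_id" %in% names(records)) {
    fid <- records$protein_id
  } else {
    fid <- sprintf("feature%05d", seq_len(nrow(records)))
  }
  fid <- make.unique(as.character(fid))
  keep <- intersect(c("protein_id", "gene_symbol", "position", "peptide",
                      "varmod_flag"), names(records))
  features <- cbind(data.frame(feature_id = fid, stringsAsFactors = FALSE),
                    records[, keep, drop = FALSE])
  rownames(features) <- NULL
  intensity_matrix(mat, runs, features)
}

# internal: column indices of one cell line's runs
line_run_idx <- function(im, line) {
  which(im$runs$cell_line == line)
}

# internal: per-feature mean log2 profile of each cell line
line_profiles_log2 <- function(im) {
  lines <- unique(im$runs$cell_line)
  prof <- sapply(lines, function(ln) {
    rowMeans(log2(im$intensity[, line_run_idx(im, ln), drop = FALSE]),
             na.rm = TRUE)
  })
  prof[is.nan(prof)] <- NA_real_
  prof
}
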