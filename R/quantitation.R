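#' Mean normalization of replicate runs
#'
#' Each run is rescaled by a single multiplicative factor so its mean over
#' non-missing features equals the grand mean of run means. Within-run
#' intensity ratios are unchanged and missing entries stay missing.
#'
#' @param im An [intensity_matrix()].
#' @return The normalized [intensity_matrix()].
#' @export
mean_normalize <- function(im) {
  run_means <- colMeans(im$intensity, na.rm = TRUE)
  if (any(!is.finite(run_means))) {
    bad <- colnames(im$intensity)[!is.finite(run_means)]
    stop("run(s) with no non-missing intensities: ",
         paste(bad, collapse = ", "))
  }
  grand <- mean(run_means)
  im$intensity <- sweep(im$intensity, 2L, grand / run_means, `*`)
  im
}

#' Specification of one pairwise cell-line comparison
#'
#' @param line_a,line_b Cell-line names (fold changes are `a / b`).
#' @param fold_threshold Linear fold-change gate, >= 1 (default 2).
#' @param cv_threshold CV gate applied in both lines (default 0.20).
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(line_a, line_b, fold_threshold = 2,
                            cv_threshold = 0.20) {
  if (identical(line_a, line_b)) stop("`line_a` and `line_b` must differ")
  if (fold_threshold < 1) stop("`fold_threshold` must be >= 1")
  structure(list(line_a = line_a, line_b = line_b,
                 fold_threshold = fold_threshold,
                 cv_threshold = cv_threshold),
            class = "comparison_spec")
}

#' Pairwise label-free comparison of two cell lines
#'
#' A site is *comparable* iff it has at least two non-missing replicates in
#' both lines, its replicate CV is at or below the CV gate in **both**
#' lines, and its peptide row carries no variable-modification flag.
#' For comparable sites the fold change is the ratio of normalized replicate
#' means (`line_a / line_b`); a site is called `up` when the fold change is
#' at least `fold_threshold`, `down` when at most `1 / fold_threshold`
#' (thresholds inclusive), `unchanged` otherwise. Sites observed in only one
#' line are not comparable rather than infinitely regulated. Per-protein
#' categories follow [protein_rollup()].
#'
#' @param im A mean-normalized [intensity_matrix()].
#' @param spec A [comparison_spec()] (or `line_a`/`line_b` passed directly).
#' @param line_a,line_b,fold_threshold,cv_threshold Used when `spec` is
#'   missing.
#' @return Object of class `comparison_result`: list with `line_a`,
#'   `line_b`, `spec`, `sites` (per-site table), `proteins` (per-protein
#'   categories) and `counts`.
#' @export
compare_lines <- function(im, spec = NULL, line_a = NULL, line_b = NULL,
                          fold_threshold = 2, cv_threshold = 0.20) {
  if (is.null(spec))
    spec <- comparison_spec(line_a, line_b, fold_threshold, cv_threshold)
  lines <- unique(im$runs$cell_line)
  if (!spec$line_a %in% lines) stop("unknown cell line: ", spec$line_a)
  if (!spec$line_b %in% lines) stop("unknown cell line: ", spec$line_b)

  stat_line <- function(ln) {
    sub <- im$intensity[, line_run_idx(im, ln), drop = FALSE]
    list(n = rowSums(!is.na(sub)),
         mean = rowMeans(sub, na.rm = TRUE),
         cv = {
           s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
           v <- s / rowMeans(sub, na.rm = TRUE)
           v
         })
  }
  a <- stat_line(spec$line_a); b <- stat_line(spec$line_b)
  varmod <- if (!is.null(im$features$varmod_flag))
    im$features$varmod_flag else rep(FALSE, nrow(im$intensity))
  comparable <- a$n >= 2L & b$n >= 2L &
    !is.na(a$cv) & !is.na(b$cv) &
    a$cv <= spec$cv_threshold & b$cv <= spec$cv_threshold & !varmod

  fold <- ifelse(comparable, a$mean / b$mean, NA_real_)
  call <- rep(NA_character_, length(fold))
  call[comparable] <- "unchanged"
  call[comparable & fold >= spec$fold_threshold] <- "up"
  call[comparable & fold <= 1 / spec$fold_threshold] <- "down"

  sites <- data.frame(
    site_id = im$features$feature_id,
    protein_id = im$features$protein_id,
    gene_symbol = if (!is.null(im$features$gene_symbol))
      im$features$gene_symbol else NA_character_,
    mean_a = a$mean, mean_b = b$mean, cv_a = a$cv, cv_b = b$cv,
    comparable = comparable, fold_change = fold, call = call,
    stringsAsFactors = FALSE, row.names = NULL)

  res <- structure(list(line_a = spec$line_a, line_b = spec$line_b,
                        spec = spec, sites = sites),
                   class = "comparison_result")
  res$proteins <- protein_rollup(res)
  res$counts <- list(
    n_comparable_sites = sum(comparable),
    n_comparable_proteins = length(unique(sites$protein_id[comparable])),
    sites = c(up = sum(call == "up", na.rm = TRUE),
              down = sum(call == "down", na.rm = TRUE),
              unchanged = sum(call == "unchanged", na.rm = TRUE)),
    proteins = table(factor(res$proteins$category,
                            levels = c("up", "down", "both", "unchanged"))))
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison %s vs %s: %d comparable sites (%d proteins)\n",
              x$line_a, x$line_b, x$counts$n_comparable_sites,
              x$counts$n_comparable_proteins))
  cat(sprintf("  site calls: %d up, %d down, %d unchanged\n",
              x$counts$sites["up"], x$counts$sites["down"],
              x$counts$sites["unchanged"]))
  pc <- x$counts$proteins
  cat(sprintf("  protein categories: %d up, %d down, %d both, %d unchanged\n",
              pc["up"], pc["down"], pc["both"], pc["unchanged"]))
  invisible(x)
}

#' Roll site-level calls up to protein categories
#'
#' A protein is `up` iff it has at least one up-called site and no
#' down-called site, `down` symmetrically, `both` iff it has at least one of
#' each, and `unchanged` when all its comparable sites are unchanged.
#'
#' @param result A `comparison_result`, or a data frame with columns
#'   `protein_id` and `call` restricted to comparable sites.
#' @return Data frame `protein_id`, `n_up`, `n_down`, `category`.
#' @export
protein_rollup <- function(result) {
  sites <- if (inherits(result, "comparison_result")) result$sites else result
  sites <- sites[!is.na(sites$call), , drop = FALSE]
  if (nrow(sites) == 0L)
    return(data.frame(protein_id = character(), n_up = integer(),
                      n_down = integer(), category = character(),
                      stringsAsFactors = FALSE))
  up <- tapply(sites$call == "up", sites$protein_id, sum)
  down <- tapply(sites$call == "down", sites$protein_id, sum)
  category <- ifelse(up > 0 & down > 0, "both",
              ifelse(up > 0, "up",
              ifelse(down > 0, "down", "unchanged")))
  data.frame(protein_id = names(up), n_up = as.integer(up),
             n_down = as.integer(down), category = unname(category),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-comparison voting for general alterations
#'
#' A site qualifies as a *general* alteration when it is called in one
#' consistent direction in at least `k` of the supplied comparisons and in
#' the opposite direction in none (`require_consistency = FALSE` drops the
#' zero-opposite condition). Proteins qualify through their qualifying
#' sites.
#'
#' @param results List of `comparison_result` objects over the same feature
#'   universe (typically all hiPSC-vs-hESC pairs).
#' @param k Minimum number of same-direction calls (default 5).
#' @param require_consistency Disqualify sites with any opposite-direction
#'   call (default `TRUE`).
#' @return Object of class `voting_result`: list with `sites`, `proteins`,
#'   `k`, `n_comparisons`.
#' @export
general_alterations <- function(results, k = 5L, require_consistency = TRUE) {
  if (!length(results)) stop("no comparison results supplied")
  if (k > length(results))
    stop("`k` cannot exceed the number of comparisons")
  ids <- unique(unlist(lapply(results, function(r) r$sites$site_id)))
  n_up <- n_down <- n_called <- stats::setNames(integer(length(ids)), ids)
  meta <- NULL
  for (r in results) {
    s <- r$sites
    if (is.null(meta)) meta <- s[, c("site_id", "protein_id", "gene_symbol")]
    i <- match(s$site_id, ids)
    n_up[i] <- n_up[i] + (!is.na(s$call) & s$call == "up")
    n_down[i] <- n_down[i] + (!is.na(s$call) & s$call == "down")
    n_called[i] <- n_called[i] + !is.na(s$call)
  }
  if (require_consistency)
    qualifies <- (n_up >= k & n_down == 0L) | (n_down >= k & n_up == 0L)
  else
    qualifies <- n_up >= k | n_down >= k
  direction <- rep(NA_character_, length(ids))
  direction[qualifies & n_up >= k] <- "up"
  direction[qualifies & n_down >= k] <- "down"
  sites <- data.frame(site_id = ids,
                      protein_id = meta$protein_id[match(ids, meta$site_id)],
                      gene_symbol = meta$gene_symbol[match(ids, meta$site_id)],
                      n_up = as.integer(n_up), n_down = as.integer(n_down),
                      n_comparable = as.integer(n_called),
                      qualifies = unname(qualifies), direction = direction,
                      stringsAsFactors = FALSE, row.names = NULL)
  q <- sites[sites$qualifies, , drop = FALSE]
  proteins <- if (nrow(q)) {
    dirs <- tapply(q$direction, q$protein_id,
                   function(d) if (length(unique(d)) > 1L) "both" else d[1])
    data.frame(protein_id = names(dirs), direction = unname(unlist(dirs)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(protein_id = character(), direction = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(sites = sites, proteins = proteins, k = as.integer(k),
                 n_comparisons = length(results)),
            class = "voting_result")
}

#' @export
print.voting_result <- function(x, ...) {
  cat(sprintf(
    "general alterations: %d site(s) on %d protein(s) (>=%d of %d comparisons)\n",
    sum(x$sites$qualifies), nrow(x$proteins), x$k, x$n_comparisons))
  invisible(x)
}
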