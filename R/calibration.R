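#' Calibrate glyco fold changes by protein-level fold changes
#'
#' Divides each altered glycosite's fold change by its parent protein's fold
#' change for the same cell-line pair (equivalently, subtracts log2 fold
#' changes), isolating glycosylation-specific regulation from bulk protein
#' abundance change. A calibrated record is:
#' * `retained` when `|log2(calibrated fold)| >= log2(retain_threshold)`;
#'   records whose calibrated magnitude falls in
#'   `[log2(note_threshold), log2(retain_threshold))` are also retained but
#'   carry a `near_threshold` flag;
#' * `explained_by_protein` when the calibrated magnitude falls below
#'   `log2(note_threshold)` -- the alteration is attributable to the protein
#'   level change;
#' * `unmatched` when the protein is absent from the proteome table (the
#'   uncalibrated fold is kept).
#' Records with a non-positive or missing protein fold are flagged
#' `fold_error` and excluded from classification.
#'
#' @param glyco A `comparison_result` (its altered comparable sites are
#'   used) or a data frame with columns `protein_id`, `glyco_fold` and
#'   optionally `site_id`.
#' @param protein_folds Data frame `protein_id`, `protein_fold`, e.g. from
#'   [protein_fold_changes()].
#' @param retain_threshold Fold gate for retention (default 2).
#' @param note_threshold Near-threshold fold (default 1.75).
#' @return Data frame of class `calibration_result` with columns
#'   `protein_id`, `site_id`, `glyco_fold`, `protein_fold`,
#'   `calibrated_fold`, `near_threshold`, `fold_error`, `status`.
#' @export
calibrate <- function(glyco, protein_folds, retain_threshold = 2,
                      note_threshold = 1.75) {
  if (note_threshold > retain_threshold)
    stop("`note_threshold` must not exceed `retain_threshold`")
  if (inherits(glyco, "comparison_result")) {
    s <- glyco$sites
    s <- s[!is.na(s$call) & s$call != "unchanged", , drop = FALSE]
    glyco <- data.frame(protein_id = s$protein_id, site_id = s$site_id,
                        glyco_fold = s$fold_change, stringsAsFactors = FALSE)
  }
  if (!"site_id" %in% names(glyco)) glyco$site_id <- glyco$protein_id
  pf <- protein_folds$protein_fold[match(glyco$protein_id,
                                         protein_folds$protein_id)]
  matched <- glyco$protein_id %in% protein_folds$protein_id
  fold_error <- matched & (is.na(pf) | pf <= 0)
  cal <- ifelse(matched & !fold_error, glyco$glyco_fold / pf, NA_real_)
  alog <- abs(log2(cal))
  status <- rep(NA_character_, nrow(glyco))
  status[!matched] <- "unmatched"
  status[matched & !fold_error] <-
    ifelse(alog[matched & !fold_error] >= log2(note_threshold),
           "retained", "explained_by_protein")
  near <- !is.na(alog) & alog >= log2(note_threshold) &
    alog < log2(retain_threshold)
  out <- data.frame(protein_id = glyco$protein_id, site_id = glyco$site_id,
                    glyco_fold = glyco$glyco_fold, protein_fold = pf,
                    calibrated_fold = cal, near_threshold = near,
                    fold_error = fold_error, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("calibration_result", "data.frame")
  out
}

#' Calibration accounting at the protein level
#'
#' Either recounts a [calibrate()] result (per-protein: a protein is matched
#' when any of its records is matched, retained when at least one matched
#' record is retained, explained when all matched records are explained) or
#' takes explicit printed counts. The headline figure is the retained
#' percentage, `100 * n_retained / n_matched`.
#'
#' @param records A `calibration_result`, or `NULL` when explicit counts are
#'   given.
#' @param n_altered,n_matched,n_explained Explicit counts (used when
#'   `records` is `NULL`); `n_retained` is `n_matched - n_explained`.
#' @return List with `n_altered`, `n_matched`, `n_explained`, `n_retained`,
#'   `retained_pct` (`NA` with a warning when nothing matched).
#' @export
calibration_summary <- function(records = NULL, n_altered = NULL,
                                n_matched = NULL, n_explained = NULL) {
  if (!is.null(records)) {
    stopifnot(inherits(records, "calibration_result"))
    r <- records[!records$fold_error, , drop = FALSE]
    prots <- unique(r$protein_id)
    by_prot <- split(r$status, r$protein_id)[prots]
    is_matched <- vapply(by_prot, function(s) any(s != "unmatched"), logical(1))
    is_retained <- vapply(by_prot, function(s) any(s == "retained"), logical(1))
    n_altered <- length(prots)
    n_matched <- sum(is_matched)
    n_retained <- sum(is_matched & is_retained)
    n_explained <- n_matched - n_retained
  } else {
    if (is.null(n_matched) || is.null(n_explained))
      stop("supply either `records` or the explicit counts")
    n_retained <- n_matched - n_explained
  }
  if (n_matched == 0L) {
    warning("no proteome-matched proteins: retained percentage undefined")
    pct <- NA_real_
  } else pct <- 100 * n_retained / n_matched
  list(n_altered = n_altered, n_matched = n_matched,
       n_explained = n_explained, n_retained = n_retained,
       retained_pct = pct)
}
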