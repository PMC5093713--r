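#' Scan a protein sequence for N-glycosylation sequons
#'
#' Returns every N-X-[S/T/C] tripeptide with X != P: position `i` (1-based)
#' is reported when residue `i` is N, residue `i+1` is not P and residue
#' `i+2` is S, T or C. Overlapping sequons are all reported, and a site
#' within two residues of the sequence end can never form a sequon. Letters
#' outside the 20-residue alphabet are allowed and never match.
#'
#' @param sequence A single amino-acid string.
#' @return Data frame with columns `position`, `x_residue`, `third_residue`.
#' @export
find_sequons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L)
    return(data.frame(position = integer(), x_residue = character(),
                      third_residue = character(), stringsAsFactors = FALSE))
  i <- which(ch == "N")
  i <- i[i <= n - 2L]
  i <- i[ch[i + 1L] != "P" & ch[i + 2L] %in% c("S", "T", "C")]
  data.frame(position = i, x_residue = ch[i + 1L], third_residue = ch[i + 2L],
             stringsAsFactors = FALSE)
}

# columns every glycosite table must carry
.required_site_columns <- c(
  "protein_id", "gene_symbol", "position", "sequence_window", "peptide",
  "localization_score", "localization_prob",
  "contaminant_flag", "reverse_flag", "varmod_flag")

#' Read a search-engine glycosite table
#'
#' Parses the tab-delimited glycosite dialect: one row per protein site with
#' identification metadata, flag columns and one `intensity_<line>_<rep>`
#' column per run (optionally per-run `locprob_<line>_<rep>` localization
#' probabilities). Empty intensity cells become `NA` -- they are missing
#' observations, not zeros -- and are excluded from downstream CV
#' denominators. Flag columns accept logical values, 0/1, or the search
#' engine's `"+"` mark.
#'
#' @param path Path to the tab-delimited file.
#' @return Data frame of site records (one row per site).
#' @export
parse_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "NaN"))
  missing_cols <- setdiff(.required_site_columns, names(tab))
  if (length(missing_cols))
    stop("glycosite table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- c("position", "localization_score", "localization_prob",
                grep("^(intensity_|locprob_)", names(tab), value = TRUE))
  for (cl in num_cols) {
    x <- tab[[cl]]
    if (is.numeric(x)) next
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   cl, bad[1], x[bad[1]]))
    tab[[cl]] <- val
  }
  for (cl in c("contaminant_flag", "reverse_flag", "varmod_flag")) {
    x <- tab[[cl]]
    if (is.logical(x)) { x[is.na(x)] <- FALSE }
    else if (is.numeric(x)) { x <- !is.na(x) & x != 0 }
    else x <- !is.na(x) & trimws(as.character(x)) %in% c("+", "TRUE", "true", "1")
    tab[[cl]] <- x
  }
  if (!"site_id" %in% names(tab))
    tab$site_id <- make.unique(paste(tab$protein_id, tab$position, sep = "@"))
  tab
}

#' Write a glycosite table to disk
#'
#' @param records Site data frame.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Apply the identification quality filters
#'
#' Removes contaminant and reverse (decoy) identifications, then requires a
#' site localization score of at least `min_score` and a localization
#' probability of at least `min_prob` in at least `min_prob_replicates`
#' replicate runs of at least one cell line. All thresholds are inclusive.
#' When per-run `locprob_<line>_<rep>` columns are absent, the single
#' `localization_prob` column is gated instead. Filtering is idempotent.
#'
#' @param records Site data frame from [parse_site_table()].
#' @param min_score Minimum site localization score (default 50).
#' @param min_prob Minimum localization probability (default 0.8).
#' @param min_prob_replicates Replicate runs (within one line) that must meet
#'   `min_prob` (default 2).
#' @return The retained subset of `records`.
#' @export
filter_records <- function(records, min_score = 50, min_prob = 0.8,
                           min_prob_replicates = 2L) {
  if (nrow(records) == 0L) return(records)
  decoy <- records$contaminant_flag | records$reverse_flag |
    grepl("^(REV__|CON__)", records$protein_id)
  score_ok <- !is.na(records$localization_score) &
    records$localization_score >= min_score

  pcols <- grep("^locprob_", names(records), value = TRUE)
  if (length(pcols)) {
    run_line <- sub("_[^_]+$", "", sub("^locprob_", "", pcols))
    pm <- as.matrix(records[, pcols, drop = FALSE])
    prob_ok <- rep(FALSE, nrow(records))
    for (ln in unique(run_line)) {
      hits <- rowSums(pm[, run_line == ln, drop = FALSE] >= min_prob,
                      na.rm = TRUE)
      prob_ok <- prob_ok | hits >= min_prob_replicates
    }
  } else {
    prob_ok <- !is.na(records$localization_prob) &
      records$localization_prob >= min_prob
  }
  records[!decoy & score_ok & prob_ok, , drop = FALSE]
}

#' Validate glycosites against the protein database sequon rule
#'
#' A site is sequon-valid iff its reported asparagine position is an
#' N-X!=P-[S/T/C] sequon of its protein sequence. Records whose protein is
#' absent from the database are excluded (with a warning) and listed with
#' reason `protein_not_in_db`; non-sequon positions are listed with reason
#' `not_sequon`. The residue tally counts valid sites by the residue at
#' position N+2 (T, S or C).
#'
#' @param records Filtered site data frame.
#' @param db Protein database: result of [generate_protein_db()], a named
#'   `AAStringSet`, or a named character vector of sequences.
#' @return List with `records` (valid subset), `tally` (named integer vector
#'   `T`, `S`, `C`) and `excluded` (data frame `site_id`, `protein_id`,
#'   `position`, `reason`).
#' @export
validate_sites <- function(records, db) {
  seqs <- db_sequences(db)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  third <- rep(NA_character_, n)
  idx <- match(records$protein_id, names(seqs))
  reason[is.na(idx)] <- "protein_not_in_db"
  for (i in which(!is.na(idx))) {
    s <- seqs[[idx[i]]]
    p <- records$position[i]
    if (is.na(p) || p < 1L || p > nchar(s) - 2L) { reason[i] <- "not_sequon"; next }
    nres <- substr(s, p, p)
    xres <- substr(s, p + 1L, p + 1L)
    tres <- substr(s, p + 2L, p + 2L)
    if (nres == "N" && xres != "P" && tres %in% c("S", "T", "C"))
      third[i] <- tres
    else
      reason[i] <- "not_sequon"
  }
  if (any(reason == "protein_not_in_db", na.rm = TRUE))
    warning(sum(reason == "protein_not_in_db", na.rm = TRUE),
            " record(s) reference proteins absent from the database")
  valid <- is.na(reason)
  tally <- c(T = sum(third == "T", na.rm = TRUE),
             S = sum(third == "S", na.rm = TRUE),
             C = sum(third == "C", na.rm = TRUE))
  excluded <- data.frame(site_id = records$site_id[!valid],
                         protein_id = records$protein_id[!valid],
                         position = records$position[!valid],
                         reason = reason[!valid], stringsAsFactors = FALSE)
  list(records = records[valid, , drop = FALSE], tally = tally,
       excluded = excluded)
}

# internal: coerce the accepted database representations to named character
db_sequences <- function(db) {
  if (is.list(db) && !is.null(db$proteins)) db <- db$proteins
  if (inherits(db, "AAStringSet")) db <- as.character(db)
  if (!is.character(db) || is.null(names(db)))
    stop("`db` must be a named set of protein sequences")
  db
}

#' Summarize identifications across cell lines
#'
#' Counts N-glycoproteins, N-glycopeptides and N-glycosites identified in
#' each cell line (a feature counts as identified in a line when at least
#' one of the line's replicate runs has a non-missing intensity), the
#' protein-set overlaps between cell-type groups, and how many sites were
#' seen in exactly one, at least two and at least seven lines.
#'
#' @param records Filtered, validated site data frame with `intensity_*`
#'   columns.
#' @param design The [experiment_design()].
#' @return List of class `identification_summary` with elements `per_line`,
#'   `overlap` (`hPSC` = proteins seen in both hiPSC and hESC groups;
#'   `all_types` = in all three groups) and `sites_by_lines`.
#' @export
summarize_identifications <- function(records, design) {
  stopifnot(inherits(design, "experiment_design"))
  icols <- grep("^intensity_", names(records), value = TRUE)
  run_line <- sub("_[^_]+$", "", sub("^intensity_", "", icols))
  detected <- sapply(design$cell_line, function(ln) {
    cols <- icols[run_line == ln]
    rowSums(!is.na(as.matrix(records[, cols, drop = FALSE]))) > 0L
  })
  detected <- matrix(detected, nrow = nrow(records),
                     dimnames = list(NULL, design$cell_line))

  per_line <- data.frame(
    cell_line = design$cell_line, cell_type = design$cell_type,
    n_proteins = vapply(design$cell_line, function(ln)
      length(unique(records$protein_id[detected[, ln]])), integer(1)),
    n_peptides = vapply(design$cell_line, function(ln)
      length(unique(records$peptide[detected[, ln]])), integer(1)),
    n_sites = vapply(design$cell_line, function(ln)
      sum(detected[, ln]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  prot_by_type <- lapply(c("hiPSC", "hESC", "SC"), function(ty) {
    lines <- design$cell_line[design$cell_type == ty]
    if (!length(lines)) return(character(0))
    unique(records$protein_id[rowSums(detected[, lines, drop = FALSE]) > 0L])
  })
  names(prot_by_type) <- c("hiPSC", "hESC", "SC")
  overlap <- list(
    hPSC = length(intersect(prot_by_type$hiPSC, prot_by_type$hESC)),
    all_types = length(Reduce(intersect, prot_by_type)))

  n_lines_per_site <- rowSums(detected)
  sites_by_lines <- c(one = sum(n_lines_per_site == 1L),
                      two_or_more = sum(n_lines_per_site >= 2L),
                      seven_or_more = sum(n_lines_per_site >= 7L))
  structure(list(per_line = per_line, overlap = overlap,
                 sites_by_lines = sites_by_lines,
                 proteins_by_type = prot_by_type),
            class = "identification_summary")
}

#' @export
print.identification_summary <- function(x, ...) {
  cat("Identification summary\n")
  print(x$per_line, row.names = FALSE)
  cat(sprintf("proteins shared by hiPSC and hESC groups: %d\n", x$overlap$hPSC))
  cat(sprintf("proteins shared by all three cell types:  %d\n",
              x$overlap$all_types))
  cat(sprintf("sites in one line: %d; in >=2 lines: %d; in >=7 lines: %d\n",
              x$sites_by_lines["one"], x$sites_by_lines["two_or_more"],
              x$sites_by_lines["seven_or_more"]))
  invisible(x)
}
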