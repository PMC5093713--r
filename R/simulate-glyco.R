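#' Simulate a multiplexed label-free N-glycoproteomics experiment
#'
#' Generates a search-engine-style glycosite table for every replicate run of
#' the design, with known planted truth. Site baselines are drawn in log2
#' space and exported as linear intensities (the convention of quantitation
#' software output). A chosen fraction of clean sites carries a planted
#' hiPSC-vs-hESC alteration of `planted_log2fc` log2 units; a further
#' fraction carries a somatic-cell-specific shift emulating the large
#' PSC-vs-SC divergence. Decoy (reverse/contaminant), variable-modification
#' and localization-failure rows are planted at their configured rates so
#' the identification filters have real work to do.
#'
#' @param design An [experiment_design()].
#' @param truth A [truth_config()].
#' @param db Optional protein database from [generate_protein_db()]; when
#'   `NULL` one is generated deterministically from the truth seed.
#'
#' @return List with elements:
#'   * `table`: the glycosite data frame (tab-delimited dialect with
#'     `intensity_<line>_<rep>` and `locprob_<line>_<rep>` columns);
#'   * `matrix`: [intensity_matrix()] over the non-decoy rows;
#'   * `truth`: planted truth (altered sites, SC-shifted sites, protein-level
#'     changes with the explained-by-protein designation, full protein list);
#'   * `db`: the protein database used.
#' @export
simulate_glyco_experiment <- function(design, truth, db = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  stopifnot(inherits(truth, "truth_config"))
  if (nrow(design) == 0L) stop("empty design")
  if (is.null(db))
    db <- generate_protein_db(truth$n_proteins, mean_length = 300L,
                              seed = derive_seed(truth$seed, 101L))
  runs <- design_runs(design)
  sd_log2 <- truth$replicate_cv / log(2)

  withr::with_seed(truth$seed, {
    # --- pick sites: a truncated-Poisson number of sequons per protein
    seq_by_prot <- split(db$sequons$position, db$sequons$protein_id)
    picks <- lapply(names(seq_by_prot), function(pid) {
      avail <- seq_by_prot[[pid]]
      k <- min(length(avail), max(1L, stats::rpois(1L, truth$sites_per_protein)))
      sort(sample(avail, k))
    })
    names(picks) <- names(seq_by_prot)
    site_prot <- rep(names(picks), lengths(picks))
    site_pos <- unlist(picks, use.names = FALSE)
    n <- length(site_pos)
    if (n == 0L) stop("no sequons available in the protein database")

    seqs <- as.character(db$proteins)
    windows <- vapply(seq_len(n), function(i) {
      sequence_window(seqs[[site_prot[i]]], site_pos[i], flank = 5L)
    }, character(1))
    peptides <- vapply(seq_len(n), function(i) {
      s <- seqs[[site_prot[i]]]
      substr(s, max(1L, site_pos[i] - 7L), min(nchar(s), site_pos[i] + 7L))
    }, character(1))

    # --- row-level artifact flags
    decoy <- stats::runif(n) < truth$decoy_rate
    decoy_kind <- ifelse(stats::runif(n) < 0.5, "REV__", "CON__")
    varmod <- !decoy & (stats::runif(n) < truth$varmod_rate)
    loc_fail <- stats::runif(n) < truth$loc_fail_rate
    fail_by_score <- stats::runif(n) < 0.5

    loc_score <- stats::runif(n, 60, 180)
    loc_score[loc_fail & fail_by_score] <-
      stats::runif(sum(loc_fail & fail_by_score), 5, 49.5)

    # --- planted hiPSC-vs-hESC alterations among clean rows
    eligible <- which(!decoy & !varmod & !loc_fail)
    n_alt <- round(truth$frac_altered * length(eligible))
    altered_idx <- if (n_alt > 0) sort(sample(eligible, n_alt)) else integer(0)
    shift_ipsc <- numeric(n)
    dir <- sample(c(-1, 1), length(altered_idx), replace = TRUE)
    shift_ipsc[altered_idx] <- dir * truth$planted_log2fc

    # --- somatic-cell divergence on a fraction of non-decoy sites
    sc_idx <- which(!decoy & stats::runif(n) < truth$sc_effect_frac)
    shift_sc <- numeric(n)
    shift_sc[sc_idx] <- sample(c(-1, 1), length(sc_idx), replace = TRUE) *
      stats::runif(length(sc_idx), truth$sc_effect_size / 2,
                   truth$sc_effect_size * 1.5)

    # --- intensities: log2 baseline + type shifts + replicate noise
    mu <- stats::runif(n, 18, 24)
    nrun <- nrow(runs)
    log2mat <- matrix(NA_real_, n, nrun)
    for (j in seq_len(nrun)) {
      type <- runs$cell_type[j]
      shift <- if (type == "hiPSC") shift_ipsc
               else if (type == "SC") shift_sc else 0
      log2mat[, j] <- mu + shift + stats::rnorm(n, 0, sd_log2)
    }
    lin <- 2^log2mat
    if (truth$missing_rate > 0)
      lin[matrix(stats::runif(n * nrun) < truth$missing_rate, n, nrun)] <- NA_real_

    # --- per-run localization probabilities
    probs <- matrix(stats::runif(n * nrun, 0.80, 1.00), n, nrun)
    low <- loc_fail & !fail_by_score
    probs[low, ] <- stats::runif(sum(low) * nrun, 0.30, 0.79)

    # --- explained-by-protein designation for altered proteins
    alt_prot <- unique(site_prot[altered_idx])
    explains <- stats::runif(length(alt_prot)) < truth$explained_fraction
  })

  protein_id_out <- ifelse(decoy, paste0(decoy_kind, site_prot), site_prot)
  gene_out <- unname(db$genes[site_prot])
  site_id <- paste(protein_id_out, site_pos, sep = "@")
  site_id <- make.unique(site_id)

  tab <- data.frame(
    site_id = site_id,
    protein_id = protein_id_out,
    gene_symbol = gene_out,
    position = site_pos,
    sequence_window = windows,
    peptide = peptides,
    localization_score = loc_score,
    localization_prob = apply(probs, 1, max),
    contaminant_flag = decoy & decoy_kind == "CON__",
    reverse_flag = decoy & decoy_kind == "REV__",
    varmod_flag = varmod,
    stringsAsFactors = FALSE
  )
  pcols <- as.data.frame(probs)
  names(pcols) <- paste0("locprob_", runs$run)
  icols <- as.data.frame(lin)
  names(icols) <- paste0("intensity_", runs$run)
  tab <- cbind(tab, pcols, icols)

  # protein-level changes: explained proteins mirror their first glyco shift
  first_shift <- vapply(alt_prot, function(p) {
    shift_ipsc[altered_idx[site_prot[altered_idx] == p][1]]
  }, numeric(1))
  protein_changes <- data.frame(
    protein_id = alt_prot,
    gene_symbol = unname(db$genes[alt_prot]),
    log2fc = ifelse(explains, first_shift, 0),
    explains_glyco = explains,
    stringsAsFactors = FALSE
  )

  truth_out <- list(
    altered_sites = data.frame(
      site_id = site_id[altered_idx],
      protein_id = site_prot[altered_idx],
      gene_symbol = unname(db$genes[site_prot[altered_idx]]),
      position = site_pos[altered_idx],
      direction = c("down", "up")[(shift_ipsc[altered_idx] > 0) + 1L],
      log2fc = shift_ipsc[altered_idx],
      target = rep("hiPSC_vs_hESC", length(altered_idx)),
      stringsAsFactors = FALSE),
    sc_altered_sites = data.frame(
      site_id = site_id[sc_idx], protein_id = site_prot[sc_idx],
      log2fc = shift_sc[sc_idx], stringsAsFactors = FALSE),
    protein_level_changes = protein_changes,
    proteins = unique(site_prot),
    reprogramming_states = NULL,
    candidate_plurinet_links = NULL
  )

  clean <- tab[!decoy, , drop = FALSE]
  list(table = tab, matrix = as_intensity_matrix(clean, design),
       truth = truth_out, db = db)
}

# internal: MaxQuant-style sequence window, underscore-padded at sequence ends
sequence_window <- function(sequence, position, flank = 5L) {
  n <- nchar(sequence)
  lo <- position - flank; hi <- position + flank
  core <- substr(sequence, max(1L, lo), min(n, hi))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - n)))
}

#' Simulate a matched whole-proteome quantitation table
#'
#' Emulates the companion proteomics dataset used for calibration: a chosen
#' fraction of the glyco-altered proteins is present ("matched"), and the
#' planted explained-by-protein subset carries protein-level changes equal to
#' their glyco changes so that calibration should classify exactly those as
#' explained. Background (unaltered) proteins pad the table.
#'
#' @param truth The `truth` element returned by [simulate_glyco_experiment()].
#' @param design The [experiment_design()].
#' @param match_fraction Fraction of altered proteins present in the
#'   proteome table (rounded).
#' @param n_background Number of additional unaltered proteins included.
#' @param replicate_cv Replicate noise of the proteome intensities; 0 gives
#'   exact, noise-free protein fold changes.
#' @param seed Integer seed.
#'
#' @return List with `table` (data frame `protein_id`, `gene_symbol`,
#'   `intensity_<line>_<rep>`) and `matched_proteins` (character).
#' @export
simulate_proteome <- function(truth, design, match_fraction = 0.75,
                              n_background = 100L, replicate_cv = 0.10,
                              seed = 1L) {
  if (match_fraction < 0 || match_fraction > 1)
    stop("`match_fraction` must lie in [0, 1]")
  stopifnot(inherits(design, "experiment_design"))
  runs <- design_runs(design)
  altered <- unique(truth$altered_sites$protein_id)
  n_match <- round(match_fraction * length(altered))
  background_pool <- setdiff(truth$proteins, altered)
  sd_log2 <- replicate_cv / log(2)

  withr::with_seed(seed, {
    matched <- if (n_match > 0) sort(sample(altered, n_match)) else character(0)
    bg <- sort(sample(background_pool, min(n_background, length(background_pool))))
    prots <- c(matched, bg)
    npr <- length(prots)
    changes <- truth$protein_level_changes
    lfc <- changes$log2fc[match(prots, changes$protein_id)]
    lfc[is.na(lfc)] <- 0
    base <- stats::runif(npr, 20, 26)
    mat <- matrix(NA_real_, npr, nrow(runs))
    for (j in seq_len(nrow(runs))) {
      shift <- if (runs$cell_type[j] == "hiPSC") lfc else 0
      mat[, j] <- 2^(base + shift + stats::rnorm(npr, 0, sd_log2))
    }
  })
  tab <- data.frame(protein_id = prots,
                    gene_symbol = truth$protein_level_changes$gene_symbol[
                      match(prots, truth$protein_level_changes$protein_id)],
                    stringsAsFactors = FALSE)
  # background genes keep their database symbol pattern
  tab$gene_symbol[is.na(tab$gene_symbol)] <-
    sub("^SYNP", "GENE", tab$protein_id[is.na(tab$gene_symbol)])
  icols <- as.data.frame(mat)
  names(icols) <- paste0("intensity_", runs$run)
  tab <- cbind(tab, icols)
  list(table = tab, matched_proteins = matched)
}

#' Per-protein fold changes between two cell lines of a proteome table
#'
#' Mean-normalizes the proteome runs and reports, for each protein, the
#' ratio of replicate-mean intensities `line_a / line_b` -- the quantity the
#' calibration stage divides glyco fold changes by.
#'
#' @param proteome_table Data frame from [simulate_proteome()] (or the same
#'   dialect read from disk).
#' @param design The [experiment_design()].
#' @param line_a,line_b Cell-line names.
#' @return Data frame `protein_id`, `protein_fold`.
#' @export
protein_fold_changes <- function(proteome_table, design, line_a, line_b) {
  im <- as_intensity_matrix(proteome_table, design)
  im <- mean_normalize(im)
  a <- rowMeans(im$intensity[, line_run_idx(im, line_a), drop = FALSE],
                na.rm = TRUE)
  b <- rowMeans(im$intensity[, line_run_idx(im, line_b), drop = FALSE],
                na.rm = TRUE)
  data.frame(protein_id = im$features$protein_id,
             protein_fold = a / b, stringsAsFactors = FALSE)
}
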