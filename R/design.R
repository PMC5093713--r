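#' Describe a multi-cell-line study design
#'
#' A design lists the cell lines profiled, their type (hiPSC, hESC or
#' parental somatic cell) and, for induced lines, the somatic line they were
#' reprogrammed from. Replicate structure is shared by all lines.
#'
#' @param cell_lines Character vector of unique cell-line names. Names must
#'   not contain underscores (run identifiers are `<line>_<replicate>`).
#' @param cell_types Character vector, same length, each one of
#'   `"hiPSC"`, `"hESC"`, `"SC"`.
#' @param parents Optional character vector naming, for each hiPSC line, its
#'   parental somatic line (must itself be an SC in the design). `NA` for
#'   lines without a recorded parent.
#' @param n_replicates Integer number of replicate runs per line (>= 2).
#'
#' @return A data frame of class `experiment_design` with columns
#'   `cell_line`, `cell_type`, `parent` and an `n_replicates` attribute.
#' @seealso [default_design()] for the nine-line reference design.
#' @export
experiment_design <- function(cell_lines, cell_types, parents = NA_character_,
                              n_replicates = 3L) {
  cell_lines <- as.character(cell_lines)
  cell_types <- as.character(cell_types)
  if (length(cell_lines) == 0L) stop("design must contain at least one cell line")
  if (length(cell_types) != length(cell_lines))
    stop("`cell_types` must match `cell_lines` in length")
  if (anyDuplicated(cell_lines)) stop("cell-line names must be unique")
  if (any(grepl("_", cell_lines, fixed = TRUE)))
    stop("cell-line names must not contain underscores")
  bad <- setdiff(unique(cell_types), c("hiPSC", "hESC", "SC"))
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  parents <- rep_len(as.character(parents), length(cell_lines))
  sc <- cell_lines[cell_types == "SC"]
  has_parent <- !is.na(parents)
  if (any(has_parent & !(parents %in% sc)))
    stop("every recorded parent must name an SC line in the design")
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("`n_replicates` must be an integer >= 2")
  out <- data.frame(cell_line = cell_lines, cell_type = cell_types,
                    parent = parents, stringsAsFactors = FALSE)
  attr(out, "n_replicates") <- n_replicates
  class(out) <- c("experiment_design", "data.frame")
  out
}

#' Reference nine-line design
#'
#' Five hiPSC lines, two hESC lines and the two parental somatic (fibroblast
#' and granulosa) lines, profiled in triplicate -- the standard comparison
#' panel this pipeline targets.
#'
#' @return An [experiment_design()].
#' @export
default_design <- function() {
  experiment_design(
    cell_lines = c("Gra1", "Gra2", "Gra7", "CBF46", "CBF50",
                   "H9", "NTU1", "HGra", "HF"),
    cell_types = c(rep("hiPSC", 5L), rep("hESC", 2L), rep("SC", 2L)),
    parents    = c("HGra", "HGra", "HGra", "HF", "HF",
                   NA, NA, NA, NA),
    n_replicates = 3L
  )
}

#' Replicate-run labels of a design
#'
#' @param design An [experiment_design()].
#' @return Data frame with one row per run: `run`, `cell_line`, `cell_type`,
#'   `replicate`.
#' @export
design_runs <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  n_rep <- attr(design, "n_replicates")
  runs <- expand.grid(replicate = seq_len(n_rep),
                      cell_line = design$cell_line,
                      stringsAsFactors = FALSE)
  runs <- runs[order(match(runs$cell_line, design$cell_line), runs$replicate), ]
  runs$cell_type <- design$cell_type[match(runs$cell_line, design$cell_line)]
  data.frame(run = paste(runs$cell_line, runs$replicate, sep = "_"),
             cell_line = runs$cell_line, cell_type = runs$cell_type,
             replicate = runs$replicate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Parameters of the planted-truth glycoproteomics simulation
#'
#' Bundles every knob of the synthetic glycosite generator: how many proteins
#' carry sites, what fraction of sites is truly altered between hiPSCs and
#' hESCs and by how much, replicate noise expressed as a target coefficient
#' of variation, run-level missingness, and the rates of decoy, contaminant,
#' variable-modification and localization-failure rows that the
#' identification filters must remove.
#'
#' @param n_proteins Number of proteins in the synthetic database.
#' @param sites_per_protein Mean number of glycosites sampled per protein
#'   (truncated-Poisson, capped by the protein's available sequons).
#' @param frac_altered Fraction of clean sites planted with an hiPSC-vs-hESC
#'   alteration.
#' @param planted_log2fc Planted effect size in log2 units; magnitude should
#'   be >= 1 so planted truths are at least 2-fold.
#' @param replicate_cv Target coefficient of variation of replicate
#'   intensities (linear scale); noise is normal in log space with
#'   sd = `replicate_cv / log(2)` in log2 units.
#' @param missing_rate Probability that any single run-level intensity is
#'   missing (missing-at-random).
#' @param decoy_rate Fraction of rows emitted as reverse/contaminant decoys
#'   (`REV__`/`CON__` identifier prefixes plus flag columns).
#' @param varmod_rate Fraction of rows flagged as carrying variable
#'   (oxidation/acetylation) modifications.
#' @param loc_fail_rate Fraction of rows generated to fail the localization
#'   gates (score < 50 or probability < 0.8).
#' @param explained_fraction Among altered proteins, fraction whose
#'   protein-level abundance change equals the glyco change, i.e. planted
#'   "explained-by-protein" calibration cases.
#' @param sc_effect_frac,sc_effect_size Fraction of sites with an additional
#'   somatic-cell-specific shift and its typical magnitude (log2); emulates
#'   the large PSC-vs-SC divergence.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#'
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_proteins = 150L, sites_per_protein = 2,
                         frac_altered = 0.15, planted_log2fc = 1.5,
                         replicate_cv = 0.15, missing_rate = 0.05,
                         decoy_rate = 0.05, varmod_rate = 0.05,
                         loc_fail_rate = 0.10, explained_fraction = 0.25,
                         sc_effect_frac = 0.4, sc_effect_size = 2,
                         seed = 1L) {
  fr <- c(frac_altered = frac_altered, missing_rate = missing_rate,
          decoy_rate = decoy_rate, varmod_rate = varmod_rate,
          loc_fail_rate = loc_fail_rate, explained_fraction = explained_fraction,
          sc_effect_frac = sc_effect_frac)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all rate/fraction parameters must lie in [0, 1]")
  if (n_proteins < 1L) stop("`n_proteins` must be >= 1")
  if (replicate_cv < 0) stop("`replicate_cv` must be non-negative")
  if (frac_altered > 0 && abs(planted_log2fc) < 1)
    warning("|planted_log2fc| < 1: planted truths are below the 2-fold gate")
  out <- list(n_proteins = as.integer(n_proteins),
              sites_per_protein = sites_per_protein,
              frac_altered = frac_altered, planted_log2fc = planted_log2fc,
              replicate_cv = replicate_cv, missing_rate = missing_rate,
              decoy_rate = decoy_rate, varmod_rate = varmod_rate,
              loc_fail_rate = loc_fail_rate,
              explained_fraction = explained_fraction,
              sc_effect_frac = sc_effect_frac, sc_effect_size = sc_effect_size,
              seed = as.integer(seed))
  class(out) <- "truth_config"
  out
}

# internal: derive a stage seed from a master seed, kept well below 2^31
derive_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000000L) * 1009L + as.integer(k)
}
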