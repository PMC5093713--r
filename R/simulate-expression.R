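#' Imperfect-reprogramming state vocabulary
#'
#' The four significant states are defined by the sign pattern of the hiPSC
#' and SC group means relative to the hESC mean (log2 expression):
#' incomplete silencing (hiPSC > hESC, SC > hESC; somatic memory),
#' over-silencing (hiPSC < hESC, SC > hESC), incomplete reactivation
#' (hiPSC < hESC, SC < hESC) and over-reactivation (hiPSC > hESC,
#' SC < hESC). `unchanged` covers non-significant or tied genes.
#'
#' @return Character vector of the five state labels.
#' @export
reprogramming_state_levels <- function() {
  c("incomplete_silencing", "over_silencing",
    "incomplete_reactivation", "over_reactivation", "unchanged")
}

#' Simulate a probe-level expression matrix with planted reprogramming states
#'
#' Builds a microarray-style probes x samples matrix (linear intensities)
#' in which each planted gene's (hiPSC, hESC, SC) group means satisfy its
#' state's inequality pattern with a configurable log2 margin. A fraction of
#' genes receives a redundant second probe (lower total intensity) and a
#' separate low-intensity probe stratum is added so the probe filters have
#' something to remove.
#'
#' @param design An [experiment_design()] (cell types are taken from it;
#'   expression studies typically use fewer replicates than proteomics).
#' @param planted_states Named character vector, gene symbol -> state label
#'   from [reprogramming_state_levels()].
#' @param n_genes Total number of genes (planted genes included).
#' @param n_replicates Replicates per cell line (expression default 2).
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param margin Log2 offset applied to hiPSC/SC means to realize a state.
#' @param noise_sd Replicate noise sd in log2 units.
#' @param dup_frac Fraction of genes with a redundant second probe.
#' @param low_frac Number of low-intensity filler probes, as a fraction of
#'   `n_genes`.
#' @param seed Integer seed.
#'
#' @return List with `expr` (an [expression_set()]) and `states` (the
#'   planted gene -> state map, including `unchanged` for unplanted genes).
#' @export
simulate_expression <- function(design, planted_states, n_genes = 200L,
                                n_replicates = 2L, baseline_range = c(6, 12),
                                margin = 1, noise_sd = 0.2, dup_frac = 0.10,
                                low_frac = 0.10, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  planted_states <- unlist(planted_states)
  bad <- setdiff(unique(planted_states), reprogramming_state_levels())
  if (length(bad))
    stop("unknown state label(s): ", paste(bad, collapse = ", "))
  genes <- names(planted_states)
  if (length(genes) > n_genes) stop("`n_genes` smaller than planted gene count")
  filler <- sprintf("XG%04d", seq_len(n_genes - length(genes)))
  genes <- c(genes, filler)
  states <- c(planted_states,
              stats::setNames(rep("unchanged", length(filler)), filler))

  samples <- expand.grid(replicate = seq_len(n_replicates),
                         cell_line = design$cell_line,
                         stringsAsFactors = FALSE)
  samples$cell_type <- design$cell_type[match(samples$cell_line,
                                              design$cell_line)]
  samples <- data.frame(
    sample = paste(samples$cell_line, samples$replicate, sep = "_"),
    cell_line = samples$cell_line, cell_type = samples$cell_type,
    replicate = samples$replicate, stringsAsFactors = FALSE)

  delta <- matrix(c( 1,  1,   # incomplete_silencing: (hiPSC, SC) vs hESC
                    -1,  1,   # over_silencing
                    -1, -1,   # incomplete_reactivation
                     1, -1,   # over_reactivation
                     0,  0),  # unchanged
                  ncol = 2, byrow = TRUE,
                  dimnames = list(reprogramming_state_levels(),
                                  c("hiPSC", "SC")))

  ng <- length(genes)
  withr::with_seed(seed, {
    # planted (regulated) genes are genuinely expressed: they draw their
    # baseline from the upper half of the range so the low-intensity probe
    # filter exercises only the filler strata
    mid <- mean(baseline_range)
    base <- ifelse(states != "unchanged",
                   stats::runif(ng, mid, baseline_range[2]),
                   stats::runif(ng, baseline_range[1], baseline_range[2]))
    type_mean <- function(type) {
      if (type == "hESC") return(base)
      base + margin * delta[states, type]
    }
    mat <- sapply(seq_len(nrow(samples)), function(j) {
      type_mean(samples$cell_type[j]) + stats::rnorm(ng, 0, noise_sd)
    })
    # redundant probes: a lower-total duplicate for a fraction of genes
    dup_idx <- which(stats::runif(ng) < dup_frac)
    dup_mat <- mat[dup_idx, , drop = FALSE] - 1 +
      matrix(stats::rnorm(length(dup_idx) * nrow(samples), 0, noise_sd),
             nrow = length(dup_idx))
    # low-intensity stratum, below every sample's main distribution
    n_low <- round(low_frac * n_genes)
    low_mat <- matrix(stats::runif(n_low * nrow(samples), 0, 3),
                      nrow = n_low)
  })

  probe_ids <- c(sprintf("P%s_1", genes),
                 sprintf("P%s_2", genes[dup_idx]),
                 sprintf("PLOW%04d_1", seq_len(n_low)))
  probe_genes <- c(genes, genes[dup_idx], sprintf("LOWG%04d", seq_len(n_low)))
  full <- rbind(mat, dup_mat, low_mat)
  rownames(full) <- probe_ids
  colnames(full) <- samples$sample

  es <- expression_set(2^full, samples,
                       probe_map = data.frame(probe_id = probe_ids,
                                              gene_symbol = probe_genes,
                                              stringsAsFactors = FALSE))
  list(expr = es, states = states)
}
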