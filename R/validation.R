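#' Planted-truth recovery study for the quantitation stage
#'
#' Repeatedly simulates the nine-line experiment with planted alterations,
#' runs the identification filters, mean normalization, every hiPSC-vs-hESC
#' comparison and the voting rule, and scores recovery against the planted
#' truth: *sensitivity* is the fraction of planted sites that qualify as
#' general alterations in the planted direction; the *false-call rate* is
#' the fraction of unplanted sites that qualify.
#'
#' @param seeds Integer vector of simulation seeds (one replicate study per
#'   seed).
#' @param design An [experiment_design()] (default nine-line panel).
#' @param truth_args Named list overriding [truth_config()] fields; the
#'   study default plants 2.5-fold alterations at replicate CV 0.1.
#' @param k Voting threshold (default 5).
#' @return Data frame `seed`, `n_planted`, `sensitivity`, `false_call_rate`.
#' @export
quant_recovery_study <- function(seeds, design = default_design(),
                                 truth_args = list(), k = 5L) {
  defaults <- list(n_proteins = 80L, frac_altered = 0.15,
                   planted_log2fc = log2(2.5), replicate_cv = 0.1)
  do.call(rbind, lapply(seeds, function(s) {
    args <- utils::modifyList(defaults, truth_args)
    args$seed <- s
    tc <- do.call(truth_config, args)
    sim <- simulate_glyco_experiment(design, tc)
    rec <- validate_sites(filter_records(sim$table), sim$db)$records
    im <- mean_normalize(as_intensity_matrix(rec, design))
    plan <- expand.grid(a = design$cell_line[design$cell_type == "hiPSC"],
                        b = design$cell_line[design$cell_type == "hESC"],
                        stringsAsFactors = FALSE)
    comps <- lapply(seq_len(nrow(plan)), function(i)
      compare_lines(im, line_a = plan$a[i], line_b = plan$b[i]))
    v <- general_alterations(comps, k = k)
    truth_sites <- sim$truth$altered_sites
    got <- v$sites[match(truth_sites$site_id, v$sites$site_id), ]
    sens <- mean(got$qualifies & got$direction == truth_sites$direction,
                 na.rm = TRUE)
    null <- v$sites[!v$sites$site_id %in% truth_sites$site_id, , drop = FALSE]
    data.frame(seed = s, n_planted = nrow(truth_sites), sensitivity = sens,
               false_call_rate = mean(null$qualifies))
  }))
}

#' Planted-truth recovery study for the reprogramming-state stage
#'
#' Simulates an expression matrix with planted imperfect-reprogramming
#' states (default: margin 1 log2 unit, replicate noise sd 0.2, two
#' replicates per line), runs the full probe-filter / collapse / test /
#' classify stage, and reports the fraction of planted states recovered.
#'
#' @param seed Simulation seed.
#' @param design An [experiment_design()].
#' @param n_planted Number of planted genes.
#' @param margin,noise_sd Generator settings.
#' @return List with `recovery` (fraction in `[0, 1]`) and `calls`.
#' @export
state_recovery_study <- function(seed, design = default_design(),
                                 n_planted = 40L, margin = 1,
                                 noise_sd = 0.2) {
  planted <- withr::with_seed(derive_seed(seed, 7L), stats::setNames(
    sample(setdiff(reprogramming_state_levels(), "unchanged"),
           n_planted, replace = TRUE),
    sprintf("TG%03d", seq_len(n_planted))))
  sim <- simulate_expression(design, planted, n_genes = 3L * n_planted,
                             margin = margin, noise_sd = noise_sd,
                             seed = derive_seed(seed, 8L))
  calls <- call_reprogramming_states(sim$expr)
  got <- calls$state[match(names(planted), calls$gene)]
  list(recovery = mean(got == planted), calls = calls)
}
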