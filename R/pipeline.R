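#' Configuration of a full pipeline run
#'
#' Bundles the experiment design, the synthetic-truth parameters, the
#' pairwise comparison plan and every analysis threshold, plus one master
#' seed from which each stage deterministically derives its own seed (so a
#' stage re-run alone reproduces its in-pipeline output).
#'
#' @param design An [experiment_design()].
#' @param truth A [truth_config()].
#' @param comparisons Data frame `line_a`, `line_b`; defaults to
#'   [default_comparisons()] of the design (all hiPSC x hESC pairs, each
#'   hiPSC vs its parent, each hESC vs each SC).
#' @param min_score,min_prob,min_prob_replicates Identification gates.
#' @param cv_threshold,fold_threshold Quantitation gates.
#' @param vote_k Minimum same-direction calls for a general alteration.
#' @param note_threshold Calibration near-threshold fold.
#' @param confidence_threshold Interaction-confidence gate.
#' @param n_random Null networks for the randomization test.
#' @param probe_quantile Expression probe-filter quantile.
#' @param alpha Significance level for state calling.
#' @param proteome_match_fraction,proteome_cv Proteome simulation settings.
#' @param n_network_nodes,plurinet_size Network simulation sizes.
#' @param n_genes,n_state_genes,expression_margin,expression_noise_sd
#'   Expression simulation settings.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(design = default_design(),
                       truth = truth_config(),
                       comparisons = default_comparisons(design),
                       min_score = 50, min_prob = 0.8,
                       min_prob_replicates = 2L,
                       cv_threshold = 0.20, fold_threshold = 2,
                       vote_k = 5L, note_threshold = 1.75,
                       confidence_threshold = 0.7, n_random = 1000L,
                       probe_quantile = 0.20, alpha = 0.05,
                       proteome_match_fraction = 0.75, proteome_cv = 0.10,
                       n_network_nodes = 300L, plurinet_size = 45L,
                       n_genes = 200L, n_state_genes = 40L,
                       expression_margin = 1, expression_noise_sd = 0.2,
                       seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "truth_config"))
  bad <- setdiff(unique(c(comparisons$line_a, comparisons$line_b)),
                 design$cell_line)
  if (length(bad))
    stop("comparison plan references undesigned cell line(s): ",
         paste(bad, collapse = ", "))
  if (any(comparisons$line_a == comparisons$line_b))
    stop("a comparison must involve two distinct lines")
  if (fold_threshold < 1 || cv_threshold < 0 || cv_threshold > 1 ||
      min_prob < 0 || min_prob > 1 || probe_quantile < 0 ||
      probe_quantile >= 1 || alpha <= 0 || alpha > 1 ||
      confidence_threshold < 0 || confidence_threshold > 1)
    stop("a threshold lies outside its documented domain")
  if (vote_k > sum(design_pair_type(design, comparisons) == "hiPSC_vs_hESC"))
    stop("`vote_k` exceeds the number of hiPSC-vs-hESC comparisons")
  structure(list(
    design = design, truth = truth, comparisons = comparisons,
    min_score = min_score, min_prob = min_prob,
    min_prob_replicates = min_prob_replicates, cv_threshold = cv_threshold,
    fold_threshold = fold_threshold, vote_k = vote_k,
    note_threshold = note_threshold,
    confidence_threshold = confidence_threshold, n_random = n_random,
    probe_quantile = probe_quantile, alpha = alpha,
    proteome_match_fraction = proteome_match_fraction,
    proteome_cv = proteome_cv, n_network_nodes = n_network_nodes,
    plurinet_size = plurinet_size, n_genes = n_genes,
    n_state_genes = n_state_genes, expression_margin = expression_margin,
    expression_noise_sd = expression_noise_sd, seed = seed),
    class = "run_config")
}

# internal: label each planned comparison by the cell types it involves
design_pair_type <- function(design, comparisons) {
  ty <- function(x) design$cell_type[match(x, design$cell_line)]
  ta <- ty(comparisons$line_a); tb <- ty(comparisons$line_b)
  ifelse((ta == "hiPSC" & tb == "hESC") | (ta == "hESC" & tb == "hiPSC"),
         "hiPSC_vs_hESC",
         ifelse(ta == "SC" | tb == "SC", "PSC_vs_SC", "other"))
}

#' Standard comparison plan for a design
#'
#' All hiPSC x hESC pairs, each hiPSC against its parental somatic line,
#' and each hESC against each somatic line. For the nine-line reference
#' design this yields the 19-comparison plan (10 between PSC types, 9
#' against somatic cells).
#'
#' @param design An [experiment_design()].
#' @return Data frame `line_a`, `line_b`.
#' @export
default_comparisons <- function(design) {
  ipsc <- design$cell_line[design$cell_type == "hiPSC"]
  esc <- design$cell_line[design$cell_type == "hESC"]
  sc <- design$cell_line[design$cell_type == "SC"]
  plan <- expand.grid(line_a = ipsc, line_b = esc, stringsAsFactors = FALSE)
  parents <- design$parent[match(ipsc, design$cell_line)]
  has_par <- !is.na(parents)
  plan <- rbind(plan,
                data.frame(line_a = ipsc[has_par], line_b = parents[has_par],
                           stringsAsFactors = FALSE),
                expand.grid(line_a = esc, line_b = sc,
                            stringsAsFactors = FALSE))
  rownames(plan) <- NULL
  plan
}

#' Run the full pipeline end to end
#'
#' Simulates every input under the configured truth, writes them to
#' `out_dir` in their on-disk formats, then reads the glycosite table back
#' and executes the analysis stages in order: identification filtering and
#' sequon validation, QC, mean normalization, the pairwise comparison plan,
#' cross-comparison voting, proteome calibration (on the first
#' hiPSC-vs-hESC pair), candidate-PluriNet network significance and
#' enrichment, and reprogramming-state calling. All stage outputs are
#' written as tab-delimited tables plus a key-value run report; a fixed
#' master seed makes every output file byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result and `report_path`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- config$design
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## --- simulate inputs ------------------------------------------------
  truth_cfg <- config$truth
  truth_cfg$seed <- derive_seed(config$seed, 1L)
  sim <- simulate_glyco_experiment(design, truth_cfg)
  write_protein_fasta(sim$db, file.path(out_dir, "protein_db.fasta"))
  write_site_table(sim$table, file.path(out_dir, "glycosites.tsv"))
  proteome <- simulate_proteome(sim$truth, design,
                                match_fraction = config$proteome_match_fraction,
                                replicate_cv = config$proteome_cv,
                                seed = derive_seed(config$seed, 2L))
  tsv(proteome$table, "proteome.tsv")

  ## --- identification --------------------------------------------------
  records <- parse_site_table(file.path(out_dir, "glycosites.tsv"))
  records <- filter_records(records, min_score = config$min_score,
                            min_prob = config$min_prob,
                            min_prob_replicates = config$min_prob_replicates)
  val <- validate_sites(records, sim$db)
  records <- val$records
  tsv(val$excluded, "excluded_sites.tsv")
  idsum <- summarize_identifications(records, design)
  tsv(idsum$per_line, "identification_per_line.tsv")

  ## --- qc ---------------------------------------------------------------
  im <- as_intensity_matrix(records, design)
  qc_cor <- replicate_correlation(im)
  qc_det <- detection_breakdown(im)
  qc_cv <- cv_profile(im, threshold = config$cv_threshold)
  tree <- cluster_cell_lines(im)
  tsv(qc_cor, "qc_correlations.tsv")
  tsv(qc_det, "qc_detection.tsv")
  tsv(data.frame(cell_line = names(qc_cv$fraction_le_threshold),
                 fraction_cv_le_threshold = qc_cv$fraction_le_threshold,
                 row.names = NULL), "qc_cv.tsv")

  ## --- quantitation -----------------------------------------------------
  im <- mean_normalize(im)
  comps <- lapply(seq_len(nrow(config$comparisons)), function(i) {
    compare_lines(im, line_a = config$comparisons$line_a[i],
                  line_b = config$comparisons$line_b[i],
                  fold_threshold = config$fold_threshold,
                  cv_threshold = config$cv_threshold)
  })
  pair_type <- design_pair_type(design, config$comparisons)
  comp_summary <- data.frame(
    line_a = config$comparisons$line_a, line_b = config$comparisons$line_b,
    pair_type = pair_type,
    n_comparable_proteins = vapply(comps, function(r)
      r$counts$n_comparable_proteins, integer(1)),
    n_comparable_sites = vapply(comps, function(r)
      r$counts$n_comparable_sites, integer(1)),
    pct_altered_proteins = vapply(comps, function(r) {
      pc <- r$counts$proteins
      100 * sum(pc[c("up", "down", "both")]) / max(1L, sum(pc))
    }, numeric(1)))
  tsv(comp_summary, "comparison_summary.tsv")
  ipsc_esc <- comps[pair_type == "hiPSC_vs_hESC"]
  voting <- general_alterations(ipsc_esc, k = config$vote_k)
  tsv(voting$sites, "general_alterations.tsv")

  ## --- calibration (first hiPSC-vs-hESC pair) ---------------------------
  cal_comp <- ipsc_esc[[1]]
  pfolds <- protein_fold_changes(proteome$table, design,
                                 cal_comp$line_a, cal_comp$line_b)
  cal <- calibrate(cal_comp, pfolds, retain_threshold = config$fold_threshold,
                   note_threshold = config$note_threshold)
  cal_sum <- calibration_summary(cal)
  tsv(cal, "calibration.tsv")

  ## --- network significance ---------------------------------------------
  retained_prot <- unique(cal$protein_id[cal$status == "retained"])
  cand_genes <- unique(records$gene_symbol[records$protein_id %in%
                                             retained_prot])
  if (!length(cand_genes))
    cand_genes <- unique(voting$sites$gene_symbol[voting$sites$qualifies])
  net_sim <- simulate_network(n_nodes = config$n_network_nodes,
                              plurinet_size = config$plurinet_size,
                              candidates = cand_genes,
                              seed = derive_seed(config$seed, 3L))
  tsv(net_sim$edges, "network_edges.tsv")
  writeLines(net_sim$plurinet, file.path(out_dir, "plurinet.txt"))
  subnet <- build_subnetwork(net_sim$edges, net_sim$candidates,
                             net_sim$plurinet,
                             threshold = config$confidence_threshold)
  net_metrics <- randomization_test(subnet, n_random = config$n_random,
                                    seed = derive_seed(config$seed, 4L))
  fisher <- fisher_overlap(net_sim$edges, net_sim$candidates,
                           net_sim$plurinet,
                           threshold = config$confidence_threshold)
  gene_sets <- list(
    PLURINET_MODULE = net_sim$plurinet,
    CANDIDATE_NEIGHBOURHOOD = c(net_sim$candidates,
                                net_sim$plurinet[seq_len(10L)]),
    BACKGROUND_SET = sprintf("BG%04d", seq_len(50L)))
  write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  enr <- enrich_pathways(igraph::V(subnet)$name,
                         read_gmt(file.path(out_dir, "gene_sets.gmt")),
                         universe = unique(c(net_sim$edges$node_a,
                                             net_sim$edges$node_b)))
  tsv(enr, "pathway_enrichment.tsv")

  ## --- reprogramming states ---------------------------------------------
  state_genes <- sprintf("SG%03d", seq_len(config$n_state_genes))
  withr::with_seed(derive_seed(config$seed, 5L), {
    planted <- stats::setNames(
      sample(setdiff(reprogramming_state_levels(), "unchanged"),
             config$n_state_genes, replace = TRUE), state_genes)
  })
  expr_sim <- simulate_expression(design, planted,
                                  n_genes = config$n_genes,
                                  margin = config$expression_margin,
                                  noise_sd = config$expression_noise_sd,
                                  seed = derive_seed(config$seed, 6L))
  tsv(data.frame(probe_id = rownames(expr_sim$expr$expr),
                 expr_sim$expr$expr, check.names = FALSE),
      "expression.tsv")
  tsv(expr_sim$expr$probe_map, "probe_map.tsv")
  tsv(expr_sim$expr$samples, "samples.tsv")
  calls <- call_reprogramming_states(expr_sim$expr,
                                     quantile = config$probe_quantile,
                                     alpha = config$alpha)
  tsv(calls, "reprogramming_calls.tsv")
  planted_calls <- calls$state[match(state_genes, calls$gene)]
  state_recovery <- mean(planted_calls == planted[state_genes], na.rm = TRUE)

  ## --- run report --------------------------------------------------------
  report <- c(
    sprintf("n_cell_lines: %d", nrow(design)),
    sprintf("n_sites_identified: %d", nrow(records)),
    sprintf("sequon_tally_T: %d", val$tally["T"]),
    sprintf("sequon_tally_S: %d", val$tally["S"]),
    sprintf("sequon_tally_C: %d", val$tally["C"]),
    sprintf("proteins_shared_hPSC: %d", idsum$overlap$hPSC),
    sprintf("mean_pct_altered_PSC_vs_SC: %.2f",
            mean(comp_summary$pct_altered_proteins[pair_type == "PSC_vs_SC"])),
    sprintf("mean_pct_altered_hiPSC_vs_hESC: %.2f",
            mean(comp_summary$pct_altered_proteins[pair_type ==
                                                     "hiPSC_vs_hESC"])),
    sprintf("n_general_alteration_sites: %d", sum(voting$sites$qualifies)),
    sprintf("n_general_alteration_proteins: %d", nrow(voting$proteins)),
    sprintf("calibration_n_altered: %d", cal_sum$n_altered),
    sprintf("calibration_n_matched: %d", cal_sum$n_matched),
    sprintf("calibration_n_explained: %d", cal_sum$n_explained),
    sprintf("calibration_retained_pct: %.4f", cal_sum$retained_pct),
    sprintf("network_clustering_coefficient: %.6f",
            net_metrics$clustering_coefficient),
    sprintf("network_mean_shortest_path: %.6f",
            net_metrics$mean_shortest_path),
    sprintf("network_empirical_p_clustering: %.6f",
            net_metrics$empirical_p_clustering),
    sprintf("network_empirical_p_path: %.6f", net_metrics$empirical_p_path),
    sprintf("fisher_overlap_p: %.6g", fisher$p_value),
    sprintf("state_recovery: %.4f", state_recovery))
  report_path <- file.path(out_dir, "run_report.txt")
  writeLines(report, report_path)

  invisible(list(design = design, truth = sim$truth, records = records,
                 identification = idsum, qc = list(correlations = qc_cor,
                                                   detection = qc_det,
                                                   cv = qc_cv, tree = tree),
                 comparisons = comps, comparison_summary = comp_summary,
                 voting = voting, calibration = cal,
                 calibration_summary = cal_sum, network = net_metrics,
                 fisher = fisher, enrichment = enr, state_calls = calls,
                 state_recovery = state_recovery,
                 report_path = report_path))
}
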