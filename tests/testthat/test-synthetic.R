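test_that("protein database generation is seeded, validated and truthful", {
  db1 <- generate_protein_db(50, mean_length = 300, seed = 1)
  db2 <- generate_protein_db(50, mean_length = 300, seed = 1)
  expect_length(db1$proteins, 50L)
  expect_identical(as.character(db1$proteins), as.character(db2$proteins))
  expect_identical(db1$sequons, db2$sequons)
  expect_error(generate_protein_db(0), ">= 1")
  expect_error(generate_protein_db(5, mean_length = 10), ">= 20")

  # truth table equals an independent position-by-position rescan
  seqs <- as.character(db1$proteins)
  for (pid in names(seqs)) {
    expect_identical(db1$sequons$position[db1$sequons$protein_id == pid],
                     oracle_sequons(seqs[[pid]]))
  }
})

test_that("glyco simulation honours the null configuration and determinism", {
  des <- default_design()
  tc <- truth_config(n_proteins = 60, frac_altered = 0, seed = 11)
  sim1 <- simulate_glyco_experiment(des, tc)
  sim2 <- simulate_glyco_experiment(des, tc)
  expect_identical(sim1$table, sim2$table)
  expect_identical(sim1$truth$altered_sites$site_id, character(0))

  # null config: hiPSC and hESC group means agree (no planted shift)
  im <- sim1$matrix
  prof <- sapply(c("Gra1", "H9"), function(ln) {
    idx <- which(im$runs$cell_line == ln)
    rowMeans(log2(im$intensity[, idx, drop = FALSE]), na.rm = TRUE)
  })
  diff <- prof[, 1] - prof[, 2]
  expect_lt(abs(mean(diff, na.rm = TRUE)), 0.1)
})

test_that("planted fold changes are recovered at the configured magnitude", {
  des <- default_design()
  # Monte-Carlo across seeds: planted 2-fold truths give mean ratio ~ 2
  ratios <- unlist(lapply(1:6, function(s) {
    tc <- truth_config(n_proteins = 50, frac_altered = 0.3,
                       planted_log2fc = 1.0, replicate_cv = 0.1,
                       missing_rate = 0, decoy_rate = 0, varmod_rate = 0,
                       loc_fail_rate = 0, seed = s)
    sim <- simulate_glyco_experiment(des, tc)
    im <- sim$matrix
    ipsc <- which(im$runs$cell_type == "hiPSC")
    esc <- which(im$runs$cell_type == "hESC")
    lfc <- rowMeans(log2(im$intensity[, ipsc])) -
      rowMeans(log2(im$intensity[, esc]))
    alt <- match(sim$truth$altered_sites$site_id, im$features$feature_id)
    2^abs(lfc[alt])
  }))
  expect_gt(length(ratios), 30)
  expect_lt(abs(mean(ratios) - 2), 0.15)
})

test_that("decoy rows appear at the configured binomial rate", {
  des <- default_design()
  tc <- truth_config(n_proteins = 500, sites_per_protein = 3,
                     decoy_rate = 0.1, seed = 3)
  sim <- simulate_glyco_experiment(des, tc)
  n <- nrow(sim$table)
  n_decoy <- sum(sim$table$reverse_flag | sim$table$contaminant_flag)
  expect_gt(n, 500)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.1)
  expect_gte(n_decoy, ci[1])
  expect_lte(n_decoy, ci[2])
  expect_true(all(grepl("^(REV__|CON__)",
                        sim$table$protein_id[sim$table$reverse_flag |
                                               sim$table$contaminant_flag])))
})

test_that("proteome simulation matches the requested fraction of altered proteins", {
  des <- default_design()
  tc <- truth_config(n_proteins = 80, frac_altered = 0.3, seed = 7)
  sim <- simulate_glyco_experiment(des, tc)
  altered <- unique(sim$truth$altered_sites$protein_id)

  full <- simulate_proteome(sim$truth, des, match_fraction = 1, seed = 2)
  expect_true(all(altered %in% full$table$protein_id))
  none <- simulate_proteome(sim$truth, des, match_fraction = 0, seed = 2)
  expect_length(intersect(altered, none$matched_proteins), 0L)
  expect_error(simulate_proteome(sim$truth, des, match_fraction = 1.2),
               "match_fraction")

  half <- simulate_proteome(sim$truth, des, match_fraction = 0.5, seed = 2)
  expect_equal(length(half$matched_proteins), round(0.5 * length(altered)))
})

test_that("planted explained-by-protein proteins calibrate as explained", {
  des <- default_design()
  tc <- truth_config(n_proteins = 80, frac_altered = 0.3, replicate_cv = 0.1,
                     explained_fraction = 0.4, seed = 13)
  sim <- simulate_glyco_experiment(des, tc)
  prot <- simulate_proteome(sim$truth, des, match_fraction = 1,
                            replicate_cv = 0, seed = 5)
  # noise-free glyco folds straight from the truth, noise-free protein folds
  glyco <- data.frame(protein_id = sim$truth$altered_sites$protein_id,
                      site_id = sim$truth$altered_sites$site_id,
                      glyco_fold = 2^sim$truth$altered_sites$log2fc)
  pf <- protein_fold_changes(prot$table, des, "Gra1", "H9")
  cal <- calibrate(glyco, pf)
  truth_explained <- sim$truth$protein_level_changes$protein_id[
    sim$truth$protein_level_changes$explains_glyco]
  got_explained <- unique(cal$protein_id[cal$status == "explained_by_protein"])
  expect_setequal(got_explained, truth_explained)
  expect_true(all(cal$status[!cal$protein_id %in% truth_explained] ==
                    "retained"))
})

test_that("expression simulation realizes planted state patterns", {
  des <- default_design()
  planted <- c(g1 = "incomplete_silencing", g2 = "over_reactivation")
  sim <- simulate_expression(des, planted, n_genes = 50, noise_sd = 0,
                             seed = 4)
  es <- sim$expr
  x <- log2(es$expr)
  m <- sapply(c("hiPSC", "hESC", "SC"), function(ty)
    rowMeans(x[, es$samples$cell_type == ty, drop = FALSE]))
  g1 <- which(rownames(x) == "Pg1_1")
  expect_gt(m[g1, "hiPSC"], m[g1, "hESC"])
  expect_gt(m[g1, "SC"], m[g1, "hESC"])
  g2 <- which(rownames(x) == "Pg2_1")
  expect_gt(m[g2, "hiPSC"], m[g2, "hESC"])
  expect_lt(m[g2, "SC"], m[g2, "hESC"])
  expect_error(simulate_expression(des, c(g = "weird_state")), "unknown state")

  # redundant probes emitted for roughly the configured fraction of genes
  sim2 <- simulate_expression(des, planted, n_genes = 400, dup_frac = 0.1,
                              seed = 9)
  n_dup <- sum(grepl("_2$", rownames(sim2$expr$expr)))
  expect_gt(n_dup, 15); expect_lt(n_dup, 80)
})

test_that("network simulation plants exact high-confidence links and true degrees", {
  cands <- sprintf("CAND%02d", 1:5)
  net <- simulate_network(n_nodes = 120, plurinet_size = 20,
                          candidates = cands, planted_links = 5, seed = 21)
  e <- net$edges
  cp <- ((e$node_a %in% cands & e$node_b %in% net$plurinet) |
           (e$node_b %in% cands & e$node_a %in% net$plurinet)) &
    e$confidence >= 0.7
  expect_equal(sum(cp), 5L)

  # all candidates with a planted link survive the >=1-direct-interaction rule
  net5 <- simulate_network(n_nodes = 120, plurinet_size = 20,
                           candidates = cands, planted_links = 5, seed = 33)
  planted_cands <- unique(c(net5$planted_links$node_a,
                            net5$planted_links$node_b))
  planted_cands <- intersect(planted_cands, cands)
  sub <- build_subnetwork(net5$edges, cands, net5$plurinet)
  got <- igraph::V(sub)$name[igraph::V(sub)$role == "candidate"]
  expect_setequal(got, planted_cands)

  # no planted links -> empty candidate set, with a warning not an error
  net0 <- simulate_network(n_nodes = 120, plurinet_size = 20,
                           candidates = cands, planted_links = 0,
                           background_density = 0, seed = 2)
  expect_warning(sub0 <- build_subnetwork(net0$edges, cands, net0$plurinet),
                 "no candidate")
  expect_equal(igraph::vcount(sub0), 0L)

  # degree sequence of the igraph equals direct counting from the edge list
  g <- igraph::graph_from_data_frame(e[, 1:2], directed = FALSE)
  counted <- table(c(e$node_a, e$node_b))
  expect_equal(unname(igraph::degree(g)[names(counted)]),
               as.integer(counted))

  expect_error(simulate_network(n_nodes = 10, plurinet_size = 9,
                                candidates = cands), "too small")
})
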