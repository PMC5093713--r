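make_site_rows <- function(n = 3) {
  data.frame(
    site_id = sprintf("P%02d@10", seq_len(n)),
    protein_id = sprintf("P%02d", seq_len(n)),
    gene_symbol = sprintf("G%02d", seq_len(n)),
    position = 10L, sequence_window = "AAAAANGTAAA", peptide = "AANGTAA",
    localization_score = 120, localization_prob = 0.95,
    contaminant_flag = FALSE, reverse_flag = FALSE, varmod_flag = FALSE,
    intensity_IP1_1 = 100, intensity_IP1_2 = 110, intensity_IP1_3 = 90,
    stringsAsFactors = FALSE)
}

test_that("site tables round-trip with missing values preserved as missing", {
  tab <- make_site_rows(3)
  tab$intensity_IP1_2[2] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  got <- parse_site_table(path)
  expect_equal(nrow(got), 3L)
  expect_true(is.na(got$intensity_IP1_2[2]))
  expect_false(any(got$intensity_IP1_2 == 0, na.rm = TRUE))
})

test_that("malformed site tables fail with informative format errors", {
  tab <- make_site_rows(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab[, setdiff(names(tab), "localization_score")], path)
  expect_error(parse_site_table(path), "localization_score")

  tab2 <- make_site_rows(3)
  tab2$intensity_IP1_1 <- c("100", "oops", "90")
  write_site_table(tab2, path)
  expect_error(parse_site_table(path), "row 2")

  expect_error(parse_site_table("no/such/file.tsv"), "not found")
})

test_that("identification filters implement the inclusive localization gates", {
  tab <- make_site_rows(6)
  tab$locprob_IP1_1 <- c(0.95, 0.95, 0.85, 0.85, 0.95, 0.95)
  tab$locprob_IP1_2 <- c(0.95, 0.95, 0.85, 0.70, 0.95, 0.95)
  tab$locprob_IP1_3 <- c(0.95, 0.95, 0.70, 0.70, 0.95, 0.95)
  tab$reverse_flag[1] <- TRUE                   # decoy: removed
  tab$localization_score[2] <- 49.9             # below score gate: removed
  tab$localization_score[5] <- 50.0             # at the gate: kept
  # row 3: prob >= 0.8 in exactly 2 of 3 replicates -> kept
  # row 4: prob >= 0.8 in only 1 replicate -> removed
  out <- filter_records(tab)
  expect_setequal(out$protein_id, c("P03", "P05", "P06"))

  # idempotence
  expect_identical(filter_records(out), out)

  # empty in, empty out
  expect_equal(nrow(filter_records(tab[0, ])), 0L)

  # without per-run columns the single probability column is gated
  tab2 <- make_site_rows(2)
  tab2$localization_prob <- c(0.79, 0.80)
  expect_equal(filter_records(tab2)$protein_id, "P02")
})

test_that("sequon scanning follows the N-X!=P-[S/T/C] rule", {
  expect_equal(find_sequons("ANGTA")$position, 2L)
  expect_equal(find_sequons("ANGTA")$third_residue, "T")
  expect_equal(nrow(find_sequons("ANPSA")), 0L)   # X = P never matches
  expect_equal(find_sequons("NNSS")$position, c(1L, 2L))  # overlapping hits
  expect_equal(nrow(find_sequons("NG")), 0L)      # too close to the end
  expect_equal(nrow(find_sequons("NXS")), 1L)     # unknown X still != P
  expect_equal(nrow(find_sequons("NGX")), 0L)     # unknown third never matches
})

test_that("sequon scanning agrees with the exhaustive triple-scan oracle", {
  withr::with_seed(42, {
    for (i in 1:300) {
      s <- random_sequence(sample(3:60, 1))
      expect_identical(find_sequons(s)$position, oracle_sequons(s),
                       label = s)
    }
  })
})

test_that("site validation enforces the sequon rule against the database", {
  db <- c(P1 = "AAAANGTAAA", P2 = "AAAANPSAAA")
  rec <- data.frame(site_id = c("a", "b", "c"),
                    protein_id = c("P1", "P2", "P9"),
                    position = c(5L, 5L, 5L), stringsAsFactors = FALSE)
  expect_warning(out <- validate_sites(rec, db), "absent")
  expect_equal(out$records$site_id, "a")
  expect_equal(unname(out$tally), c(1L, 0L, 0L))  # one T-site
  expect_setequal(out$excluded$reason, c("not_sequon", "protein_not_in_db"))

  # never passes an N+1 = P site; tally always sums to the valid count
  des <- default_design()
  sim <- simulate_glyco_experiment(des, truth_config(n_proteins = 40, seed = 8))
  res <- validate_sites(filter_records(sim$table), sim$db)
  expect_equal(sum(res$tally), nrow(res$records))
  seqs <- as.character(sim$db$proteins)
  xres <- substr(seqs[res$records$protein_id], res$records$position + 1L,
                 res$records$position + 1L)
  expect_false(any(xres == "P"))
})

test_that("identification summaries match exhaustive set algebra", {
  des <- default_design()
  sim <- simulate_glyco_experiment(des, truth_config(n_proteins = 60,
                                                     missing_rate = 0.3,
                                                     seed = 19))
  rec <- validate_sites(filter_records(sim$table), sim$db)$records
  s <- summarize_identifications(rec, des)

  # oracle: recompute protein sets per line by brute force
  icols <- grep("^intensity_", names(rec), value = TRUE)
  prot_line <- lapply(des$cell_line, function(ln) {
    cols <- icols[grepl(paste0("^intensity_", ln, "_"), icols)]
    unique(rec$protein_id[rowSums(!is.na(rec[, cols])) > 0])
  })
  names(prot_line) <- des$cell_line
  expect_equal(s$per_line$n_proteins, unname(lengths(prot_line)))
  by_type <- lapply(c("hiPSC", "hESC", "SC"), function(ty)
    unique(unlist(prot_line[des$cell_line[des$cell_type == ty]])))
  expect_equal(s$overlap$hPSC, length(intersect(by_type[[1]], by_type[[2]])))
  expect_equal(s$overlap$all_types, length(Reduce(intersect, by_type)))

  # two lines with identical protein sets overlap fully; disjoint sets at 0
  des2 <- experiment_design(c("A", "B"), c("hiPSC", "hESC"), n_replicates = 2)
  rec2 <- data.frame(site_id = c("s1", "s2"), protein_id = c("P1", "P2"),
                     peptide = c("PEP1", "PEP2"),
                     intensity_A_1 = c(1, 2), intensity_A_2 = c(1, 2),
                     intensity_B_1 = c(1, 2), intensity_B_2 = c(1, 2),
                     stringsAsFactors = FALSE)
  s2 <- summarize_identifications(rec2, des2)
  expect_equal(s2$overlap$hPSC, 2L)
  rec3 <- rec2
  rec3$intensity_B_1[1] <- NA; rec3$intensity_B_2[1] <- NA
  rec3$intensity_A_1[2] <- NA; rec3$intensity_A_2[2] <- NA
  expect_equal(summarize_identifications(rec3, des2)$overlap$hPSC, 0L)
})
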