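test_that("mean normalization equalizes run means and preserves ratios", {
  des <- experiment_design(c("A", "B"), c("hiPSC", "hESC"), n_replicates = 2)
  x <- matrix(c(5, 15, 10, 30, 20, 60, 40, 120,
                15, 5, 30, 10, 60, 20, 120, 40), ncol = 4)
  im <- make_im(x, des)
  nn <- mean_normalize(im)
  cm <- colMeans(nn$intensity, na.rm = TRUE)
  expect_true(all(abs(cm - mean(colMeans(x))) < 1e-9))
  # within-run ratios unchanged
  expect_equal(nn$intensity[1, 1] / nn$intensity[2, 1], x[1, 1] / x[2, 1])
  # already-equal means: identity
  y <- matrix(c(1, 3, 2, 2, 1, 3, 3, 2, 1, 1, 2, 3), ncol = 4)
  expect_equal(mean_normalize(make_im(y, des))$intensity,
               make_im(y, des)$intensity)
  # all-missing run is an error naming the run
  z <- x; z[, 2] <- NA
  expect_error(mean_normalize(make_im(z, des)), "A_2")
})

test_that("pairwise comparison applies fold, CV and varmod gates", {
  des <- tiny_design()
  x <- matrix(NA_real_, 5, 9)
  x[1, ] <- c(4, 4, 4, 2, 2, 2, 1, 1, 1)      # exact 2-fold, call up
  x[2, ] <- c(4, 4, 4, 2, 2, 3.2, 1, 1, 1)    # CV > 0.2 in ES1: no call
  x[3, ] <- c(4, 4, 4, 2, 2, 2, 1, 1, 1)      # varmod flagged: excluded
  x[4, ] <- c(4, 4, 4, NA, NA, NA, 1, 1, 1)   # missing in ES1: not comparable
  x[5, ] <- c(3, 3, 3, 2, 2, 2, 1, 1, 1)      # 1.5-fold: unchanged
  im <- make_im(x, des, varmod = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  res <- compare_lines(im, line_a = "IP1", line_b = "ES1")
  s <- res$sites
  expect_equal(s$call[1], "up")
  expect_equal(s$fold_change[1], 2.0)
  expect_false(s$comparable[2])
  expect_false(s$comparable[3])
  expect_false(s$comparable[4])
  expect_equal(s$call[5], "unchanged")
  expect_equal(res$counts$n_comparable_sites, 2L)
  expect_error(compare_lines(im, line_a = "IP1", line_b = "nope"),
               "unknown cell line")
})

test_that("swapping the two lines inverts folds and exchanges calls", {
  des <- default_design()
  sim <- simulate_glyco_experiment(des, truth_config(n_proteins = 60,
                                                     frac_altered = 0.3,
                                                     seed = 17))
  im <- mean_normalize(sim$matrix)
  ab <- compare_lines(im, line_a = "Gra1", line_b = "H9")
  ba <- compare_lines(im, line_a = "H9", line_b = "Gra1")
  expect_equal(ab$sites$comparable, ba$sites$comparable)
  ok <- ab$sites$comparable
  expect_equal(ab$sites$fold_change[ok], 1 / ba$sites$fold_change[ok])
  map <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_equal(unname(map[ab$sites$call[ok]]), ba$sites$call[ok])
  # counts table equals exhaustive recount from per-site calls
  expect_equal(unname(ab$counts$sites["up"]),
               sum(ab$sites$call == "up", na.rm = TRUE))
  expect_equal(unname(ab$counts$sites["down"]),
               sum(ab$sites$call == "down", na.rm = TRUE))
  expect_equal(ab$counts$n_comparable_sites, sum(ab$sites$comparable))
})

test_that("protein rollup follows the up/down/both rule", {
  sites <- data.frame(
    protein_id = c("P1", "P1", "P2", "P2", "P3", "P4"),
    call = c("up", "unchanged", "up", "down", "unchanged", "down"),
    stringsAsFactors = FALSE)
  r <- protein_rollup(sites)
  expect_equal(r$category[r$protein_id == "P1"], "up")
  expect_equal(r$category[r$protein_id == "P2"], "both")
  expect_equal(r$category[r$protein_id == "P3"], "unchanged")
  expect_equal(r$category[r$protein_id == "P4"], "down")
})

test_that("general-alteration voting requires k consistent calls", {
  des <- experiment_design(c("A", "B"), c("hiPSC", "hESC"), n_replicates = 2)
  mk <- function(calls) {
    # one comparison result carrying the given single-site call
    s <- data.frame(site_id = "s1", protein_id = "P1", gene_symbol = "G1",
                    mean_a = 1, mean_b = 1, cv_a = 0, cv_b = 0,
                    comparable = !is.na(calls), fold_change = 1,
                    call = calls, stringsAsFactors = FALSE)
    structure(list(line_a = "A", line_b = "B", sites = s),
              class = "comparison_result")
  }
  vote <- function(calls, k = 5, consistency = TRUE) {
    res <- lapply(calls, mk)
    general_alterations(res, k = k, require_consistency = consistency)
  }
  v1 <- vote(c(rep("up", 6), rep("unchanged", 4)))       # 6 up, 0 down
  expect_true(v1$sites$qualifies)
  expect_equal(v1$sites$direction, "up")
  v2 <- vote(c(rep("up", 4), rep("unchanged", 6)))       # below k
  expect_false(v2$sites$qualifies)
  v3 <- vote(c(rep("up", 5), rep("down", 3), rep("unchanged", 2)))
  expect_false(v3$sites$qualifies)                       # inconsistent
  v4 <- vote(c(rep("up", 5), rep("down", 3), rep("unchanged", 2)),
             consistency = FALSE)
  expect_true(v4$sites$qualifies)
  expect_error(vote(rep("up", 3), k = 5), "cannot exceed")
})

test_that("planted alterations are recovered with high sensitivity", {
  # single-seed version of the multi-seed acceptance study
  des <- default_design()
  tc <- truth_config(n_proteins = 60, frac_altered = 0.15,
                     planted_log2fc = log2(2.5), replicate_cv = 0.1,
                     seed = 101)
  sim <- simulate_glyco_experiment(des, tc)
  rec <- validate_sites(filter_records(sim$table), sim$db)$records
  im <- mean_normalize(as_intensity_matrix(rec, des))
  plan <- expand.grid(a = des$cell_line[des$cell_type == "hiPSC"],
                      b = des$cell_line[des$cell_type == "hESC"],
                      stringsAsFactors = FALSE)
  comps <- lapply(seq_len(nrow(plan)), function(i)
    compare_lines(im, line_a = plan$a[i], line_b = plan$b[i]))
  v <- general_alterations(comps, k = 5)
  truth_sites <- sim$truth$altered_sites
  got <- v$sites[match(truth_sites$site_id, v$sites$site_id), ]
  sens <- mean(got$qualifies & got$direction == truth_sites$direction,
               na.rm = TRUE)
  expect_gte(sens, 0.9)
  null_sites <- v$sites[!v$sites$site_id %in% truth_sites$site_id, ]
  expect_lte(mean(null_sites$qualifies), 0.05)
})
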