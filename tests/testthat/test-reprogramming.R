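test_that("probe filtering removes only uniformly bottom-quantile probes", {
  des <- tiny_design(n_replicates = 2)
  samples <- data.frame(sample = paste0("s", 1:6),
                        cell_line = rep(c("IP1", "ES1", "SC1"), each = 2),
                        cell_type = rep(c("hiPSC", "hESC", "SC"), each = 2),
                        replicate = rep(1:2, 3))
  x <- matrix(100, 10, 6, dimnames = list(sprintf("pr%02d", 1:10),
                                          samples$sample))
  x[1:8, ] <- matrix(rep(seq(10, 80, by = 10), 6), ncol = 6)
  x[9, ] <- 1          # bottom 20% of every sample: removed
  x[10, ] <- c(1, 1, 1, 1, 1, 95)  # above the cut in one sample: kept
  pm <- data.frame(probe_id = rownames(x), gene_symbol = rownames(x))
  es <- expression_set(x, samples, pm)
  f <- filter_probes(es, quantile = 0.20)
  expect_false("pr09" %in% rownames(f$expr))
  expect_true("pr10" %in% rownames(f$expr))
  # quantile zero removes nothing
  expect_equal(nrow(filter_probes(es, quantile = 0)$expr), 10L)
})

test_that("probe collapse keeps the highest-total probe with lexicographic ties", {
  samples <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                        cell_line = c("A", "A", "B", "B"),
                        cell_type = c("hiPSC", "hiPSC", "hESC", "hESC"),
                        replicate = c(1, 2, 1, 2))
  x <- rbind(g1_hi = c(30, 30, 20, 20),   # total 100
             g1_lo = c(20, 20, 20, 20),   # total 80
             g2_b  = c(25, 25, 25, 25),   # tie with g2_a
             g2_a  = c(25, 25, 25, 25),
             g3    = c(9, 9, 9, 9),
             orphan = c(50, 50, 50, 50))  # unmapped: dropped
  colnames(x) <- samples$sample
  pm <- data.frame(probe_id = c("g1_hi", "g1_lo", "g2_b", "g2_a", "g3"),
                   gene_symbol = c("G1", "G1", "G2", "G2", "G3"))
  es <- expression_set(x, samples, pm)
  expect_message(out <- collapse_probes(es), "without gene mapping")
  expect_setequal(rownames(out$expr), c("G1", "G2", "G3"))
  expect_equal(unname(out$expr["G1", "a1"]), 30)
  expect_equal(out$probe_map$probe_id[out$probe_map$gene_symbol == "G2"],
               "g2_a")   # lexicographically smaller of the tie
  # single-probe gene passes through unchanged
  expect_equal(unname(out$expr["G3", ]), rep(9, 4), ignore_attr = TRUE)
})

test_that("Welch test matches the textbook formula and its edge cases", {
  samples <- data.frame(sample = paste0("s", 1:8),
                        cell_line = rep(c("I1", "I2", "E1", "E2"), each = 2),
                        cell_type = rep(c("hiPSC", "hiPSC", "hESC", "hESC"),
                                        each = 2),
                        replicate = rep(1:2, 4))
  withr::with_seed(3, x <- matrix(2^rnorm(80, 8, 1), 10, 8))
  colnames(x) <- samples$sample
  rownames(x) <- sprintf("g%02d", 1:10)
  pm <- data.frame(probe_id = rownames(x), gene_symbol = rownames(x))
  es <- expression_set(x, samples, pm)
  dt <- differential_test(es)
  # independent direct-formula oracle
  for (i in 1:10) {
    a <- log2(x[i, 1:4]); b <- log2(x[i, 5:8])
    va <- var(a) / 4; vb <- var(b) / 4
    t_or <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_or <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
    p_or <- 2 * pt(-abs(t_or), df_or)
    expect_equal(dt$t[i], t_or, tolerance = 1e-10)
    expect_equal(dt$p[i], p_or, tolerance = 1e-10)
  }
  # identical groups: p = 1
  y <- x; y[1, ] <- 16
  es2 <- expression_set(y, samples, pm)
  dt2 <- differential_test(es2)
  expect_equal(dt2$t[1], 0)
  expect_equal(dt2$p[1], 1)
  # planted 3-log2-unit separation at tiny noise is highly significant
  withr::with_seed(4, z <- c(2^(10 + rnorm(4, 0, 0.1)),
                             2^(7 + rnorm(4, 0, 0.1))))
  y[2, ] <- z
  expect_lt(differential_test(expression_set(y, samples, pm))$p[2], 0.005)
})

test_that("state classification covers the exhaustive sign truth table", {
  expect_equal(classify_state(8, 4, 9, TRUE), "incomplete_silencing")
  expect_equal(classify_state(2, 4, 9, TRUE), "over_silencing")
  expect_equal(classify_state(2, 4, 1, TRUE), "incomplete_reactivation")
  expect_equal(classify_state(6, 4, 2, TRUE), "over_reactivation")
  expect_equal(classify_state(4, 4, 9, TRUE), "unchanged")  # tie
  expect_equal(classify_state(8, 4, 9, FALSE), "unchanged") # not significant

  # all 9 sign combinations of (hiPSC - hESC, SC - hESC)
  deltas <- c(-1, 0, 1)
  expected <- matrix(c(
    "incomplete_reactivation", "unchanged", "over_silencing",
    "unchanged",               "unchanged", "unchanged",
    "over_reactivation",       "unchanged", "incomplete_silencing"),
    nrow = 3, byrow = TRUE,
    dimnames = list(ipsc = deltas, sc = deltas))
  for (di in deltas) for (ds in deltas) {
    got <- classify_state(5 + di, 5, 5 + ds, TRUE)
    expect_equal(got, expected[as.character(di), as.character(ds)],
                 label = sprintf("di=%d ds=%d", di, ds))
  }
  # the four significant states partition the strict-sign space
  strict <- expand.grid(di = c(-1, 1), ds = c(-1, 1))
  states <- mapply(function(di, ds) classify_state(5 + di, 5, 5 + ds, TRUE),
                   strict$di, strict$ds)
  expect_setequal(states, setdiff(reprogramming_state_levels(), "unchanged"))
})

test_that("planted reprogramming states are recovered from synthetic expression", {
  des <- default_design()
  withr::with_seed(12, {
    planted <- setNames(sample(setdiff(reprogramming_state_levels(),
                                       "unchanged"), 40, replace = TRUE),
                        sprintf("TG%02d", 1:40))
  })
  sim <- simulate_expression(des, planted, n_genes = 120, margin = 1,
                             noise_sd = 0.2, seed = 6)
  calls <- suppressMessages(call_reprogramming_states(sim$expr))
  got <- calls$state[match(names(planted), calls$gene)]
  expect_gte(mean(got == planted), 0.95)
  # unplanted genes overwhelmingly stay unchanged
  bg <- calls$state[grepl("^XG", calls$gene)]
  expect_gte(mean(bg == "unchanged"), 0.85)
})
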