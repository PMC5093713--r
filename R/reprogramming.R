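#' Probe-level expression container
#'
#' @param expr Numeric matrix of non-negative expression values, probes x
#'   samples.
#' @param samples Data frame `sample`, `cell_line`, `cell_type`,
#'   `replicate`; every cell line must have at least two replicates.
#' @param probe_map Data frame `probe_id`, `gene_symbol` mapping probes to
#'   genes (probes absent from the map are allowed until
#'   [collapse_probes()]).
#' @return Object of class `expression_set`.
#' @export
expression_set <- function(expr, samples, probe_map) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  need <- c("sample", "cell_line", "cell_type", "replicate")
  if (!all(need %in% names(samples)))
    stop("`samples` must contain columns: ", paste(need, collapse = ", "))
  if (!identical(colnames(expr), as.character(samples$sample)))
    stop("column names of `expr` must equal `samples$sample`")
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  bad <- setdiff(unique(samples$cell_type), c("hiPSC", "hESC", "SC"))
  if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  reps <- table(samples$cell_line)
  if (any(reps < 2L))
    stop("every cell line needs >= 2 replicate samples")
  structure(list(expr = expr, samples = samples, probe_map = probe_map),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d probes x %d samples (%d cell lines)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$samples$cell_line))))
  invisible(x)
}

#' Remove uniformly low-intensity probes
#'
#' A probe is excluded iff its value lies strictly below the per-sample
#' bottom `quantile` cut in **every** sample; a probe above the cut in even
#' one sample is kept. With `quantile = 0` nothing is removed.
#'
#' @param es An [expression_set()].
#' @param quantile Bottom quantile (default 0.20).
#' @return The filtered [expression_set()].
#' @export
filter_probes <- function(es, quantile = 0.20) {
  if (quantile < 0 || quantile >= 1) stop("`quantile` must lie in [0, 1)")
  cuts <- apply(es$expr, 2L, stats::quantile, probs = quantile, na.rm = TRUE)
  below_all <- rowSums(sweep(es$expr, 2L, cuts, `<`)) == ncol(es$expr)
  es$expr <- es$expr[!below_all, , drop = FALSE]
  es
}

#' Collapse redundant probes to one probe per gene
#'
#' Keeps, for each gene, the single probe with the highest total intensity
#' across samples (ties broken by the lexicographically smaller probe id).
#' Probes without a gene mapping are dropped and their count reported in a
#' message. Row names of the result are gene symbols.
#'
#' @param es An [expression_set()].
#' @return A gene-level [expression_set()].
#' @export
collapse_probes <- function(es) {
  gene <- es$probe_map$gene_symbol[match(rownames(es$expr),
                                         es$probe_map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped))
    message(sum(unmapped), " probe(s) without gene mapping dropped")
  expr <- es$expr[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  totals <- rowSums(expr, na.rm = TRUE)
  ord <- order(gene, -totals, rownames(expr))
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)   # row-order invariance of the output
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  es$expr <- out
  es$probe_map <- data.frame(probe_id = rownames(expr)[keep][order(gene[keep])],
                             gene_symbol = sort(gene[keep]),
                             stringsAsFactors = FALSE)
  es
}

#' Per-gene Welch t-test between two cell-type groups
#'
#' Two-sided Welch (unequal-variance) t-test on log2 expression, pooling all
#' replicate samples of each group's cell lines. When both groups are
#' constant: equal means give `t = 0, p = 1`; unequal means give an
#' infinite statistic and the smallest representable positive p.
#'
#' @param es A gene-level [expression_set()] (after [collapse_probes()]).
#' @param group_a,group_b Cell types to compare (defaults hiPSC vs hESC).
#' @param log2 Log2-transform before testing (default `TRUE`).
#' @return Data frame `gene`, `mean_a`, `mean_b`, `t`, `p`.
#' @export
differential_test <- function(es, group_a = "hiPSC", group_b = "hESC",
                              log2 = TRUE) {
  ia <- which(es$samples$cell_type == group_a)
  ib <- which(es$samples$cell_type == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per group")
  x <- if (log2) base::log2(es$expr) else es$expr
  res <- t(apply(x, 1L, function(v) {
    a <- v[ia]; b <- v[ib]
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {        # essentially constant data
      if (isTRUE(all.equal(mean(a), mean(b))))
        c(mean(a), mean(b), 0, 1)
      else
        c(mean(a), mean(b), sign(mean(a) - mean(b)) * Inf,
          .Machine$double.xmin)
    } else c(mean(a), mean(b), unname(tt$statistic), tt$p.value)
  }))
  data.frame(gene = rownames(x), mean_a = res[, 1], mean_b = res[, 2],
             t = res[, 3], p = res[, 4],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a gene's imperfect-reprogramming state
#'
#' Given the three group means (log2) and a significance indicator from the
#' hiPSC-vs-hESC test, assigns one of the four states by the strict sign
#' pattern of the hiPSC and SC means relative to the hESC mean:
#' `incomplete_silencing` (hiPSC > hESC and SC > hESC, somatic memory),
#' `over_silencing` (hiPSC < hESC and SC > hESC),
#' `incomplete_reactivation` (hiPSC < hESC and SC < hESC),
#' `over_reactivation` (hiPSC > hESC and SC < hESC).
#' Non-significant genes, and equality in either governing comparison, give
#' `unchanged`. All arguments are vectorized.
#'
#' @param mean_ipsc,mean_esc,mean_sc Group means (log2 expression).
#' @param significant Logical from the differential test.
#' @return Character vector of state labels.
#' @export
classify_state <- function(mean_ipsc, mean_esc, mean_sc, significant) {
  n <- max(length(mean_ipsc), length(mean_esc), length(mean_sc),
           length(significant))
  mean_ipsc <- rep_len(mean_ipsc, n); mean_esc <- rep_len(mean_esc, n)
  mean_sc <- rep_len(mean_sc, n); significant <- rep_len(significant, n)
  i_gt <- mean_ipsc > mean_esc; i_lt <- mean_ipsc < mean_esc
  s_gt <- mean_sc > mean_esc; s_lt <- mean_sc < mean_esc
  state <- rep("unchanged", n)
  state[significant & i_gt & s_gt] <- "incomplete_silencing"
  state[significant & i_lt & s_gt] <- "over_silencing"
  state[significant & i_lt & s_lt] <- "incomplete_reactivation"
  state[significant & i_gt & s_lt] <- "over_reactivation"
  state
}

#' Full transcriptomic reprogramming-state stage
#'
#' Filters low-intensity probes, collapses redundancy to one probe per
#' gene, computes per-cell-type log2 group means, tests hiPSC vs hESC with
#' a Welch t-test, and classifies every gene into an
#' imperfect-reprogramming state at the chosen significance level.
#'
#' @param es An [expression_set()] (probe level, already normalized).
#' @param quantile Probe-filter bottom quantile (default 0.20).
#' @param alpha Significance level for state calling (default 0.05).
#' @return Data frame `gene`, `mean_ipsc`, `mean_esc`, `mean_sc`, `t`, `p`,
#'   `state`.
#' @export
call_reprogramming_states <- function(es, quantile = 0.20, alpha = 0.05) {
  es <- filter_probes(es, quantile = quantile)
  es <- collapse_probes(es)
  x <- log2(es$expr)
  type_mean <- function(ty) {
    idx <- which(es$samples$cell_type == ty)
    rowMeans(x[, idx, drop = FALSE], na.rm = TRUE)
  }
  m_i <- type_mean("hiPSC"); m_e <- type_mean("hESC"); m_s <- type_mean("SC")
  dt <- differential_test(es, "hiPSC", "hESC")
  data.frame(gene = rownames(x), mean_ipsc = m_i, mean_esc = m_e,
             mean_sc = m_s, t = dt$t, p = dt$p,
             state = classify_state(m_i, m_e, m_s, dt$p < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
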