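# shared fixture builders: everything is generated in code at test time

tiny_design <- function(n_replicates = 3L) {
  experiment_design(cell_lines = c("IP1", "ES1", "SC1"),
                    cell_types = c("hiPSC", "hESC", "SC"),
                    parents = c("SC1", NA, NA),
                    n_replicates = n_replicates)
}

# intensity matrix from a features x runs value matrix and a design
make_im <- function(values, design, varmod = NULL) {
  runs <- design_runs(design)
  stopifnot(ncol(values) == nrow(runs))
  colnames(values) <- runs$run
  features <- data.frame(
    feature_id = sprintf("site%03d", seq_len(nrow(values))),
    protein_id = sprintf("P%03d", seq_len(nrow(values))),
    gene_symbol = sprintf("G%03d", seq_len(nrow(values))),
    varmod_flag = if (is.null(varmod)) rep(FALSE, nrow(values)) else varmod,
    stringsAsFactors = FALSE)
  intensity_matrix(values, runs, features)
}

# independent triple-scan sequon oracle (deliberately naive, loop-based)
oracle_sequons <- function(sequence) {
  s <- toupper(sequence)
  hits <- integer(0)
  if (nchar(s) >= 3L) {
    for (i in 1:(nchar(s) - 2L)) {
      if (substr(s, i, i) == "N" &&
          substr(s, i + 1L, i + 1L) != "P" &&
          substr(s, i + 2L, i + 2L) %in% c("S", "T", "C"))
        hits <- c(hits, i)
    }
  }
  hits
}

# exact upper-tail hypergeometric sum for a 2x2 table [[a,b],[c,d]],
# enrichment of 'a' given fixed margins
oracle_hyper_tail <- function(a, b, c, d) {
  K <- a + b; N <- a + b + c + d; n <- a + c
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# random amino-acid-like sequence, occasionally with unknown letters
random_sequence <- function(len) {
  alpha <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
             "S","T","W","Y","V","X","B")
  paste(sample(alpha, len, replace = TRUE,
               prob = c(rep(1, 20), 0.2, 0.2)), collapse = "")
}
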