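#' Simulate a confidence-scored protein interaction edge list
#'
#' Emits an undirected edge list in the style of a STRING export: node pairs
#' with a confidence score in (0, 1). Exactly `planted_links` distinct
#' candidate-PluriNet pairs are planted at high confidence (>= 0.7), the
#' PluriNet module itself is densely wired (local structure a uniform
#' random background would lack; degree-preserving nulls retain much of it,
#' so small empirical p-values are not guaranteed on synthetic data), and
#' the remainder is random background in which candidate-PluriNet pairs are
#' capped below the confidence threshold so the planted count is exact.
#'
#' @param n_nodes Total number of nodes.
#' @param plurinet_size Number of PluriNet nodes.
#' @param candidates Character vector of candidate gene symbols.
#' @param planted_links Number of distinct high-confidence candidate-PluriNet
#'   edges to plant.
#' @param background_density Edge density of the random background.
#' @param plurinet_density Edge density within the PluriNet module.
#' @param seed Integer seed.
#'
#' @return List with `edges` (data frame `node_a`, `node_b`, `confidence`),
#'   `plurinet` (node names), `candidates`, and `planted_links` (data frame
#'   of the planted pairs).
#' @export
simulate_network <- function(n_nodes = 300L, plurinet_size = 45L, candidates,
                             planted_links = 2L * length(candidates),
                             background_density = 0.01,
                             plurinet_density = 0.25, seed = 1L) {
  candidates <- unique(toupper(candidates))
  n_cand <- length(candidates)
  if (plurinet_size + n_cand > n_nodes)
    stop("`n_nodes` too small for the requested candidates and PluriNet")
  if (planted_links > n_cand * plurinet_size)
    stop("`planted_links` exceeds the number of candidate-PluriNet pairs")
  plurinet <- sprintf("PLURI%03d", seq_len(plurinet_size))
  background <- sprintf("BG%04d", seq_len(n_nodes - plurinet_size - n_cand))
  nodes <- c(candidates, plurinet, background)

  withr::with_seed(seed, {
    # planted candidate-PluriNet links, distinct pairs, confidence >= 0.7
    pairs <- expand.grid(node_a = candidates, node_b = plurinet,
                         stringsAsFactors = FALSE)
    planted <- pairs[sample(nrow(pairs), planted_links), , drop = FALSE]
    planted$confidence <- stats::runif(planted_links, 0.70, 0.99)

    # dense PluriNet module
    pn_pairs <- utils::combn(plurinet, 2L)
    keep <- stats::runif(ncol(pn_pairs)) < plurinet_density
    pn_edges <- data.frame(node_a = pn_pairs[1, keep],
                           node_b = pn_pairs[2, keep],
                           confidence = stats::runif(sum(keep), 0.70, 0.99),
                           stringsAsFactors = FALSE)

    # random background over all remaining pairs
    n_pairs_total <- choose(length(nodes), 2L)
    n_bg <- stats::rbinom(1L, n_pairs_total, background_density)
    ia <- sample(length(nodes), n_bg, replace = TRUE)
    ib <- sample(length(nodes), n_bg, replace = TRUE)
    ok <- ia != ib
    bg_edges <- data.frame(node_a = nodes[pmin(ia[ok], ib[ok])],
                           node_b = nodes[pmax(ia[ok], ib[ok])],
                           stringsAsFactors = FALSE)
    bg_edges <- bg_edges[!duplicated(bg_edges), , drop = FALSE]
    is_cp <- (bg_edges$node_a %in% candidates & bg_edges$node_b %in% plurinet) |
             (bg_edges$node_b %in% candidates & bg_edges$node_a %in% plurinet)
    bg_edges$confidence <- ifelse(is_cp,
                                  stats::runif(nrow(bg_edges), 0.15, 0.69),
                                  stats::runif(nrow(bg_edges), 0.15, 0.95))
  })

  edges <- rbind(planted, pn_edges, bg_edges)
  # canonical orientation, planted pairs win deduplication
  flip <- edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]; edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  edges <- edges[!duplicated(edges[, c("node_a", "node_b")]), , drop = FALSE]
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, plurinet = plurinet, candidates = candidates,
       planted_links = planted[, c("node_a", "node_b", "confidence")])
}
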