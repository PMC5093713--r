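#' Build the candidate-PluriNet subnetwork
#'
#' Retains interaction edges at or above the confidence threshold, keeps a
#' candidate iff it has at least one retained direct edge to a PluriNet
#' node, and induces the subnetwork on the kept candidates plus the PluriNet
#' nodes connected to them. Gene symbols are matched case-insensitively.
#' When no candidate survives, an empty network is returned with a warning
#' rather than an error.
#'
#' @param edges Data frame `node_a`, `node_b`, `confidence` (undirected).
#' @param candidates,plurinet Character vectors of gene symbols (non-empty).
#' @param threshold Confidence gate, inclusive (default 0.7).
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attribute `role` in `{"candidate", "plurinet"}` and edge attribute
#'   `confidence`.
#' @export
build_subnetwork <- function(edges, candidates, plurinet, threshold = 0.7) {
  if (!length(candidates) || !length(plurinet))
    stop("`candidates` and `plurinet` must be non-empty")
  candidates <- unique(toupper(candidates))
  plurinet <- unique(toupper(plurinet))
  e <- data.frame(node_a = toupper(edges$node_a),
                  node_b = toupper(edges$node_b),
                  confidence = edges$confidence, stringsAsFactors = FALSE)
  e <- e[e$confidence >= threshold & e$node_a != e$node_b, , drop = FALSE]

  cp <- (e$node_a %in% candidates & e$node_b %in% plurinet) |
        (e$node_b %in% candidates & e$node_a %in% plurinet)
  kept_cand <- intersect(candidates, unique(c(e$node_a[cp], e$node_b[cp])))
  kept_pn <- intersect(plurinet, unique(c(e$node_a[cp], e$node_b[cp])))
  if (!length(kept_cand)) {
    warning("no candidate has a direct PluriNet interaction at confidence >= ",
            threshold)
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nodes <- c(kept_cand, kept_pn)
  sub <- e[e$node_a %in% nodes & e$node_b %in% nodes, , drop = FALSE]
  sub <- sub[!duplicated(t(apply(sub[, 1:2], 1L, sort))), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub, directed = FALSE,
    vertices = data.frame(name = nodes,
                          role = ifelse(nodes %in% kept_cand,
                                        "candidate", "plurinet"),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Average local clustering coefficient
#'
#' Mean over all vertices of the local clustering coefficient (triangles
#' through the vertex divided by pairs of its neighbours); vertices of
#' degree below two contribute zero.
#'
#' @param net An igraph graph.
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  if (igraph::vcount(net) < 1L) stop("network has no nodes")
  igraph::transitivity(net, type = "localaverage", isolates = "zero")
}

#' Mean shortest path length
#'
#' Mean of shortest-path lengths over all unordered vertex pairs within the
#' largest connected component. Undefined (NA, with a warning) when every
#' component is a singleton.
#'
#' @param net An igraph graph with at least two vertices.
#' @return Mean geodesic length (>= 1), or `NA`.
#' @export
mean_shortest_path <- function(net) {
  if (igraph::vcount(net) < 2L) stop("network has fewer than two nodes")
  comp <- igraph::components(net)
  if (max(comp$csize) < 2L) {
    warning("all components are singletons: mean shortest path undefined")
    return(NA_real_)
  }
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(net, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE)
}

#' Degree-preserving randomization test of network topology
#'
#' Generates `n_random` null networks by degree-preserving double-edge
#' swaps (`10 * |E|` attempted swaps each, rejecting self-loops and
#' multi-edges), recomputes the clustering coefficient and mean shortest
#' path on each, and reports add-one empirical p-values:
#' `p = (b + 1) / (n_random + 1)` where `b` counts null networks at least
#' as extreme (clustering: `random >= observed`; mean shortest path:
#' `random <= observed`). The empirical p can therefore never be zero and is
#' bounded below by `1 / (n_random + 1)`. Every draw preserves the observed
#' degree sequence exactly.
#'
#' @param net An igraph graph with at least two edges.
#' @param n_random Number of null networks (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `network_metrics`: observed `clustering_coefficient`
#'   and `mean_shortest_path`, `empirical_p_clustering`, `empirical_p_path`,
#'   `n_random`, and the null distributions `null_clustering`, `null_path`.
#' @export
randomization_test <- function(net, n_random = 1000L, seed = NULL) {
  obs_cc <- clustering_coefficient(net)
  obs_mp <- mean_shortest_path(net)
  n_edges <- igraph::ecount(net)
  if (n_edges < 2L) {
    warning("fewer than two edges: no degree-preserving swap is possible; ",
            "empirical p reported as 1")
    return(structure(list(clustering_coefficient = obs_cc,
                          mean_shortest_path = obs_mp,
                          empirical_p_clustering = 1,
                          empirical_p_path = 1,
                          n_random = 0L, null_clustering = numeric(0),
                          null_path = numeric(0)),
                     class = "network_metrics"))
  }
  deg0 <- sort(igraph::degree(net))
  run <- function() {
    null_cc <- null_mp <- numeric(n_random)
    for (i in seq_len(n_random)) {
      r <- igraph::rewire(net, igraph::keeping_degseq(niter = 10L * n_edges))
      if (!identical(sort(igraph::degree(r)), deg0))
        stop("randomization failed to preserve the degree sequence")
      null_cc[i] <- clustering_coefficient(r)
      null_mp[i] <- mean_shortest_path(r)
    }
    list(cc = null_cc, mp = null_mp)
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  eps <- 1e-12
  p_cc <- (sum(null$cc >= obs_cc - eps) + 1) / (n_random + 1)
  p_mp <- (sum(null$mp <= obs_mp + eps, na.rm = TRUE) + 1) / (n_random + 1)
  structure(list(clustering_coefficient = obs_cc,
                 mean_shortest_path = obs_mp,
                 empirical_p_clustering = p_cc, empirical_p_path = p_mp,
                 n_random = as.integer(n_random),
                 null_clustering = null$cc, null_path = null$mp),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("clustering coefficient: %.4f (empirical p = %.4g)\n",
              x$clustering_coefficient, x$empirical_p_clustering))
  cat(sprintf("mean shortest path:     %.4f (empirical p = %.4g)\n",
              x$mean_shortest_path, x$empirical_p_path))
  cat(sprintf("null networks: %d (degree-preserving edge swaps)\n",
              x$n_random))
  invisible(x)
}

#' Fisher's exact test of candidate-PluriNet interaction enrichment
#'
#' Classifies every non-PluriNet gene of the universe by candidate
#' membership and by whether it has at least one interaction with a PluriNet
#' node at or above the confidence threshold, and tests the resulting 2x2
#' table for enrichment with the one-sided (hypergeometric upper-tail)
#' Fisher's exact test.
#'
#' @param edges Edge data frame `node_a`, `node_b`, `confidence`.
#' @param candidates,plurinet Gene symbol vectors.
#' @param universe Background gene universe; defaults to all nodes of the
#'   edge list. Candidates must be contained in it.
#' @param threshold Confidence gate (default 0.7).
#' @return List with `p_value`, `odds_ratio` and `table` (2x2 matrix).
#' @export
fisher_overlap <- function(edges, candidates, plurinet, universe = NULL,
                           threshold = 0.7) {
  candidates <- unique(toupper(candidates))
  plurinet <- unique(toupper(plurinet))
  ea <- toupper(edges$node_a); eb <- toupper(edges$node_b)
  if (is.null(universe))   # isolated query genes still belong to the universe
    universe <- unique(c(ea, eb, candidates, plurinet))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  if (!all(candidates %in% universe))
    stop("`candidates` must be contained in `universe`")
  keep <- edges$confidence >= threshold
  touches_pn <- unique(c(ea[keep & eb %in% plurinet],
                         eb[keep & ea %in% plurinet]))
  genes <- setdiff(universe, plurinet)
  is_cand <- genes %in% candidates
  interacts <- genes %in% touches_pn
  tab <- matrix(c(sum(is_cand & interacts), sum(is_cand & !interacts),
                  sum(!is_cand & interacts), sum(!is_cand & !interacts)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(candidate = c("yes", "no"),
                                interacts_plurinet = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' One-sided hypergeometric upper-tail enrichment of a query gene list in
#' each gene set, restricted to the background universe, with
#' Benjamini-Hochberg correction across sets. A set with zero overlap has
#' p = 1 under the upper-tail convention.
#'
#' @param genes Query gene symbols.
#' @param gmt Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene universe (must contain `genes`).
#' @return Data frame `set`, `set_size`, `overlap`, `p`, `p_adjusted`,
#'   sorted by corrected then raw p-value.
#' @export
enrich_pathways <- function(genes, gmt, universe) {
  if (!length(gmt))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  genes <- unique(toupper(genes))
  universe <- unique(toupper(universe))
  if (!all(genes %in% universe))
    stop("`genes` must be contained in `universe`")
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(gmt), function(nm) {
    set <- intersect(unique(toupper(gmt[[nm]])), universe)
    K <- length(set)
    k <- length(intersect(set, genes))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p_adjusted, out$p, out$set), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
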