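#' Node degrees of a bipartite network
#'
#' @param network a `dtn` network.
#' @return named integer vector over all nodes (drugs first, then genes).
#'   The drug-side degrees and the gene-side degrees each sum to the edge
#'   count.
#' @export
node_degree <- function(network) {
  stopifnot(inherits(network, "dtn"))
  nodes <- c(network$drugs, network$genes)
  counts <- table(factor(c(network$edges$drug_id, network$edges$gene_symbol),
                         levels = nodes))
  stats::setNames(as.integer(counts), nodes)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness of every node: for node v, the sum
#' over node pairs \{s, t\} (s != t != v) of the fraction of shortest s-t
#' paths passing through v. Disconnected pairs contribute zero. By default
#' each unordered pair is counted once ("unordered", the convention under
#' which the bridge threshold of 2000 is interpreted); "ordered" counts each
#' pair in both directions, doubling every value, for parity with tools that
#' sum over ordered pairs.
#'
#' @param network a `dtn` network.
#' @param pair_convention "unordered" (default) or "ordered".
#' @return named numeric vector; attribute `pair_convention` records the
#'   convention used.
#' @export
node_betweenness <- function(network, pair_convention = c("unordered", "ordered")) {
  pair_convention <- match.arg(pair_convention)
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (pair_convention == "ordered") b <- 2 * b
  b <- b[c(network$drugs, network$genes)]
  attr(b, "pair_convention") <- pair_convention
  b
}

#' Detect a distribution cutoff (knee of the rank curve)
#'
#' Reproduces the visual "point where the distribution begins to reach its
#' asymptote" procedure algorithmically: values are ranked in descending
#' order and the knee is the rank at maximum perpendicular distance from the
#' chord joining the curve's endpoints (Kneedle-style). Ties are broken
#' toward the smallest rank; an (almost) linear curve has no meaningful knee
#' and is flagged low-confidence. A manual threshold bypasses detection and
#' is the documented way to reproduce externally chosen cutoffs such as a
#' degree cutoff of 9 or a betweenness cutoff of 2000.
#'
#' @param values numeric multiset (e.g. all node degrees).
#' @param method "knee" or "manual".
#' @param manual_threshold threshold echoed when `method = "manual"`.
#' @param metric label stored in the decision ("degree", "betweenness", ...).
#' @return list of class `cutoff_decision` with `metric`, `threshold`,
#'   `method`, `curve` (rank/value data frame) and `low_confidence`.
#' @export
detect_cutoff <- function(values, method = c("knee", "manual"),
                          manual_threshold = NULL, metric = "degree") {
  method <- match.arg(method)
  curve <- data.frame(rank = seq_along(values),
                      value = sort(as.numeric(values), decreasing = TRUE))
  if (method == "manual") {
    if (is.null(manual_threshold))
      stop("manual method requires manual_threshold")
    dec <- list(metric = metric, threshold = as.numeric(manual_threshold),
                method = "manual", curve = curve, low_confidence = FALSE)
    class(dec) <- "cutoff_decision"
    return(dec)
  }
  if (length(unique(curve$value)) < 3L)
    stop("knee detection needs >= 3 distinct values; use method = \"manual\"")
  n <- nrow(curve)
  x1 <- curve$rank[1]; y1 <- curve$value[1]
  x2 <- curve$rank[n]; y2 <- curve$value[n]
  # perpendicular distance to the chord; |cross product| / chord length
  d <- abs((x2 - x1) * (y1 - curve$value) - (x1 - curve$rank) * (y2 - y1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  knee <- which.max(d)  # which.max takes the first maximum: smallest rank
  low_conf <- max(d) <= 1e-9 * max(1, abs(y1 - y2))
  dec <- list(metric = metric, threshold = curve$value[knee],
              method = "knee", curve = curve, low_confidence = low_conf)
  class(dec) <- "cutoff_decision"
  dec
}

#' @export
print.cutoff_decision <- function(x, ...) {
  cat("<cutoff_decision>", x$metric, "threshold", x$threshold,
      "(", x$method, if (x$low_confidence) ", low confidence" else "", ")\n")
  invisible(x)
}

cutoff_value <- function(cutoff) {
  if (inherits(cutoff, "cutoff_decision")) cutoff$threshold
  else as.numeric(cutoff)
}

#' Flag hub nodes
#'
#' Nodes whose degree strictly exceeds the threshold ("degree greater than
#' eight" under the cutoff value 9 means degree > 8; the strictness is on
#' the detected point itself).
#'
#' @param network a `dtn` network.
#' @param cutoff a `cutoff_decision` or bare numeric threshold. Flags apply
#'   strictly above the threshold.
#' @return character vector of node ids.
#' @export
flag_hubs <- function(network, cutoff) {
  d <- node_degree(network)
  names(d)[d > cutoff_value(cutoff)]
}

#' Flag bridge nodes
#'
#' Nodes whose betweenness strictly exceeds the threshold.
#'
#' @inheritParams flag_hubs
#' @param betweenness optional precomputed vector from [node_betweenness()].
#' @return character vector of node ids.
#' @export
flag_bridges <- function(network, cutoff, betweenness = NULL) {
  b <- if (is.null(betweenness)) node_betweenness(network) else betweenness
  names(b)[b > cutoff_value(cutoff)]
}

#' Per-node centrality table with hub/bridge flags
#'
#' @param network a `dtn` network.
#' @param degree_cutoff,betweenness_cutoff thresholds (decision objects or
#'   numbers) for the strict hub/bridge rules.
#' @param pair_convention passed to [node_betweenness()].
#' @return data frame: node_id, node_kind, set_label, degree, betweenness,
#'   is_hub, is_bridge.
#' @export
centrality_table <- function(network, degree_cutoff, betweenness_cutoff,
                             pair_convention = "unordered") {
  d <- node_degree(network)
  b <- node_betweenness(network, pair_convention)
  nodes <- names(d)
  data.frame(
    node_id = nodes,
    node_kind = ifelse(nodes %in% network$drugs, "drug", "gene"),
    set_label = c(unname(network$drug_labels[network$drugs]),
                  unname(network$gene_labels[network$genes])),
    degree = as.integer(d),
    betweenness = as.numeric(b),
    is_hub = d > cutoff_value(degree_cutoff),
    is_bridge = b > cutoff_value(betweenness_cutoff),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Compare two degree distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison. When both samples
#' have at most `exact_max` observations the null distribution of the
#' rank-sum statistic is enumerated exhaustively over all assignments of the
#' pooled values (ties included); larger samples use the normal
#' approximation with tie and continuity corrections.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param exact_max exact-enumeration size limit per sample.
#' @return list with `statistic` (Mann-Whitney U of sample_a), `p_value`,
#'   and `method` ("exact" or "normal").
#' @export
compare_degree_distributions <- function(sample_a, sample_b, exact_max = 10) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])            # rank sum of sample_a
  u_obs <- w_obs - n1 * (n1 + 1) / 2      # Mann-Whitney U
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    mu <- n1 * (n1 + n2 + 1) / 2
    lo <- mean(w_all <= w_obs + 1e-9)
    hi <- mean(w_all >= w_obs - 1e-9)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    p <- stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                            correct = TRUE)$p.value
    method <- "normal"
  }
  list(statistic = u_obs, p_value = p, method = method)
}
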