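# Builders for in-code fixtures and independent oracles used across tests.

tgt <- function(accs, species = "Humans") {
  data.frame(uniprot_acc = accs, species = rep_len(species, length(accs)),
             stringsAsFactors = FALSE)
}

drec <- function(id, name = id, groups = "approved", atc = character(),
                 targets = tgt(character())) {
  structure(list(drug_id = id, name = name, groups = tolower(groups),
                 categories = character(), atc_codes = atc, targets = targets),
            class = "drug_record")
}

mapping_of <- function(accs, syms) {
  structure(data.frame(uniprot_acc = accs, gene_symbol = syms,
                       entrez_id = seq_along(accs), stringsAsFactors = FALSE),
            class = c("gene_mapping", "data.frame"))
}

# random bipartite network; declared isolated nodes are allowed
rand_bipartite <- function(n_drugs, n_genes, p, seed) {
  set.seed(seed)
  drugs <- paste0("d", seq_len(n_drugs))
  genes <- paste0("g", seq_len(n_genes))
  grid <- expand.grid(drug_id = drugs, gene_symbol = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  if (!nrow(e)) e <- grid[1, , drop = FALSE]
  dtn_network(drugs, genes, e)
}

# Exhaustive geodesic-enumeration betweenness oracle. Counts minimal-length
# walks via adjacency-matrix powers (a minimal-length walk is a path), then
# sums pair-dependency fractions directly. Independent of igraph.
brute_betweenness <- function(net) {
  nodes <- c(net$drugs, net$genes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$drug_id[i], net$edges$gene_symbol[i]] <- 1
    A[net$edges$gene_symbol[i], net$edges$drug_id[i]] <- 1
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(n)
  P <- diag(n)
  for (L in seq_len(n)) {
    P <- P %*% A
    newly <- (P > 0) & !is.finite(D)
    D[newly] <- L
    S[newly] <- P[newly]
  }
  b <- stats::setNames(numeric(n), nodes)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t])
          b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  b
}

# support-enumeration oracles (base-R density, independent of the log-space
# implementation under test)
fisher_oracle <- function(a, b, c, d) {
  mA <- a + c; mB <- b + d; k <- a + b
  supp <- max(0, k - mB):min(k, mA)
  pr <- stats::dhyper(supp, mA, mB, k)
  p0 <- stats::dhyper(a, mA, mB, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

hyper_oracle <- function(N, K, n, k) {
  sum(stats::dhyper(k:min(n, K), K, N - K, n))
}

# point-to-line distance knee scan, written against the explicit line
# equation rather than the cross-product form used by the implementation
knee_oracle_rank <- function(values) {
  v <- sort(values, decreasing = TRUE)
  r <- seq_along(v)
  x1 <- r[1]; y1 <- v[1]; x2 <- r[length(r)]; y2 <- v[length(v)]
  # line through the endpoints: a x + b y + c = 0
  a <- y2 - y1; b <- x1 - x2; c <- -(a * x1 + b * y1)
  d <- abs(a * r + b * v + c) / sqrt(a^2 + b^2)
  which.max(d)
}

# a 20-drug fixture with known partition sizes: 4 illicit, 6 related
# (sharing gene G1 or G2 with the illicit drugs), 10 other (own genes)
partition_fixture <- function() {
  accs <- paste0("P", 1:14)
  syms <- c("G1", "G2", paste0("H", 1:12))
  recs <- c(
    lapply(1:4, function(i)
      drec(sprintf("DBI%02d", i), groups = c("approved", "illicit"),
           targets = tgt(accs[1 + (i %% 2)]))),
    lapply(1:6, function(i)
      drec(sprintf("DBR%02d", i), targets = tgt(accs[1 + (i %% 2)]))),
    lapply(1:10, function(i)
      drec(sprintf("DBO%02d", i), targets = tgt(accs[2 + i]))))
  list(records = recs, mapping = mapping_of(accs, syms))
}
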