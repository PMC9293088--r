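# Toy networks and genotype tables built in code, plus slow independent
# oracles used to cross-check the package implementations.

# 3-node path A -> B -> C (C is the outlet), lengths 2 and 3 km
path3 <- function() {
  river_network(
    nodes = data.frame(node_id = c("A", "B", "C"),
                       local_area_km2 = c(1, 1, 1)),
    edges = data.frame(from_node = c("A", "B"), to_node = c("B", "C"),
                       length_km = c(2, 3)))
}

# 7-node balanced binary tree, unit lengths, outlet n1
bintree7 <- function() {
  river_network(
    nodes = data.frame(node_id = paste0("n", 1:7),
                       local_area_km2 = c(3, 2, 2, 1, 1, 1, 1)),
    edges = data.frame(from_node = paste0("n", c(2, 3, 4, 5, 6, 7)),
                       to_node = paste0("n", c(1, 1, 2, 2, 3, 3)),
                       length_km = 1))
}

# brute-force all-pairs shortest-path matrix by Floyd-Warshall, written
# directly from the edge table (independent of the package's graph backend)
fw_distances <- function(net, directed = FALSE) {
  ids <- net$nodes$node_id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from_node[i]; t <- net$edges$to_node[i]
    w <- net$edges$length_km[i]
    D[f, t] <- min(D[f, t], w)
    if (!directed) D[t, f] <- min(D[t, f], w)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# betweenness by exhaustive path enumeration on the distance matrix: node v
# lies on the (unique, tree) shortest path i -> j iff d(i,v) + d(v,j) = d(i,j)
fw_betweenness <- function(net, directed = FALSE) {
  D <- fw_distances(net, directed)
  ids <- rownames(D)
  b <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j || !is.finite(D[i, j])) next
    if (!directed && i > j) next             # unordered pairs once
    for (v in seq_along(ids)) {
      if (v == i || v == j) next
      if (abs(D[i, v] + D[v, j] - D[i, j]) < 1e-9) b[v] <- b[v] + 1
    }
  }
  b
}

# tiny genotype table: 4 individuals, 2 loci, one node; locus 1 has gene
# copies {120,120,120,122} among the observed calls
toy_genotypes <- function() {
  genotype_table(data.frame(
    individual_id = paste0("ind", 1:4),
    node_id = "n1",
    species = "A",
    loc1_a1 = c(120L, 120L, NA, NA),
    loc1_a2 = c(120L, 122L, NA, NA),
    loc2_a1 = c(120L, 120L, 120L, 124L),
    loc2_a2 = c(124L, 124L, 124L, 124L)))
}

# exhaustive-subset rarefied richness: mean number of distinct alleles over
# all choose(N, g) subsets of the gene copies
enum_ar <- function(copies, g) {
  subsets <- utils::combn(length(copies), g)
  mean(apply(subsets, 2, function(ix) length(unique(copies[ix]))))
}

# Heap's algorithm permutation enumerator (independent of the package's
# recursive insertion enumerator)
heap_perms <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      rec(k - 1)
      if (k %% 2 == 0) { tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp }
      else { tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp }
    }
  }
  rec(n)
  out
}

# degenerate single-node network (isolated deme; the node is the outlet)
single_node_net <- function() river_network(
  nodes = data.frame(node_id = "A", local_area_km2 = 1),
  edges = data.frame(from_node = character(0), to_node = character(0),
                     length_km = numeric(0)))

# simulator param shorthand for fast desk-scale runs
quick_params <- function(...) {
  sim_params(K_base = 50, generations = 200, replicates = 2, seed = 11, ...)
}
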