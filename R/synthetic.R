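#' Generate a random dendritic river network
#'
#' Builds a random recursive in-tree: starting from the outlet, nodes are
#' added one at a time, each attaching upstream of an existing node chosen
#' either among the current headwaters (with probability `leaf_bias`,
#' elongating the network) or uniformly among all nodes (creating
#' confluences). Edge lengths are lognormal and local subcatchment areas are
#' gamma distributed; the defaults emulate a fine subcatchment partition
#' with a mean local area of 2 km^2 and stream segments of a few km.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param seed RNG seed (set when not `NULL`).
#' @param edge_length_meanlog,edge_length_sdlog lognormal parameters of edge
#'   lengths (km).
#' @param area_shape,area_scale gamma parameters of local areas (km^2);
#'   defaults give mean `shape * scale = 2` km^2.
#' @param leaf_bias probability that a new node attaches to a current
#'   headwater rather than to a uniformly chosen node.
#' @return a validated [river_network()] with node ids `n1..nN` (`n1` is the
#'   outlet).
#' @export
random_dendritic_network <- function(n_nodes, seed = NULL,
                                     edge_length_meanlog = log(1.5),
                                     edge_length_sdlog = 0.5,
                                     area_shape = 4, area_scale = 0.5,
                                     leaf_bias = 0.5) {
  stopifnot(n_nodes >= 2)
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("n", seq_len(n_nodes))
  from <- to <- character(n_nodes - 1)
  has_upstream <- logical(n_nodes)
  for (i in 2:n_nodes) {
    existing <- seq_len(i - 1)
    leaves <- existing[!has_upstream[existing]]
    target <- if (stats::runif(1) < leaf_bias && length(leaves))
      leaves[sample.int(length(leaves), 1)]
    else existing[sample.int(length(existing), 1)]
    from[i - 1] <- ids[i]
    to[i - 1] <- ids[target]
    has_upstream[target] <- TRUE
  }
  nodes <- data.frame(
    node_id = ids,
    local_area_km2 = stats::rgamma(n_nodes, shape = area_shape,
                                   scale = area_scale),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from_node = from, to_node = to,
    length_km = stats::rlnorm(n_nodes - 1, edge_length_meanlog,
                              edge_length_sdlog),
    stringsAsFactors = FALSE)
  river_network(nodes, edges)
}

#' Generate island-model genotypes with a target F_ST
#'
#' Draws structured microsatellite genotypes under the Balding-Nichols
#' model: per locus, ancestral allele frequencies are Dirichlet-uniform over
#' the allele set; each population's frequencies are then drawn from a
#' Dirichlet with mean at the ancestral frequencies and concentration
#' `(1 - F) / F`. The Balding-Nichols parameter is calibrated as
#' `F = 2 t / (1 + t)` with `t = target_fst`, because the expected
#' *pairwise* Nei differentiation between two populations drawn with
#' parameter `F` is `(F/2) / (1 - F/2)` (the total diversity of a pair uses
#' only the two populations); with this calibration the mean pairwise Nei
#' F_ST estimated from the generated genotypes recovers `target_fst`.
#' Individuals are sampled in Hardy-Weinberg proportions (two independent
#' gene copies per locus). With `target_fst = 0` all populations share the
#' ancestral frequencies exactly.
#'
#' @param n_pops number of populations (placed at nodes `p1..pN`).
#' @param n_per_pop individuals per population: a scalar, or a length-2
#'   range from which each population's size is drawn uniformly. The
#'   default 15-40 mirrors typical per-site microsatellite sample sizes
#'   above the inclusion filter of 15.
#' @param n_loci number of loci (default 9, a typical microsatellite panel).
#' @param n_alleles allele states per locus (sizes `101..100+n_alleles`).
#' @param target_fst expected differentiation among populations, in `[0, 1)`.
#' @param species species label for all individuals.
#' @param seed RNG seed (set when not `NULL`).
#' @return a [genotype_table()].
#' @export
island_model_genotypes <- function(n_pops = 10, n_per_pop = c(15, 40),
                                   n_loci = 9, n_alleles = 10,
                                   target_fst = 0.2, species = "sim",
                                   seed = NULL) {
  stopifnot(n_pops >= 2, n_loci >= 1, n_alleles >= 2,
            target_fst >= 0, target_fst < 1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (length(n_per_pop) == 2)
    sample(seq(n_per_pop[1], n_per_pop[2]), n_pops, replace = TRUE)
  else rep(n_per_pop, n_pops)
  states <- 100 + seq_len(n_alleles)
  rdirichlet <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    x / sum(x)
  }
  # pairwise-Fst calibration of the Balding-Nichols parameter (see Details)
  F_bn <- 2 * target_fst / (1 + target_fst)
  n_tot <- sum(sizes)
  df <- data.frame(
    individual_id = sprintf("i%05d", seq_len(n_tot)),
    node_id = rep(paste0("p", seq_len(n_pops)), times = sizes),
    species = species,
    stringsAsFactors = FALSE)
  for (l in seq_len(n_loci)) {
    anc <- rdirichlet(rep(1, n_alleles))
    a1 <- a2 <- integer(0)
    for (p in seq_len(n_pops)) {
      freq <- if (target_fst == 0) anc
      else rdirichlet(anc * (1 - F_bn) / F_bn)
      a1 <- c(a1, sample(states, sizes[p], replace = TRUE, prob = freq))
      a2 <- c(a2, sample(states, sizes[p], replace = TRUE, prob = freq))
    }
    df[[sprintf("loc%d_a1", l)]] <- a1
    df[[sprintf("loc%d_a2", l)]] <- a2
  }
  genotype_table(df)
}

#' Write the worked toy fixture files
#'
#' Writes deterministic, byte-stable toy inputs used in examples and tests:
#' a 7-node balanced binary-tree network (`nodes.tsv`, `edges.tsv`; unit
#' edge lengths, outlet `n1`), a 4-individual two-locus genotype table
#' (`genotypes.tsv`) whose first locus carries allele copies `{1,1,1,2}`
#' (rarefied richness at g = 2 is exactly 1.5), and a sidecar
#' `expected_stats.tsv` with hand-computed statistics.
#'
#' @param out_dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_worked_fixture <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(
    node_id = paste0("n", 1:7),
    local_area_km2 = c(3, 2, 2, 1, 1, 1, 1))
  edges <- data.frame(
    from_node = paste0("n", c(2, 3, 4, 5, 6, 7)),
    to_node = paste0("n", c(1, 1, 2, 2, 3, 3)),
    length_km = 1)
  geno <- data.frame(
    individual_id = paste0("ind", 1:4),
    node_id = "n1",
    species = "A",
    loc1_a1 = c(120L, 120L, NA, NA),
    loc1_a2 = c(120L, 122L, NA, NA),
    loc2_a1 = c(120L, 120L, 120L, 124L),
    loc2_a2 = c(124L, 124L, 124L, 124L))
  expected <- data.frame(
    quantity = c("AR_loc1_g2", "Ho_loc2", "n_individuals", "outlet",
                 "leaf_upstream_distance", "outlet_catchment_area"),
    value = c(1.5, 0.75, 4, 1, 2, 11))
  paths <- file.path(out_dir, c("nodes.tsv", "edges.tsv", "genotypes.tsv",
                                "expected_stats.tsv"))
  utils::write.table(nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geno, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expected, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
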