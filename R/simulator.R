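#' Simulation parameters
#'
#' Parameter set for the individual-based metapopulation genetic simulator.
#' Defaults reproduce the fixed study conditions: ten neutral diploid loci
#' with 100 possible allele states, mutation rate 1e-4 per allele copy per
#' generation, Beverton-Holt fecundity `lambda0 = 2`, no dispersal mortality,
#' mean carrying capacity 1000 individuals per node, 10,000 generations and
#' ten replicates. The explored axes are the dispersal rate
#' `d` (0.001, 0.01, 0.1), the upstream movement probability `W` (0, 0.5, 1),
#' the carrying-capacity mode (`"fixed"` or `"scaled"` with the square root
#' of accumulated catchment area) and the mutation model (`"stepwise"` or
#' `"random"`).
#'
#' @param d per-offspring emigration probability, in `[0, 1]`.
#' @param W weight of each upstream neighbour relative to the downstream
#'   neighbour when choosing a dispersal target (0 = pure downstream drift,
#'   1 = symmetric).
#' @param k_mode `"fixed"` (all nodes at `K_base`) or `"scaled"` (see
#'   [scaled_capacities()]).
#' @param K_base mean carrying capacity per node (individuals).
#' @param mu mutation rate per allele copy per generation.
#' @param lambda0 fecundity (per-capita growth at low density is `lambda0`).
#' @param m dispersal mortality (applies to emigrants).
#' @param n_loci number of neutral diploid loci.
#' @param n_allele_states number of possible allele states (labelled
#'   `1..n_allele_states`, reflecting boundaries for stepwise mutation).
#' @param mut_model `"stepwise"` (+/- 1 with reflection) or `"random"`
#'   (uniform over all states, resampling the current state allowed).
#' @param generations number of non-overlapping generations.
#' @param replicates independent replicate runs.
#' @param seed master seed; replicate streams are derived from it.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(d = 0.01, W = 0.5, k_mode = c("fixed", "scaled"),
                       K_base = 1000, mu = 1e-4, lambda0 = 2, m = 0,
                       n_loci = 10, n_allele_states = 100,
                       mut_model = c("stepwise", "random"),
                       generations = 10000, replicates = 10, seed = 1) {
  k_mode <- match.arg(k_mode)
  mut_model <- match.arg(mut_model)
  stopifnot(d >= 0, d <= 1, W >= 0, W <= 1, mu >= 0, mu <= 1,
            lambda0 > 1, m >= 0, m <= 1, K_base >= 1, n_loci >= 1,
            n_allele_states >= 2, generations >= 1, replicates >= 1)
  structure(list(d = d, W = W, k_mode = k_mode, K_base = K_base, mu = mu,
                 lambda0 = lambda0, m = m, n_loci = n_loci,
                 n_allele_states = n_allele_states, mut_model = mut_model,
                 generations = generations, replicates = replicates,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Carrying capacities scaled with the square root of catchment area
#'
#' `K_i = round(c * sqrt(A_i))` with `A_i` the accumulated catchment area and
#' `c` chosen so the metapopulation total stays at
#' `n_nodes * K_base` (up to rounding). Capacities are floored at
#' `floor_k` individuals so every node can host a breeding pair; the most
#' downstream node receives the maximum capacity by construction (it has the
#' largest accumulated area).
#' @param net a [river_network()].
#' @param K_base mean capacity per node.
#' @param floor_k minimum capacity per node.
#' @return named integer vector of capacities over nodes.
#' @export
scaled_capacities <- function(net, K_base = 1000, floor_k = 2) {
  A <- catchment_accumulation(net)
  if (sum(A) <= 0) stop("total catchment area is zero; cannot scale")
  w <- sqrt(A)
  K <- round(length(A) * K_base * w / sum(w))
  K[K < floor_k] <- floor_k
  stats::setNames(as.integer(K), names(A))
}

# internal: adjacency in the 1-based index space of net$nodes
.net_index <- function(net) {
  ids <- net$nodes$node_id
  idx <- stats::setNames(seq_along(ids), ids)
  down <- ifelse(is.na(net$down[ids]), 0L, idx[net$down[ids]])
  down[is.na(down)] <- 0L
  up <- lapply(net$up[ids], function(u) as.integer(idx[u]))
  list(ids = ids, down = as.integer(down), up = up)
}

.check_state <- function(state) {
  stopifnot(is.list(state), is.matrix(state$geno),
            length(state$node) == nrow(state$geno),
            length(state$sex) == nrow(state$geno))
  state
}

#' One reproduction step
#'
#' Non-overlapping generations: every female with at least one male in her
#' node mates with a uniform-random local male and produces a Poisson number
#' of offspring with mean `2 * lambda0 / (1 + (lambda0 - 1) * N_i / K_i)`
#' (Beverton-Holt density regulation; `N_i` is the local census before
#' reproduction, both sexes). Offspring inherit one uniformly chosen allele
#' copy per locus from each parent and a sex with probability 0.5. All
#' adults die.
#'
#' @param state list with `geno` (individuals x 2*n_loci integer matrix),
#'   `node` (1-based node index), `sex` (1 = female, 0 = male).
#' @param K integer vector of node carrying capacities.
#' @param params a [sim_params()].
#' @return the offspring state (same structure).
#' @export
reproduction_step <- function(state, K, params) {
  .check_state(state)
  .cpp_reproduction(state$geno, as.integer(state$node),
                    as.integer(state$sex), as.integer(K), params$lambda0)
}

#' One mutation step
#'
#' Each allele copy mutates independently with probability `mu`. Under the
#' stepwise model the state changes by +/- 1 with equal probability,
#' reflecting at the boundaries (from state 1 always to 2, from the highest
#' state always one down); under the random model the new state is uniform
#' over all states, so the probability of actually changing value is
#' `mu * (1 - 1/n_states)`.
#' @inheritParams reproduction_step
#' @return the mutated state.
#' @export
mutation_step <- function(state, params) {
  .check_state(state)
  state$geno <- .cpp_mutation(state$geno, params$mu,
                              if (params$mut_model == "stepwise") 1L else 2L,
                              as.integer(params$n_allele_states))
  state
}

#' One natal dispersal step
#'
#' Each individual emigrates with probability `d`; the target is drawn among
#' adjacent nodes with weight 1 for the downstream neighbour and weight `W`
#' for each upstream neighbour. If all weights are zero (the outlet with
#' `W = 0`) the individual stays. Dispersal mortality `m` removes emigrants
#' with probability `m`.
#' @inheritParams reproduction_step
#' @param net a [river_network()]; its node order defines the index space.
#' @return the dispersed state (dead emigrants removed).
#' @export
dispersal_step <- function(state, net, params) {
  .check_state(state)
  adj <- .net_index(net)
  res <- .cpp_dispersal(as.integer(state$node), params$d, params$W,
                        params$m, adj$down, adj$up)
  keep <- res$alive
  list(geno = state$geno[keep, , drop = FALSE],
       node = as.integer(res$node[keep]),
       sex = as.integer(state$sex[keep]))
}

# replicate seed derivation: documented splitting rule, kept below 2^31
.replicate_seed <- function(master, replicate) {
  as.integer((as.numeric(master) * 1000 + 7919 * replicate) %% 2147483647)
}

#' Run the metapopulation simulator
#'
#' Initializes every node at its carrying capacity with uniform-random allele
#' states and sexes, then iterates reproduction, mutation and natal dispersal
#' for `params$generations` generations, once per replicate with
#' replicate-specific seeds derived from the master seed. Population genetic
#' output is the final generation of each replicate, exported in the
#' [genotype_table()] schema (`node_id` = network node, `species` = scenario
#' label), plus a per-generation trajectory of total population size and
#' mean pooled expected heterozygosity.
#'
#' @param net a [river_network()].
#' @param params a [sim_params()].
#' @param label scenario label stored in the `species` column; defaults to a
#'   compact encoding of the varying parameters.
#' @param traj_every record the trajectory every this many generations.
#' @return list of class `sim_result` with elements `params`, `K`, and
#'   `replicates`: each replicate a list with `genotypes`
#'   (a [genotype_table()]), `trajectory` (data frame) and `extinct` flag.
#' @export
run_simulation <- function(net, params, label = NULL, traj_every = 10) {
  stopifnot(inherits(net, "river_network"), inherits(params, "sim_params"))
  adj <- .net_index(net)
  K <- if (params$k_mode == "scaled")
    scaled_capacities(net, params$K_base)[adj$ids]
  else stats::setNames(rep(as.integer(params$K_base), length(adj$ids)),
                       adj$ids)
  if (is.null(label))
    label <- sprintf("d%g_W%g_K%s_%s", params$d, params$W, params$k_mode,
                     params$mut_model)
  reps <- vector("list", params$replicates)
  for (r in seq_len(params$replicates)) {
    set.seed(.replicate_seed(params$seed, r))
    res <- .cpp_run(as.integer(K), adj$down, adj$up,
                    params$d, params$W, params$mu, params$lambda0, params$m,
                    as.integer(params$n_loci),
                    as.integer(params$n_allele_states),
                    if (params$mut_model == "stepwise") 1L else 2L,
                    as.integer(params$generations), as.integer(traj_every))
    reps[[r]] <- list(
      genotypes = .state_to_genotypes(res, adj$ids, label, r,
                                      params$n_loci),
      trajectory = res$trajectory,
      extinct = res$extinct,
      last_generation = res$last_generation)
    if (res$extinct)
      warning("replicate ", r, " went extinct at generation ",
              res$last_generation)
  }
  structure(list(params = params, K = K, label = label, replicates = reps),
            class = "sim_result")
}

.state_to_genotypes <- function(res, ids, label, replicate, n_loci) {
  n <- nrow(res$geno)
  df <- data.frame(
    individual_id = sprintf("r%d_i%06d", replicate, seq_len(max(n, 0))),
    node_id = ids[res$node],
    species = label,
    stringsAsFactors = FALSE)
  for (l in seq_len(n_loci)) {
    df[[sprintf("L%02d_a1", l)]] <- res$geno[, 2 * l - 1]
    df[[sprintf("L%02d_a2", l)]] <- res$geno[, 2 * l]
  }
  genotype_table(df)
}

#' @export
print.sim_result <- function(x, ...) {
  n <- vapply(x$replicates, function(r) nrow(r$genotypes), numeric(1))
  cat("sim_result:", x$label, "-", length(x$replicates), "replicates,",
      "final N:", paste(n, collapse = "/"), "\n")
  invisible(x)
}

#' Per-node diversity statistics of a simulation result
#'
#' Computes [node_diversity()] for the final generation of every replicate
#' and returns one long table tagged with the scenario parameters, ready for
#' [scenario_fit()]. Nodes with fewer than `min_n` individuals in a
#' replicate are dropped (small scaled-capacity nodes can drift to very low
#' numbers); pass an explicit `g` to make rarefied allelic richness
#' comparable across replicates and scenarios.
#'
#' @param sim a `sim_result` from [run_simulation()].
#' @param min_n minimum individuals per node per replicate.
#' @param g rarefaction size in gene copies (see [allelic_richness()]).
#' @return data frame with columns `d`, `W`, `k_mode`, `mut_model`,
#'   `replicate`, `node_id`, `n`, `g`, `AR`, `Ho`, `He`.
#' @export
sim_diversity <- function(sim, min_n = 2, g = NULL) {
  stopifnot(inherits(sim, "sim_result"))
  do.call(rbind, lapply(seq_along(sim$replicates), function(r) {
    gt <- filter_nodes(sim$replicates[[r]]$genotypes, min_n = min_n)
    div <- node_diversity(gt, g = g)
    cbind(data.frame(d = sim$params$d, W = sim$params$W,
                     k_mode = sim$params$k_mode,
                     mut_model = sim$params$mut_model,
                     replicate = r, stringsAsFactors = FALSE),
          div[c("node_id", "n", "g", "AR", "Ho", "He")])
  }))
}

#' Initial simulator state (for stepwise use of the step functions)
#'
#' Every node is seeded at its carrying capacity with uniform-random allele
#' states and sexes.
#' @param net a [river_network()].
#' @param K integer vector of capacities (node order of `net`).
#' @param params a [sim_params()].
#' @return a state list (`geno`, `node`, `sex`).
#' @export
init_state <- function(net, K, params) {
  n <- sum(K)
  geno <- matrix(sample.int(params$n_allele_states, n * 2 * params$n_loci,
                            replace = TRUE),
                 nrow = n, ncol = 2 * params$n_loci)
  list(geno = geno,
       node = rep(seq_along(K), times = K),
       sex = stats::rbinom(n, 1, 0.5))
}
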