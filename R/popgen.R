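#' Construct and validate a genotype table
#'
#' A genotype table holds diploid microsatellite calls: one row per
#' individual with columns `individual_id`, `node_id`, `species`, followed by
#' two integer allele columns per locus named `<locus>_a1` and `<locus>_a2`.
#' Allele states are positive integers (e.g. fragment sizes); a locus call is
#' either fully observed (both copies) or fully missing (`NA` in both).
#'
#' @param df data frame in the schema above.
#' @return the validated data frame with class `genotype_table` and attribute
#'   `loci` (locus name vector).
#' @export
genotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("individual_id", "node_id", "species")
  if (!all(req %in% names(df)))
    stop("genotype table must have columns: ", paste(req, collapse = ", "))
  df$individual_id <- as.character(df$individual_id)
  df$node_id <- as.character(df$node_id)
  df$species <- as.character(df$species)
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual id: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]),
               collapse = ", "))
  a1 <- grep("_a1$", names(df), value = TRUE)
  loci <- sub("_a1$", "", a1)
  missing_pair <- loci[!paste0(loci, "_a2") %in% names(df)]
  if (length(missing_pair))
    stop("locus without second allele column: ",
         paste(missing_pair, collapse = ", "))
  if (length(loci) == 0L) stop("no locus columns (<locus>_a1/_a2) found")
  for (l in loci) {
    c1 <- df[[paste0(l, "_a1")]]
    c2 <- df[[paste0(l, "_a2")]]
    if (!is.numeric(c1) || !is.numeric(c2))
      stop("non-numeric allele column for locus ", l)
    half <- xor(is.na(c1), is.na(c2))
    if (any(half))
      stop("half-missing call at locus ", l, " for individual ",
           paste(df$individual_id[half], collapse = ", "))
    ok <- is.na(c1) | (c1 > 0 & c2 > 0 & c1 == floor(c1) & c2 == floor(c2))
    if (!all(ok))
      stop("allele states must be positive integers at locus ", l,
           " (individual ", paste(df$individual_id[!ok], collapse = ", "), ")")
  }
  structure(df, class = c("genotype_table", "data.frame"), loci = loci)
}

#' Locus names of a genotype table
#' @param gt a [genotype_table()].
#' @return character vector of locus names.
#' @export
locus_names <- function(gt) attr(gt, "loci")

#' Read a genotype table from TSV
#'
#' @param path TSV with columns `individual_id`, `node_id`, `species` and
#'   integer allele columns `<locus>_a1`, `<locus>_a2`; missing encoded as
#'   empty or `NA`.
#' @return a validated [genotype_table()]; per-node sample sizes are attached
#'   as attribute `node_counts`.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  gt <- genotype_table(df)
  attr(gt, "node_counts") <- as.data.frame(
    table(node_id = gt$node_id, species = gt$species),
    responseName = "n", stringsAsFactors = FALSE)
  gt
}

#' Write a genotype table to TSV
#' @param gt a [genotype_table()].
#' @param path output path.
#' @export
write_genotypes <- function(gt, path) {
  utils::write.table(as.data.frame(gt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gt)
}

#' Drop node groups with too few genotyped individuals
#'
#' Retains only (node, species) groups with at least `min_n` individuals,
#' mirroring the inclusion filter applied to empirical microsatellite data.
#' @param gt a [genotype_table()].
#' @param min_n minimum number of individuals per (node, species) group.
#' @return filtered [genotype_table()]; warns if nothing survives.
#' @export
filter_nodes <- function(gt, min_n = 15) {
  key <- paste(gt$node_id, gt$species, sep = "\r")
  n <- table(key)
  keep <- key %in% names(n)[n >= min_n]
  if (!any(keep)) warning("no (node, species) group has >= ", min_n,
                          " individuals; result is empty")
  genotype_table(as.data.frame(gt)[keep, , drop = FALSE])
}

# Allele count table for one (rows subset, locus): named integer vector of
# gene-copy counts per allele state, NULL if no observed call.
.allele_counts <- function(gt, rows, locus) {
  a <- c(gt[[paste0(locus, "_a1")]][rows], gt[[paste0(locus, "_a2")]][rows])
  a <- a[!is.na(a)]
  if (!length(a)) return(NULL)
  tab <- table(a)
  stats::setNames(as.integer(tab), names(tab))
}

#' Allele frequencies at one node and locus
#'
#' @param gt a [genotype_table()].
#' @param node node id.
#' @param locus locus name.
#' @return named numeric vector of frequencies over observed allele states,
#'   summing to 1; `NULL` (with a warning) if the locus is entirely missing
#'   at the node.
#' @export
allele_frequencies <- function(gt, node, locus) {
  if (!locus %in% locus_names(gt)) stop("unknown locus: ", locus)
  cnt <- .allele_counts(gt, gt$node_id == node, locus)
  if (is.null(cnt)) {
    warning("all calls missing at node ", node, ", locus ", locus)
    return(NULL)
  }
  cnt / sum(cnt)
}

# Expected number of distinct alleles in a sample of g gene copies drawn
# without replacement from counts (hypergeometric rarefaction).
.rarefied_richness <- function(counts, g) {
  N <- sum(counts)
  # P(allele absent from the subsample) = C(N - N_a, g) / C(N, g)
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

#' Rarefied allelic richness per node and locus
#'
#' Expected number of distinct alleles in a standardized sample of `g` gene
#' copies, correcting allele counts for unequal sample sizes:
#' `AR_g = sum_a (1 - choose(N - N_a, g) / choose(N, g))` with `N` observed
#' gene copies and `N_a` copies of allele `a`. Equals the observed allele
#' count when `g = N`.
#'
#' @param gt a [genotype_table()].
#' @param g rarefaction size in gene copies; default: per species, twice the
#'   smallest per-node number of fully observed calls at the limiting locus
#'   (rarefy-to-minimum convention). Must satisfy `2 <= g <= min N`.
#' @return data frame with one row per (node, species, locus): `n_copies`,
#'   `g`, `AR`; per-node means are available via [node_diversity()].
#' @export
allelic_richness <- function(gt, g = NULL) {
  groups <- unique(data.frame(node_id = gt$node_id, species = gt$species,
                              stringsAsFactors = FALSE))
  loci <- locus_names(gt)
  out <- list()
  for (sp in unique(groups$species)) {
    gsub_ <- groups[groups$species == sp, , drop = FALSE]
    rows_l <- lapply(gsub_$node_id,
                     function(nd) which(gt$node_id == nd & gt$species == sp))
    copies <- sapply(seq_along(rows_l), function(i) {
      min(sapply(loci, function(l) {
        cnt <- .allele_counts(gt, rows_l[[i]], l)
        if (is.null(cnt)) Inf else sum(cnt)
      }))
    })
    g_sp <- if (is.null(g)) min(copies) else g
    if (!is.finite(g_sp) || g_sp < 2)
      stop("rarefaction size must be >= 2 (species ", sp, ")")
    for (i in seq_along(rows_l)) {
      for (l in loci) {
        cnt <- .allele_counts(gt, rows_l[[i]], l)
        if (is.null(cnt)) {
          ar <- NA_real_; nc <- 0L
        } else {
          nc <- sum(cnt)
          if (g_sp > nc)
            stop("rarefaction size g = ", g_sp, " exceeds the ", nc,
                 " observed gene copies at node ", gsub_$node_id[i],
                 ", locus ", l)
          ar <- .rarefied_richness(cnt, g_sp)
        }
        out[[length(out) + 1L]] <- data.frame(
          node_id = gsub_$node_id[i], species = sp, locus = l,
          n_copies = nc, g = g_sp, AR = ar, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Observed heterozygosity per node and locus
#'
#' Fraction of observed individuals that are heterozygous at the locus.
#' @param gt a [genotype_table()].
#' @return data frame with one row per (node, species, locus): `n`, `Ho`
#'   (`NA` where the locus is entirely missing).
#' @export
observed_heterozygosity <- function(gt) {
  .per_group_locus(gt, function(a1, a2) {
    obs <- !is.na(a1)
    if (!any(obs)) return(c(n = 0, value = NA_real_))
    c(n = sum(obs), value = mean(a1[obs] != a2[obs]))
  }, value_name = "Ho")
}

#' Expected heterozygosity (gene diversity) per node and locus
#'
#' Plain gene diversity `1 - sum(p_a^2)`, or (default) Nei's unbiased
#' small-sample estimator `Hs = n/(n-1) * (1 - sum p^2 - Ho/(2n))` with `n`
#' the number of observed individuals.
#' @param gt a [genotype_table()].
#' @param unbiased use the unbiased estimator (requires `n >= 2`).
#' @return data frame with one row per (node, species, locus): `n`, `He`.
#' @export
expected_heterozygosity <- function(gt, unbiased = TRUE) {
  .per_group_locus(gt, function(a1, a2) {
    obs <- !is.na(a1)
    n <- sum(obs)
    if (n == 0) return(c(n = 0, value = NA_real_))
    p <- .allele_counts(data.frame(x_a1 = a1[obs], x_a2 = a2[obs]),
                        rep(TRUE, n), "x")
    p <- p / sum(p)
    d <- 1 - sum(p^2)
    if (!unbiased) return(c(n = n, value = d))
    if (n < 2) stop("unbiased gene diversity requires >= 2 individuals")
    ho <- mean(a1[obs] != a2[obs])
    c(n = n, value = n / (n - 1) * (d - ho / (2 * n)))
  }, value_name = "He")
}

# apply fun(a1, a2) -> c(n, value) over every (node, species) x locus
.per_group_locus <- function(gt, fun, value_name) {
  groups <- unique(data.frame(node_id = gt$node_id, species = gt$species,
                              stringsAsFactors = FALSE))
  loci <- locus_names(gt)
  out <- list()
  for (i in seq_len(nrow(groups))) {
    rows <- gt$node_id == groups$node_id[i] & gt$species == groups$species[i]
    for (l in loci) {
      v <- fun(gt[[paste0(l, "_a1")]][rows], gt[[paste0(l, "_a2")]][rows])
      rec <- data.frame(node_id = groups$node_id[i],
                        species = groups$species[i], locus = l,
                        n = as.integer(v[["n"]]), value = v[["value"]],
                        stringsAsFactors = FALSE)
      names(rec)[names(rec) == "value"] <- value_name
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Subsample individuals per node to matched sample sizes
#'
#' Randomly retains at most `n_per_node[node]` individuals in each
#' (node, species) group, e.g. to compute simulated statistics on sample
#' sizes matched to an empirical survey before comparing rarefied allelic
#' richness.
#' @param gt a [genotype_table()].
#' @param n_per_node named integer vector of target sizes keyed by node id;
#'   nodes without an entry are kept in full.
#' @param seed RNG seed (set when not `NULL`).
#' @return a [genotype_table()] with the retained rows.
#' @export
subsample_genotypes <- function(gt, n_per_node, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  key <- paste(gt$node_id, gt$species, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(gt)), key), function(ix) {
    tgt <- n_per_node[gt$node_id[ix[1]]]
    if (is.na(tgt) || length(ix) <= tgt) ix
    else sample(ix, tgt)
  }), use.names = FALSE)
  genotype_table(as.data.frame(gt)[sort(keep), , drop = FALSE])
}

#' Within-population inbreeding coefficient F_IS per node
#'
#' `F_IS = 1 - mean_l(Ho_l) / mean_l(Hs_l)`, the ratio of locus means of
#' observed heterozygosity and unbiased gene diversity; loci with undefined
#' values are excluded pairwise.
#' @param gt a [genotype_table()].
#' @return data frame with one row per (node, species): `Fis` (`NA`, with a
#'   warning, where all loci are monomorphic).
#' @export
fis <- function(gt) {
  ho <- observed_heterozygosity(gt)
  hs <- expected_heterozygosity(gt, unbiased = TRUE)
  key <- paste(ho$node_id, ho$species, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sel <- key == k & !is.na(ho$Ho) & !is.na(hs$He)
    mhs <- mean(hs$He[sel])
    f <- if (!any(sel) || mhs <= 0) {
      warning("F_IS undefined (all loci monomorphic) for group ",
              ho$node_id[key == k][1])
      NA_real_
    } else 1 - mean(ho$Ho[sel]) / mhs
    data.frame(node_id = ho$node_id[key == k][1],
               species = ho$species[key == k][1], Fis = f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-node diversity summary
#'
#' One row per (node, species) with sample size, rarefaction size, and the
#' locus means of rarefied allelic richness, observed heterozygosity,
#' expected heterozygosity, plus F_IS. The estimator conventions (unbiased
#' gene diversity; rarefy-to-minimum g) are recorded as attributes.
#' @param gt a [genotype_table()].
#' @param g rarefaction size (gene copies); see [allelic_richness()].
#' @param unbiased use the unbiased gene-diversity estimator.
#' @return data frame with columns `node_id`, `species`, `n`, `g`, `AR`,
#'   `Ho`, `He`, `Fis`.
#' @export
node_diversity <- function(gt, g = NULL, unbiased = TRUE) {
  ar <- allelic_richness(gt, g = g)
  ho <- observed_heterozygosity(gt)
  he <- expected_heterozygosity(gt, unbiased = unbiased)
  fi <- fis(gt)
  key <- paste(ar$node_id, ar$species, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    nd <- ar$node_id[sel][1]; sp <- ar$species[sel][1]
    rows <- gt$node_id == nd & gt$species == sp
    data.frame(node_id = nd, species = sp, n = sum(rows),
               g = ar$g[sel][1],
               AR = mean(ar$AR[sel], na.rm = TRUE),
               Ho = mean(ho$Ho[sel], na.rm = TRUE),
               He = mean(he$He[sel], na.rm = TRUE),
               Fis = fi$Fis[fi$node_id == nd & fi$species == sp],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "estimators") <- list(
    He = if (unbiased) "Nei unbiased gene diversity" else "plain 1 - sum p^2",
    AR = "hypergeometric rarefaction, g = 2 x min fully-typed individuals")
  res
}

# Nei/Chesser sample-size-corrected Hs and Ht for one pair of populations at
# one locus; counts1/counts2 are gene-copy count vectors, n1/n2 the numbers
# of observed individuals, ho1/ho2 observed heterozygosities.
.nei_pair_locus <- function(counts1, counts2, n1, n2, ho1, ho2) {
  p1 <- counts1 / sum(counts1)
  p2 <- counts2 / sum(counts2)
  alleles <- union(names(p1), names(p2))
  q1 <- stats::setNames(rep(0, length(alleles)), alleles); q1[names(p1)] <- p1
  q2 <- stats::setNames(rep(0, length(alleles)), alleles); q2[names(p2)] <- p2
  nh <- 2 / (1 / n1 + 1 / n2)              # harmonic mean sample size
  ho <- mean(c(ho1, ho2))
  hs0 <- 1 - mean(c(sum(q1^2), sum(q2^2)))
  hs <- nh / (nh - 1) * (hs0 - ho / (2 * nh))
  pbar <- (q1 + q2) / 2
  ht <- 1 - sum(pbar^2) + hs / (2 * nh) - ho / (4 * nh)
  c(hs = hs, ht = ht)
}

#' Pairwise Nei F_ST between nodes
#'
#' Nei's `F_ST = (Ht - Hs) / Ht` for every pair of nodes, with `Hs` the
#' sample-size-corrected mean within-population gene diversity and `Ht` the
#' total gene diversity from mean allele frequencies (Nei & Chesser
#' corrections, two populations per pair). `Hs` and `Ht` are averaged over
#' loci before taking the ratio. Loci with data in only one member of a pair
#' are excluded from that pair. Small negative values can arise as estimator
#' artefacts and are reported as computed.
#'
#' Call this on a single-species table; pairs are formed between node groups
#' of whatever the table contains.
#'
#' @param gt a [genotype_table()].
#' @return symmetric matrix of F_ST values with zero diagonal; a pair with
#'   `Ht = 0` (e.g. two identical monomorphic populations) is `NA` and
#'   flagged with a warning.
#' @export
pairwise_nei_fst <- function(gt) {
  nodes <- unique(gt$node_id)
  loci <- locus_names(gt)
  # cache per (node, locus): counts, n individuals, Ho
  cache <- lapply(nodes, function(nd) {
    rows <- which(gt$node_id == nd)
    lapply(stats::setNames(loci, loci), function(l) {
      a1 <- gt[[paste0(l, "_a1")]][rows]; a2 <- gt[[paste0(l, "_a2")]][rows]
      obs <- !is.na(a1)
      if (!any(obs)) return(NULL)
      list(counts = .allele_counts(gt, rows, l), n = sum(obs),
           ho = mean(a1[obs] != a2[obs]))
    })
  })
  names(cache) <- nodes
  M <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) for (j in seq_len(i - 1L)) {
    hs <- ht <- numeric(0)
    for (l in loci) {
      c1 <- cache[[i]][[l]]; c2 <- cache[[j]][[l]]
      if (is.null(c1) || is.null(c2)) next
      v <- .nei_pair_locus(c1$counts, c2$counts, c1$n, c2$n, c1$ho, c2$ho)
      hs <- c(hs, v["hs"]); ht <- c(ht, v["ht"])
    }
    mht <- mean(ht)
    if (!length(ht) || !is.finite(mht) || mht <= 0) {
      warning("F_ST undefined (Ht = 0 or no shared locus) for pair ",
              nodes[i], " / ", nodes[j])
      fst <- NA_real_
    } else fst <- (mht - mean(hs)) / mht
    M[i, j] <- M[j, i] <- fst
  }
  M
}

#' Garza-Williamson M-ratio per node and locus
#'
#' `M = k / (r + 1)` with `k` the number of distinct allele sizes and `r`
#' the allele size range (in the units of the allele states, assumed to be a
#' 1-unit repeat ladder). Low values indicate allele-size gaps, a signature
#' of recent bottlenecks. Monomorphic loci give `M = 1` by convention.
#' @param gt a [genotype_table()].
#' @param by_node compute per (node, species) group (default) or pooled over
#'   the whole table (one row per locus).
#' @return data frame with columns `node_id`, `species` (absent when pooled),
#'   `locus`, `k`, `r`, `M`.
#' @export
m_ratio <- function(gt, by_node = TRUE) {
  loci <- locus_names(gt)
  one <- function(rows, nd = NULL, sp = NULL) {
    recs <- lapply(loci, function(l) {
      cnt <- .allele_counts(gt, rows, l)
      if (is.null(cnt)) return(NULL)
      sizes <- as.numeric(names(cnt))
      k <- length(sizes); r <- diff(range(sizes))
      data.frame(locus = l, k = k, r = r, M = k / (r + 1),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, recs)
    if (!is.null(nd) && !is.null(res))
      res <- cbind(data.frame(node_id = nd, species = sp,
                              stringsAsFactors = FALSE), res)
    res
  }
  if (!by_node) return(one(rep(TRUE, nrow(gt))))
  groups <- unique(data.frame(node_id = gt$node_id, species = gt$species,
                              stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    one(gt$node_id == groups$node_id[i] & gt$species == groups$species[i],
        groups$node_id[i], groups$species[i])
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries of two symmetric
#' matrices with a one-tailed permutation test (H1: positive association);
#' rows and columns of the second matrix are permuted jointly. With
#' `exact = TRUE` all `n!` permutations are enumerated (feasible for
#' `n <= 8`) and the p-value is the exact fraction of permutations with
#' `r >= r_obs` (identity included); otherwise `n_perm` random permutations
#' are drawn and the p-value uses add-one smoothing
#' `(1 + #(r_perm >= r_obs)) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices in the same node order.
#' @param n_perm number of random permutations.
#' @param seed RNG seed (set for reproducibility when not `NULL`).
#' @param exact enumerate all permutations instead of sampling.
#' @return list with elements `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000, seed = NULL, exact = FALSE) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) stop("matrices must have the same dimension")
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  if (stats::sd(v1) == 0 || stats::sd(m2[ut]) == 0)
    stop("zero-variance matrix: Mantel r undefined")
  r_obs <- stats::cor(v1, m2[ut])
  stat <- function(perm) stats::cor(v1, m2[perm, perm][ut])
  if (exact) {
    perms <- .all_permutations(n)
    rs <- vapply(perms, stat, numeric(1))
    return(list(r = r_obs, p = mean(rs >= r_obs - 1e-12),
                n_perm = length(perms)))
  }
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm))
    if (stat(sample.int(n)) >= r_obs - 1e-12) ge <- ge + 1L
  list(r = r_obs, p = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}

.all_permutations <- function(n) {
  if (n > 8) stop("exact Mantel test limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}
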