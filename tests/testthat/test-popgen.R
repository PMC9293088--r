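test_that("genotype table validation rejects malformed input", {
  gt <- toy_genotypes()
  expect_s3_class(gt, "genotype_table")
  expect_equal(nrow(gt), 4)
  expect_setequal(locus_names(gt), c("loc1", "loc2"))

  bad <- as.data.frame(toy_genotypes())
  bad$loc2_a2[1] <- NA                       # half-missing call
  expect_error(genotype_table(bad), "half-missing.*loc2.*ind1")

  dup <- as.data.frame(toy_genotypes())
  dup$individual_id[2] <- "ind1"
  expect_error(genotype_table(dup), "duplicate individual id")

  neg <- as.data.frame(toy_genotypes())
  neg$loc1_a1[1] <- -3
  expect_error(genotype_table(neg), "positive integers")
})

test_that("genotype TSV round trip preserves calls including missing", {
  gt <- toy_genotypes()
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gt, path)
  back <- read_genotypes(path)
  df_back <- as.data.frame(back); attr(df_back, "node_counts") <- NULL
  expect_equal(df_back, as.data.frame(gt))
  counts <- attr(back, "node_counts")
  expect_equal(counts$n[counts$node_id == "n1"], 4)
})

test_that("filter_nodes applies the minimum-sample inclusion rule", {
  sizes <- c(14, 15, 16)
  df <- do.call(rbind, lapply(seq_along(sizes), function(i) data.frame(
    individual_id = sprintf("g%d_%02d", i, seq_len(sizes[i])),
    node_id = paste0("node", i), species = "A",
    loc1_a1 = 100L, loc1_a2 = 102L)))
  gt <- genotype_table(df)
  kept <- filter_nodes(gt, min_n = 15)
  expect_setequal(unique(kept$node_id), c("node2", "node3"))
  expect_equal(nrow(filter_nodes(gt, min_n = 1)), nrow(gt))
  expect_warning(filter_nodes(gt, min_n = 100), "empty")
})

test_that("allele frequencies normalize over observed gene copies", {
  gt <- toy_genotypes()
  f <- allele_frequencies(gt, "n1", "loc1")
  expect_equal(f[["120"]], 0.75)
  expect_equal(f[["122"]], 0.25)
  expect_equal(sum(f), 1)
  # all-homozygous locus
  mono <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(120L, 120L), l_a2 = c(120L, 120L)))
  expect_equal(allele_frequencies(mono, "x", "l"), c("120" = 1))
  miss <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = NA_integer_, l_a2 = NA_integer_))
  expect_warning(expect_null(allele_frequencies(miss, "x", "l")),
                 "all calls missing")
})

test_that("rarefied allelic richness equals subset enumeration", {
  gt <- toy_genotypes()
  ar <- allelic_richness(gt, g = 2)
  # gene copies {120,120,120,122}: enumeration over C(4,2) subsets
  expect_equal(ar$AR[ar$locus == "loc1"], 1.5)
  expect_equal(ar$AR[ar$locus == "loc1"],
               enum_ar(c(120, 120, 120, 122), 2))

  # monomorphic copies always give 1
  mono <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(7L, 7L), l_a2 = c(7L, 7L)))
  expect_equal(allelic_richness(mono, g = 2)$AR, 1)

  # identity at g = N, monotonicity in g, enumeration oracle on random data
  set.seed(5)
  for (rep in 1:5) {
    copies <- sample(1:4, 8, replace = TRUE)
    df <- data.frame(individual_id = paste0("i", 1:4), node_id = "x",
                     species = "s",
                     l_a1 = copies[1:4], l_a2 = copies[5:8])
    gt1 <- genotype_table(df)
    ars <- sapply(2:8, function(g) allelic_richness(gt1, g = g)$AR)
    expect_equal(ars[length(ars)], length(unique(copies)))
    expect_true(all(diff(ars) >= -1e-12))
    expect_equal(ars[1], enum_ar(copies, 2), tolerance = 1e-12)
    expect_equal(ars[4], enum_ar(copies, 5), tolerance = 1e-12)
  }

  # g exceeding the observed copies names the limiting locus
  expect_error(allelic_richness(gt, g = 6), "g = 6 exceeds.*loc1")
})

test_that("observed and expected heterozygosity match hand calculations", {
  gt <- toy_genotypes()
  ho <- observed_heterozygosity(gt)
  expect_equal(ho$Ho[ho$locus == "loc1"], 0.5)   # 1 het of 2 observed
  expect_equal(ho$Ho[ho$locus == "loc2"], 0.75)  # 3 het of 4

  # two individuals both 1/2: plain He = 0.5 and unbiased He = 0.5
  both_het <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(1L, 1L), l_a2 = c(2L, 2L)))
  expect_equal(expected_heterozygosity(both_het, unbiased = FALSE)$He, 0.5)
  expect_equal(expected_heterozygosity(both_het, unbiased = TRUE)$He, 0.5)

  # p = (0.25, 0.25, 0.5) -> plain gene diversity 0.625
  p3 <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(1L, 2L), l_a2 = c(3L, 3L)))
  expect_equal(expected_heterozygosity(p3, unbiased = FALSE)$He, 0.625)

  # monomorphic -> 0 under either estimator
  mono <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(7L, 7L), l_a2 = c(7L, 7L)))
  expect_equal(expected_heterozygosity(mono, unbiased = FALSE)$He, 0)
  expect_equal(expected_heterozygosity(mono, unbiased = TRUE)$He, 0)
})

test_that("statistics agree with a slow loop-based reference on random tables", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 8
    df <- data.frame(individual_id = paste0("i", 1:n),
                     node_id = rep(c("x", "y"), each = n / 2), species = "s")
    for (l in 1:3) {
      df[[paste0("loc", l, "_a1")]] <- sample(1:5, n, replace = TRUE)
      df[[paste0("loc", l, "_a2")]] <- sample(1:5, n, replace = TRUE)
    }
    gt <- genotype_table(df)
    ho <- observed_heterozygosity(gt)
    he <- expected_heterozygosity(gt, unbiased = TRUE)
    for (nd in c("x", "y")) for (l in paste0("loc", 1:3)) {
      rows <- df$node_id == nd
      a1 <- df[[paste0(l, "_a1")]][rows]; a2 <- df[[paste0(l, "_a2")]][rows]
      # slow Ho: explicit loop
      nhet <- 0
      for (i in seq_along(a1)) if (a1[i] != a2[i]) nhet <- nhet + 1
      expect_equal(ho$Ho[ho$node_id == nd & ho$locus == l],
                   nhet / length(a1))
      # slow unbiased He: direct scalar formula
      copies <- c(a1, a2)
      p <- as.vector(table(copies)) / length(copies)
      ni <- length(a1)
      hs <- ni / (ni - 1) * (1 - sum(p^2) - (nhet / ni) / (2 * ni))
      expect_equal(he$He[he$node_id == nd & he$locus == l], hs)
    }
  }
})

test_that("F_IS is the ratio of locus means of Ho and Hs", {
  # Ho = Hs at every locus -> 0 is approached by construction in HWE data;
  # assert the two limiting cases and a hand-computed toy value instead
  all_hom <- genotype_table(data.frame(
    individual_id = paste0("i", 1:4), node_id = "x", species = "s",
    l_a1 = c(1L, 1L, 2L, 2L), l_a2 = c(1L, 1L, 2L, 2L)))
  expect_equal(fis(all_hom)$Fis, 1)   # Ho = 0, Hs > 0

  mono <- genotype_table(data.frame(
    individual_id = c("a", "b"), node_id = "x", species = "s",
    l_a1 = c(7L, 7L), l_a2 = c(7L, 7L)))
  expect_warning(expect_true(is.na(fis(mono)$Fis)), "monomorphic")

  # two-locus toy: independent ratio-of-means computation
  gt <- genotype_table(data.frame(
    individual_id = paste0("i", 1:4), node_id = "x", species = "s",
    la_a1 = c(1L, 1L, 1L, 2L), la_a2 = c(2L, 1L, 2L, 2L),
    lb_a1 = c(3L, 3L, 4L, 4L), lb_a2 = c(3L, 4L, 4L, 4L)))
  ho_l <- c(2 / 4, 1 / 4)
  hs_l <- mapply(function(copies, ho) 4 / 3 * (1 - sum((table(copies) / 8)^2) - ho / 8),
                 list(c(1, 2, 1, 1, 1, 2, 2, 2), c(3, 3, 3, 4, 4, 4, 4, 4)),
                 ho_l)
  expect_equal(fis(gt)$Fis, 1 - mean(ho_l) / mean(hs_l))
})

test_that("pairwise Nei F_ST behaves at its calibration points", {
  # two large populations fixed for different alleles -> 1
  fixed <- genotype_table(data.frame(
    individual_id = paste0("i", 1:100),
    node_id = rep(c("p1", "p2"), each = 50), species = "s",
    l_a1 = rep(c(1L, 2L), each = 50), l_a2 = rep(c(1L, 2L), each = 50)))
  M <- pairwise_nei_fst(fixed)
  expect_equal(M["p1", "p2"], 1)
  expect_equal(diag(M), c(p1 = 0, p2 = 0))
  expect_equal(M, t(M))

  # identical monomorphic populations: Ht = 0, undefined and flagged
  mono2 <- genotype_table(data.frame(
    individual_id = paste0("i", 1:20),
    node_id = rep(c("p1", "p2"), each = 10), species = "s",
    l_a1 = 5L, l_a2 = 5L))
  expect_warning(Mm <- pairwise_nei_fst(mono2), "Ht = 0")
  expect_true(is.na(Mm["p1", "p2"]))

  # identical allele-frequency spectra -> ~0 within estimator noise
  set.seed(7)
  block <- function(pop) {
    # both populations carry exactly 30 copies of allele 1, 50 of 2, 20 of 3
    copies <- sample(rep(c(1L, 2L, 3L), times = c(30, 50, 20)))
    data.frame(individual_id = paste0(pop, "_", 1:50), node_id = pop,
               species = "s",
               l_a1 = copies[1:50], l_a2 = copies[51:100])
  }
  same <- genotype_table(rbind(block("p1"), block("p2")))
  Ms <- pairwise_nei_fst(same)
  expect_lt(abs(Ms["p1", "p2"]), 0.02)

  # scalar oracle: direct evaluation of the corrected Nei formulas on a
  # small printed table
  t1 <- data.frame(individual_id = paste0("a", 1:4), node_id = "p1",
                   species = "s", l_a1 = c(1L, 1L, 2L, 2L),
                   l_a2 = c(1L, 2L, 2L, 3L))
  t2 <- data.frame(individual_id = paste0("b", 1:4), node_id = "p2",
                   species = "s", l_a1 = c(2L, 3L, 3L, 3L),
                   l_a2 = c(3L, 3L, 3L, 1L))
  gt <- genotype_table(rbind(t1, t2))
  p1 <- c(3, 4, 1) / 8; p2 <- c(1, 1, 6) / 8
  ho <- mean(c(2 / 4, 2 / 4))
  nh <- 2 / (1 / 4 + 1 / 4)
  hs <- nh / (nh - 1) * (1 - mean(c(sum(p1^2), sum(p2^2))) - ho / (2 * nh))
  pb <- (p1 + p2) / 2
  ht <- 1 - sum(pb^2) + hs / (2 * nh) - ho / (4 * nh)
  expect_equal(pairwise_nei_fst(gt)["p1", "p2"], (ht - hs) / ht)
})

test_that("island-model genotypes recover the target differentiation", {
  gt <- island_model_genotypes(n_pops = 10, n_per_pop = 50, n_loci = 10,
                               target_fst = 0.2, seed = 31)
  M <- pairwise_nei_fst(gt)
  expect_lt(abs(mean(M[upper.tri(M)]) - 0.2), 0.05)

  gt0 <- island_model_genotypes(n_pops = 10, n_per_pop = 50, n_loci = 10,
                                target_fst = 0, seed = 32)
  M0 <- pairwise_nei_fst(gt0)
  expect_lt(abs(mean(M0[upper.tri(M0)])), 0.02)
})

test_that("subsampling matches per-node target sizes and keeps valid tables", {
  gt <- island_model_genotypes(n_pops = 4, n_per_pop = 30, seed = 21)
  targets <- c(p1 = 10, p2 = 40, p3 = 15)   # p4 deliberately missing
  sub <- subsample_genotypes(gt, targets, seed = 1)
  n <- table(sub$node_id)
  expect_equal(unname(n[["p1"]]), 10)
  expect_equal(unname(n[["p2"]]), 30)   # target above group size: kept whole
  expect_equal(unname(n[["p3"]]), 15)
  expect_equal(unname(n[["p4"]]), 30)   # no entry: kept whole
  expect_s3_class(sub, "genotype_table")
  # subsampled rows are a subset of the original individuals
  expect_true(all(sub$individual_id %in% gt$individual_id))
})

test_that("M-ratio counts distinct sizes over the size range", {
  gt <- genotype_table(data.frame(
    individual_id = paste0("i", 1:3), node_id = "x", species = "s",
    la_a1 = c(10L, 11L, 12L), la_a2 = c(10L, 11L, 12L),   # {10,11,12}
    lb_a1 = c(10L, 10L, 14L), lb_a2 = c(14L, 10L, 14L),   # {10,14}
    lc_a1 = 9L, lc_a2 = 9L))                              # monomorphic
  m <- m_ratio(gt)
  expect_equal(m$M[m$locus == "la"], 1)        # 3 / (2 + 1)
  expect_equal(m$M[m$locus == "lb"], 0.4)      # 2 / (4 + 1)
  expect_equal(m$M[m$locus == "lc"], 1)        # monomorphic convention
  pooled <- m_ratio(gt, by_node = FALSE)
  expect_equal(pooled$M, m$M)                  # single node: identical
})

test_that("Mantel test statistic and permutation p-value are correct", {
  set.seed(3)
  n <- 6
  x <- matrix(runif(n * n), n); m1 <- x + t(x); diag(m1) <- 0
  res <- mantel_test(m1, m1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  res_rev <- mantel_test(m1, max(m1) - m1 + 0.1 * (diag(n) > 0), n_perm = 99,
                         seed = 1)
  expect_equal(res_rev$r, -1)

  expect_error(mantel_test(m1, matrix(1, n, n)), "zero-variance")

  # exact p-value against Heap's-algorithm enumeration on a 5x5 pair
  n <- 5
  y <- matrix(runif(n * n), n); m2 <- y + t(y); diag(m2) <- 0
  m1s <- m1[1:5, 1:5]; diag(m1s) <- 0
  ex <- mantel_test(m1s, m2, exact = TRUE)
  ut <- upper.tri(m1s)
  r_obs <- cor(m1s[ut], m2[ut])
  rs <- vapply(heap_perms(n),
               function(p) cor(m1s[ut], m2[p, p][ut]), numeric(1))
  expect_equal(ex$n_perm, factorial(5))
  expect_equal(ex$p, mean(rs >= r_obs - 1e-12))
  expect_equal(ex$r, r_obs)

  # sampled p-value has add-one smoothing and is seed-stable
  r1 <- mantel_test(m1s, m2, n_perm = 199, seed = 9)
  r2 <- mantel_test(m1s, m2, n_perm = 199, seed = 9)
  expect_equal(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)

  # cross-check r against vegan's implementation
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::mantel(m1s, m2, permutations = 99)
    expect_equal(r1$r, unname(vg$statistic))
  }
})
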