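toy_loci <- function(repertoires) {
  dplyr::bind_rows(lapply(names(repertoires), function(sp) {
    tibble::tibble(species = sp, motif = repertoires[[sp]])
  }))
}

test_that("the motif matrix encodes presence over the motif union", {
  m <- build_motif_matrix(toy_loci(list(s1 = c("A", "AT"),
                                        s2 = c("A", "TTA"))))
  expect_equal(sort(setdiff(names(m), "species")), c("A", "AT", "TTA"))
  expect_equal(unlist(m[m$species == "s1", c("A", "AT", "TTA")]),
               c(A = 1L, AT = 1L, TTA = 0L))
  expect_equal(unlist(m[m$species == "s2", c("A", "AT", "TTA")]),
               c(A = 1L, AT = 0L, TTA = 1L))

  same <- build_motif_matrix(toy_loci(list(x = c("A", "AT"),
                                           y = c("A", "AT", "A"))))
  expect_equal(unlist(same[1, -1]), unlist(same[2, -1]))
  expect_error(build_motif_matrix(tibble::tibble(species = "only",
                                                 motif = "A")),
               "2 species")
})

test_that("a planted 10-species repertoire design is recovered exactly", {
  set.seed(7)
  motifs <- c("A", "T", "AT", "TA", "TTA", "TAA", "AAT", "ATTT", "TATAT")
  design <- matrix(rbinom(10 * length(motifs), 1, 0.5), nrow = 10,
                   dimnames = list(paste0("sp", 1:10), motifs))
  design[, "A"] <- 1L  # keep every repertoire non-empty
  reps <- lapply(rownames(design), function(sp) {
    motifs[design[sp, ] == 1L]
  })
  names(reps) <- rownames(design)
  m <- build_motif_matrix(toy_loci(reps))
  present <- sort(colnames(design)[colSums(design) > 0])
  expect_equal(sort(setdiff(names(m), "species")), present)
  got <- as.matrix(m[, present])
  rownames(got) <- m$species
  expect_equal(got[rownames(design), present],
               design[, present, drop = FALSE])
})

test_that("the balance index is min(present, absent) / n", {
  reps <- c(rep(list(c("A", "TTA")), 5), rep(list(c("A", "TAA")), 2),
            rep(list("A"), 3))
  names(reps) <- paste0("sp", 1:10)
  # TTA in 5/10, TAA in 2/10, A in 10/10
  b <- balance_index(build_motif_matrix(toy_loci(reps)))
  expect_equal(b$balance_index[b$motif == "TTA"], 0.5)
  expect_equal(b$balance_index[b$motif == "TAA"], 0.2)
  expect_equal(b$balance_index[b$motif == "A"], 0)
  expect_equal(b$motif[1], "TTA")  # sorted by decreasing informativeness
  expect_error(balance_index(build_motif_matrix(toy_loci(reps)), "GGC"),
               "Unknown")
})

test_that("the balance index is invariant under complementing a column", {
  set.seed(31)
  for (n_present in 1:9) {
    reps <- lapply(1:10, function(i) {
      if (i <= n_present) c("BASE", "X") else "BASE"
    })
    names(reps) <- paste0("sp", 1:10)
    b <- balance_index(build_motif_matrix(toy_loci(reps)))
    idx <- b$balance_index[b$motif == "X"]
    # complement: X present in the other 10 - n_present species
    reps2 <- lapply(1:10, function(i) {
      if (i > n_present) c("BASE", "X") else "BASE"
    })
    names(reps2) <- paste0("sp", 1:10)
    b2 <- balance_index(build_motif_matrix(toy_loci(reps2)))
    expect_equal(b2$balance_index[b2$motif == "X"], idx)
    expect_equal(idx, min(n_present, 10 - n_present) / 10)
  }
})

test_that("Sørensen dissimilarity matches set arithmetic", {
  m <- build_motif_matrix(toy_loci(list(
    same1 = c("A", "AT"), same2 = c("A", "AT"),
    disjoint = c("TTA", "TAA"),
    i = c("A", "AT", "TTA"),
    j = c("A", "AT", "TAA", "CTA", "ATTT")
  )))
  d <- as.matrix(sorensen_dissimilarity(m))
  expect_equal(d["same1", "same2"], 0)
  expect_equal(d["same1", "disjoint"], 1)
  # |P_i| = 3, |P_j| = 5, overlap 2 -> 1 - 4/8
  expect_equal(d["i", "j"], 0.5)
  empty <- toy_loci(list(a = "A", b = "T"))
  mm <- build_motif_matrix(empty)
  mm$A[mm$species == "a"] <- 0L
  mm$T[mm$species == "a"] <- 0L
  expect_error(sorensen_dissimilarity(mm), "empty")
})

test_that("Sørensen output is a proper bounded dissimilarity", {
  set.seed(88)
  for (rep in 1:25) {
    cells <- matrix(rbinom(8 * 12, 1, runif(1, 0.3, 0.8)), nrow = 8)
    cells[, 1] <- 1L
    m <- tibble::as_tibble(as.data.frame(cells))
    names(m) <- paste0("m", 1:12)
    m <- dplyr::bind_cols(tibble::tibble(species = paste0("s", 1:8)), m)
    class(m) <- c("motif_matrix", class(m))
    d <- as.matrix(sorensen_dissimilarity(m))
    expect_true(all(diag(d) == 0))
    expect_true(isSymmetric(d))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("Ward.D2 clustering matches an independent centroid oracle", {
  pts <- matrix(c(0, 0, 1, 0, 3, 2, 5, 5), ncol = 2, byrow = TRUE)
  d <- dist(pts)
  attr(d, "Labels") <- paste0("p", 1:4)
  hc <- ward_cluster(d)
  o <- oracle_ward(d)
  expect_equal(hc$height, o$heights, tolerance = 1e-12)
  coph <- as.matrix(stats::cophenetic(hc))
  dimnames(o$cophenetic) <- dimnames(coph)
  expect_equal(coph, o$cophenetic, tolerance = 1e-12)
})

test_that("Ward.D2 handles the base cases and rejects bad input", {
  d2 <- stats::as.dist(matrix(c(0, 0.3, 0.3, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  hc <- ward_cluster(d2)
  expect_equal(hc$height, 0.3)
  dn <- stats::as.dist(matrix(c(0, NaN, NaN, 0), 2))
  expect_error(ward_cluster(dn), "finite")
})

test_that("a planted two-block structure is recovered by the first cut", {
  labs <- paste0("s", 1:8)
  m <- matrix(0.9, 8, 8, dimnames = list(labs, labs))
  m[1:4, 1:4] <- 0.1
  m[5:8, 5:8] <- 0.1
  diag(m) <- 0
  hc <- ward_cluster(stats::as.dist(m))
  blocks <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(blocks[1:4])), 1L)
  expect_equal(length(unique(blocks[5:8])), 1L)
  expect_false(blocks[1] == blocks[5])
})

test_that("Ward.D2 reproduces an ultrametric input's topology", {
  # build an ultrametric: ((a,b):1,(c,d):2):4 -> cophenetic heights
  labs <- c("a", "b", "c", "d")
  u <- matrix(4, 4, 4, dimnames = list(labs, labs))
  u["a", "b"] <- u["b", "a"] <- 1
  u["c", "d"] <- u["d", "c"] <- 2
  diag(u) <- 0
  hc <- ward_cluster(stats::as.dist(u))
  first <- stats::cutree(hc, k = 3)
  expect_equal(first[["a"]], first[["b"]])
  second <- stats::cutree(hc, k = 2)
  expect_equal(second[["c"]], second[["d"]])
})

test_that("Newick export writes a readable 4-leaf tree", {
  labs <- paste0("t", 1:4)
  m <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
              dimnames = list(labs, labs))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(ward_cluster(stats::as.dist(m)), path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, labs)
})

test_that("Mantel r is 1 for identical and affine-related matrices", {
  set.seed(12)
  m <- as.matrix(dist(matrix(rnorm(12), 6)))
  labs <- paste0("s", 1:6)
  dimnames(m) <- list(labs, labs)
  d1 <- stats::as.dist(m)
  r_same <- mantel_test(d1, d1, n_permutations = 99, seed = 1)$r_observed
  expect_equal(r_same, 1)
  d2 <- stats::as.dist(2.5 * m + 0.3)
  expect_equal(mantel_test(d1, d2, n_permutations = 99,
                           seed = 1)$r_observed, 1)
})

test_that("Mantel validates labels, variance and the seed requirement", {
  set.seed(12)
  m <- as.matrix(dist(matrix(rnorm(12), 6)))
  labs <- paste0("s", 1:6)
  dimnames(m) <- list(labs, labs)
  d1 <- stats::as.dist(m)
  m2 <- m
  dimnames(m2) <- list(rev(labs), rev(labs))
  expect_error(mantel_test(d1, stats::as.dist(m2), seed = 1), "labels")
  expect_error(mantel_test(d1, d1), "seed")
  flat <- matrix(1, 6, 6, dimnames = list(labs, labs))
  diag(flat) <- 0
  expect_error(mantel_test(d1, stats::as.dist(flat), seed = 1), "variance")
})

test_that("Mantel is reproducible under a fixed seed and obeys its p formula", {
  set.seed(5)
  a <- as.matrix(dist(matrix(rnorm(16), 8)))
  b <- as.matrix(dist(matrix(rnorm(16), 8)))
  labs <- paste0("x", 1:8)
  dimnames(a) <- dimnames(b) <- list(labs, labs)
  r1 <- mantel_test(stats::as.dist(a), stats::as.dist(b), 499, seed = 77)
  r2 <- mantel_test(stats::as.dist(a), stats::as.dist(b), 499, seed = 77)
  expect_identical(tidy(r1), tidy(r2))
  expect_equal(r1$p_value,
               (1 + sum(r1$perm >= r1$r_observed)) / (1 + 499))
})

test_that("sampled Mantel p at n = 4 sits inside exact-enumeration bounds", {
  set.seed(42)
  a <- as.matrix(dist(matrix(rnorm(8), 4)))
  b <- as.matrix(dist(matrix(rnorm(8), 4)))
  labs <- paste0("q", 1:4)
  dimnames(a) <- dimnames(b) <- list(labs, labs)
  d1 <- stats::as.dist(a)
  d2 <- stats::as.dist(b)
  r_all <- oracle_mantel_exact_r(d1, d2)
  r_obs <- r_all[1]  # identity permutation is the first enumerated
  k <- sum(r_all >= r_obs - 1e-12)
  res <- mantel_test(d1, d2, n_permutations = 999, seed = 3)
  expect_equal(res$r_observed, r_obs, tolerance = 1e-12)
  count <- res$p_value * 1000 - 1
  bounds <- qbinom(c(0.005, 0.995), 999, k / 24)
  expect_gte(count, bounds[1])
  expect_lte(count, bounds[2])
})

test_that("count-density correlation recovers planted and degenerate r", {
  # equal genome lengths: density proportional to count -> r = 1
  eq <- tibble::tibble(n_ssrs = c(10, 20, 30, 40),
                       genome_length = rep(150000, 4))
  expect_equal(count_density_correlation(eq)$r, 1)
  two <- tibble::tibble(n_ssrs = c(10, 55),
                        genome_length = c(150000, 160000))
  expect_equal(abs(count_density_correlation(two)$r), 1)
  set.seed(10)
  pl <- tibble::tibble(n_ssrs = sample(50:120, 10),
                       genome_length = sample(150000:165000, 10))
  expect_equal(count_density_correlation(pl)$r,
               cor(pl$n_ssrs, pl$n_ssrs / pl$genome_length * 1000),
               tolerance = 1e-6)
  expect_error(count_density_correlation(
    tibble::tibble(n_ssrs = c(5, 5, 5), genome_length = rep(1000, 3))),
    "Constant")
})
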