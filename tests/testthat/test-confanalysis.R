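test_that("Kabsch superposition recovers exact rigid transforms", {
  ca <- helix_ca(20)
  # identity input
  fit0 <- kabsch_superpose(ca, ca)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-10)
  # rotated + translated copy superposes to ~0 RMSD
  set.seed(9)
  for (rep in 1:5) {
    rot <- with_seed_rotation()
    mob <- sweep(ca %*% t(rot), 2, runif(3, -2, 2), FUN = "+")
    fit <- kabsch_superpose(mob, ca)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }
  expect_error(kabsch_superpose(cbind(0:4, 0, 0), cbind(0:4, 0, 0) * 1.1),
               "degenerate")
})

test_that("Kabsch RMSD is optimal against random rotations", {
  set.seed(17)
  for (rep in 1:20) {
    A <- matrix(runif(36, 0, 2), 12, 3)
    B <- A + matrix(rnorm(36, 0, 0.15), 12, 3)
    best <- kabsch_superpose(A, B)$rmsd
    # random proper rotations (with optimal translation) never beat it
    trials <- vapply(1:50, function(i) {
      rot <- with_seed_rotation()
      Ar <- A %*% t(rot)
      Ar <- sweep(Ar, 2, colMeans(Ar) - colMeans(B))
      sqrt(mean(rowSums((Ar - B)^2)))
    }, numeric(1))
    expect_true(all(best <= trials + 1e-12))
  }
})

test_that("daura_cluster matches the brute-force greedy oracle, including ties", {
  set.seed(29)
  for (rep in 1:12) {
    n <- 20
    # constructed symmetric 'RMSD' matrices with deliberate duplicate
    # rows to exercise tie-breaking
    M <- matrix(runif(n * n, 0, 0.4), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    M[3, ] <- M[7, ]; M[, 3] <- M[, 7]; M[3, 3] <- 0  # tie pair
    cl <- daura_cluster(M, cutoff = 0.15)
    or <- daura_oracle(M, cutoff = 0.15)
    # same partition and same centroids (up to the size-ordering relabel)
    expect_equal(sort(cl$centroids), sort(or$centroids))
    expect_equal(length(unique(cl$assignment)), max(or$assignment))
    for (k in unique(or$assignment))
      expect_equal(length(unique(cl$assignment[or$assignment == k])), 1L)
  }
})

test_that("two planted conformational groups give exactly two clusters", {
  ca <- helix_ca(25)
  other <- perturb_to_rmsd(ca, 0.5, seed = 77)
  frames <- c(lapply(1:9, function(s) perturb_to_rmsd(ca, 0.014, seed = s)),
              lapply(1:11, function(s) perturb_to_rmsd(other, 0.014,
                                                       seed = 100 + s)))
  w <- c(rep(1, 9), rep(2, 11))
  cl <- daura_cluster(frames, cutoff = 0.1, weights = w)
  expect_equal(length(cl$centroids), 2L)
  expect_equal(sum(cl$sizes), 20L)
  expect_equal(sum(cl$weighted_fractions), 1)
  # weighted ranking puts the heavier group first
  expect_equal(cl$sizes[1], 11L)
  # all frames of one planted group share a cluster
  expect_equal(length(unique(cl$assignment[1:9])), 1L)
  expect_equal(length(unique(cl$assignment[10:20])), 1L)
  # single identical group collapses to one cluster
  one <- daura_cluster(lapply(1:5, function(i) ca), cutoff = 0.1)
  expect_equal(length(one$centroids), 1L)
  expect_equal(one$sizes, 5L)
})

test_that("clustering is invariant under frame reordering (up to relabeling)", {
  ca <- helix_ca(15)
  frames <- lapply(seq(0.02, 0.6, length.out = 12), function(t)
    perturb_to_rmsd(ca, t, seed = round(t * 1000)))
  cl1 <- daura_cluster(frames, cutoff = 0.15)
  perm <- c(5, 1, 12, 3, 8, 2, 10, 7, 4, 11, 6, 9)
  cl2 <- daura_cluster(frames[perm], cutoff = 0.15)
  # partitions agree after mapping through the permutation
  part1 <- cl1$assignment[perm]
  expect_equal(length(unique(part1)), length(unique(cl2$assignment)))
  tab <- table(part1, cl2$assignment)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("qres equals the brute-force oracle and is 1 on identical structures", {
  ca <- helix_ca(24)
  q1 <- qres(ca, ca)
  expect_true(all(abs(q1$q - 1) < 1e-12))
  for (rep in 1:20) {
    p <- perturb_to_rmsd(ca, runif(1, 0.05, 0.5), seed = rep)
    got <- qres(ca, p)$q
    want <- qres_oracle(ca, p)
    expect_equal(got, want, tolerance = 1e-10)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("qres on a 5-residue toy matches hand-evaluated sums", {
  # CA positions on a line, 0.4 nm apart; displace residue 3 by 0.5 nm
  A <- cbind(0.4 * (0:4), 0, 0)
  B <- A
  B[3, 2] <- 0.5
  q <- qres(A, B)$q
  dd <- function(i, j, X) 10 * sqrt(sum((X[i, ] - X[j, ])^2))  # Angstrom
  term <- function(i, j) {
    exp(-(dd(i, j, A) - dd(i, j, B))^2 / (2 * abs(i - j)^0.15))
  }
  # residue 1: pairs (1,3), (1,4), (1,5)
  expect_equal(q[1], mean(c(term(1, 3), term(1, 4), term(1, 5))),
               tolerance = 1e-12)
  # residue 3: pairs (3,1), (3,5)
  expect_equal(q[3], mean(c(term(3, 1), term(3, 5))), tolerance = 1e-12)
  # residue 5: pairs (5,1), (5,2), (5,3)
  expect_equal(q[5], mean(c(term(5, 1), term(5, 2), term(5, 3))),
               tolerance = 1e-12)
})

test_that("qres is symmetric and decreases with planted perturbation", {
  ca <- helix_ca(30)
  p <- perturb_to_rmsd(ca, 0.1, seed = 5)
  expect_equal(qres(ca, p)$q, qres(p, ca)$q, tolerance = 1e-12)
  med <- vapply(c(0.05, 0.1, 0.2, 0.4), function(t)
    median(vapply(1:20, function(s)
      median(qres(ca, perturb_to_rmsd(ca, t, seed = s))$q), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("unstable patches threshold the Q profile", {
  qp <- data.frame(residue_index = 1:4, q = c(0.9, 0.4, 0.6, 0.49))
  expect_equal(unstable_patches(qp), c(2L, 4L))
  expect_equal(unstable_patches(qp, threshold = 0), integer(0))
  qp1 <- data.frame(residue_index = 1:3, q = rep(1, 3))
  expect_equal(unstable_patches(qp1), integer(0))
})

test_that("patch frequencies count systems and stratify consistently", {
  sets <- list(c(2, 5), c(2, 7), c(2, 5, 9), c(4))
  pf <- patch_frequency(sets, 1:10)
  expect_equal(pf$frequency[pf$residue_index == 2], 0.75)
  expect_equal(pf$frequency[pf$residue_index == 5], 0.5)
  expect_equal(pf$frequency[pf$residue_index == 1], 0)
  # residue unstable in 3 of 8 systems -> 0.375
  sets8 <- c(sets, list(integer(0), c(5), integer(0), integer(0)))
  pf8 <- patch_frequency(sets8, 1:10)
  expect_equal(pf8$frequency[pf8$residue_index == 5], 0.375)
  # stratified frequencies, weighted by group sizes, give the pooled one
  groups <- c("bcd", "bcd", "hpbcd", "hpbcd", "none", "none", "none", "none")
  pfs <- patch_frequency(sets8, 1:10, groups = groups)
  pooled <- (2 * pfs$frequency_bcd + 2 * pfs$frequency_hpbcd +
               4 * pfs$frequency_none) / 8
  expect_equal(pooled, pfs$frequency, tolerance = 1e-12)
  expect_error(patch_frequency(list(c(11)), 1:10), "outside")
})

test_that("crossref joins frequencies, ranks and APR overlap correctly", {
  pf <- data.frame(residue_index = 1:20,
                   frequency = c(rep(0, 10), seq(0.1, 1, by = 0.1)))
  inc <- data.frame(residue_index = 1:20, frequency = pf$frequency)
  # identical profiles -> rank correlation 1
  cx <- crossref_patches(pf, inc, c(15:18))
  expect_equal(cx$rank_correlation, 1)
  # APR 15-18 all within the patch set 11..20: jaccard 4/10
  expect_equal(cx$jaccard_apr, 4 / 10)
  # disjoint sets -> jaccard 0
  cx0 <- crossref_patches(pf, inc, 1:5)
  expect_equal(cx0$jaccard_apr, 0)
  # 4 overlapping of 10+10 residues -> 4/16
  pf2 <- data.frame(residue_index = 1:30,
                    frequency = as.numeric(1:30 %in% 1:10))
  cx2 <- crossref_patches(pf2, data.frame(residue_index = 1:30,
                                          frequency = 0), 7:16)
  expect_equal(cx2$jaccard_apr, 4 / 16)
  expect_error(crossref_patches(pf, inc, 19:25), "outside")
})

test_that("APR range strings parse to residue sets", {
  expect_equal(parse_apr_ranges("PHE13-CYS17"), 13:17)
  expect_equal(parse_apr_ranges("ILE56"), 56L)
  expect_equal(parse_apr_ranges("PHE13-CYS17, CYS36-LYS40"),
               c(13:17, 36:40))
  expect_equal(parse_apr_ranges(c("SER80-LEU89", "ILE56")),
               sort(c(56L, 80:89)))
  expect_error(parse_apr_ranges("LEU20-PHE10"), "descending")
})
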