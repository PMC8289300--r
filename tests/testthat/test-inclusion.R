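test_that("cavity geometry recovers construction and rotates covariantly", {
  cd <- make_cd_molecule(center = c(1, 2, 3))
  cg <- cavity_geometry(cd$topology, cd$frame, 1)
  expect_equal(cg$axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(cg$radius, 0.5, tolerance = 1e-9)
  expect_equal(cg$centroid, c(1, 2, 3), tolerance = 1e-9)
  # a known rotation of the molecule rotates the axis identically
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  fr2 <- cd$frame
  fr2$coords <- cd$frame$coords %*% t(R)
  cg2 <- cavity_geometry(cd$topology, fr2, 1)
  expect_equal(cg2$axis, as.numeric(R %*% cg$axis), tolerance = 1e-9)
  expect_error(cavity_geometry(cd$topology[-2, ], cd$frame, 1), "rim")
})

test_that("a residue at the cavity centre is included; a distant one is not", {
  tr <- make_inclusion_system(include_res = 4)
  ev <- detect_inclusions(tr)
  expect_true(any(ev$residue_index == 4 &
                    abs(ev$radial_offset) < 1e-9 &
                    abs(ev$axial_offset) < 1e-9))
  # push the protein 3 nm away: no events
  far <- tr
  np <- sum(startsWith(tr$topology$role, "protein_backbone"))
  far$frames[[1]]$coords[seq_len(np), 1] <-
    far$frames[[1]]$coords[seq_len(np), 1] - 3
  expect_equal(nrow(detect_inclusions(far)), 0L)
})

test_that("detect_inclusions equals a brute-force cylinder check on random frames", {
  set.seed(19)
  for (rep in 1:20) {
    n_res <- 6
    box <- c(6, 6, 6)
    h <- make_ideal_helix(n_res, seed = rep, box = box)
    cd1 <- make_cd_molecule(center = runif(3, 1.5, 4.5),
                            axis = rand_unit(), box = box)
    cd2 <- make_cd_molecule(center = runif(3, 1.5, 4.5),
                            axis = rand_unit(), box = box)
    top <- cdx_topology(
      c(h$topology$atom_name, cd1$topology$atom_name, cd2$topology$atom_name),
      c(h$topology$residue_name, cd1$topology$residue_name,
        cd2$topology$residue_name),
      c(h$topology$residue_index, cd1$topology$residue_index + n_res,
        cd2$topology$residue_index + n_res + 7))
    top <- assign_roles(top)
    cc <- rbind(h$frame$coords, cd1$frame$coords, cd2$frame$coords)
    tr <- cdx_trajectory(top, list(cdx_frame(cc, box)))
    ev <- detect_inclusions(tr, radial_max = 0.6, axial_max = 0.5)

    # independent oracle: explicit point-in-cylinder over all CD-residue pairs
    oracle <- list()
    cd_mols <- sort(unique(top$molecule_id[top$residue_name == "GLC"]))
    for (m in cd_mols) {
      prim <- cc[top$molecule_id == m & top$role == "cd_primary_rim", ]
      seco <- cc[top$molecule_id == m & top$role == "cd_secondary_rim", ]
      ctr <- (colMeans(prim) + colMeans(seco)) / 2
      ax <- colMeans(seco) - colMeans(prim)
      ax <- ax / sqrt(sum(ax^2))
      for (r in seq_len(n_res)) {
        ca <- cc[top$residue_index == r & top$atom_name == "CA", ]
        v <- ca - ctr
        axial <- sum(v * ax)
        radial <- sqrt(sum(v^2) - axial^2)
        if (radial < 0.6 && abs(axial) < 0.5)
          oracle[[length(oracle) + 1L]] <- c(m, r)
      }
    }
    got <- if (nrow(ev)) unname(as.matrix(ev[, c("cd_id", "residue_index")]))
           else matrix(0, 0, 2)
    want <- if (length(oracle)) do.call(rbind, oracle) else matrix(0, 0, 2)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("inclusion events are monotone in both thresholds", {
  tr <- make_inclusion_system(include_res = 3)
  e_small <- detect_inclusions(tr, radial_max = 0.3, axial_max = 0.25)
  e_big <- detect_inclusions(tr, radial_max = 0.6, axial_max = 0.5)
  key <- function(e) paste(e$cd_id, e$residue_index)
  expect_true(all(key(e_small) %in% key(e_big)))
})

test_that("planted inclusion frequency is recovered exactly", {
  # residue 5's CA sits in the cavity in 30 of 100 frames
  base <- make_inclusion_system(n_res = 8, include_res = 5,
                                cd_center = c(2, 2, 2))
  top <- base$topology
  inside <- base$frames[[1]]$coords
  outside <- inside
  np <- sum(startsWith(top$role, "protein_backbone"))
  outside[seq_len(np), 1] <- outside[seq_len(np), 1] - 2.5
  frames <- lapply(1:100, function(k) {
    cdx_frame(if (k <= 30) inside else outside, c(6, 6, 6), time = k - 1)
  })
  tr <- cdx_trajectory(top, frames)
  ev <- detect_inclusions(tr)
  fr <- inclusion_frequency(ev, n_frames = 100, residue_range = 1:8)
  expect_equal(fr$frequency[fr$residue_index == 5], 0.30)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1))
  # no events -> all zeros
  fr0 <- inclusion_frequency(detect_inclusions(tr, 0, 0),
                             n_frames = 100, residue_range = 1:8)
  expect_true(all(fr0$frequency == 0))
})

test_that("aggregate sizes: isolated, chained, and brute-force components", {
  box <- c(30, 30, 30)
  mk_frame <- function(centers) {
    tops <- lapply(seq_len(nrow(centers)), function(i) cd_topology())
    top <- do.call(rbind, tops)
    top$residue_index <- rep(seq_len(7 * nrow(centers)), each = 4)
    top <- assign_roles(cdx_topology(top$atom_name, top$residue_name,
                                     top$residue_index))
    cc <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      cd_coords(centers[i, ], c(0, 0, 1))))
    list(top = top, fr = cdx_frame(cc, box, periodic = rep(FALSE, 3)))
  }
  # 11 CDs far apart
  far <- mk_frame(cbind(seq(2, 22, by = 2), 5, 5))
  ag <- cd_aggregate_sizes(far$top, far$fr)
  expect_equal(sort(ag$sizes), rep(1L, 11))
  expect_equal(ag$mean_size, 1.0)
  # 11 CDs in one contact chain (ring diameter 1 nm; 1.2 nm spacing
  # leaves 0.2 nm < 0.35 nm between neighbouring rings)
  chain <- mk_frame(cbind(2 + 1.2 * (0:10), 5, 5))
  agc <- cd_aggregate_sizes(chain$top, chain$fr)
  expect_equal(agc$sizes, 11L)
  expect_equal(agc$mean_size, 11.0)
  # random configurations vs brute-force union-find
  set.seed(23)
  for (rep in 1:10) {
    centers <- cbind(runif(8, 2, 10), runif(8, 2, 10), runif(8, 2, 10))
    sys <- mk_frame(centers)
    ag <- cd_aggregate_sizes(sys$top, sys$fr)
    # oracle: union-find over the exact pairwise contact matrix
    parent <- 1:8
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    idx <- lapply(1:8, function(m)
      which(sys$top$molecule_id == m))
    for (i in 1:7) for (j in (i + 1):8) {
      dmin <- sqrt(min(vapply(idx[[i]], function(a)
        min(rowSums(sweep(sys$fr$coords[idx[[j]], , drop = FALSE], 2,
                          sys$fr$coords[a, ])^2)), numeric(1))))
      if (dmin < 0.35) parent[find(i)] <- find(j)
    }
    roots <- vapply(1:8, find, integer(1))
    oracle_sizes <- sort(as.integer(table(roots)))
    expect_equal(sort(ag$sizes), oracle_sizes)
    expect_equal(sum(ag$sizes), 8L)  # partition property
  }
})

test_that("hydration-layer partition: null is 1, planted 3x enrichment recovered", {
  box <- c(12, 12, 12)
  shell_w <- 0.8
  h <- make_ideal_helix(20, seed = 2, box = box)
  hc <- sweep(h$frame$coords, 2, colMeans(h$frame$coords))
  hc <- sweep(hc, 2, c(6, 6, 6), FUN = "+")
  prot_heavy <- hc  # all backbone atoms are heavy
  in_shell <- function(p) {
    min(rowSums(sweep(prot_heavy, 2, p)^2)) < shell_w^2
  }
  n_cd <- 40; n_w <- 400; n_fr <- 60
  # accept/reject so CD *concentration* is `ratio`x higher in the shell
  build <- function(ratio, seed) {
    set.seed(seed)
    top <- h$topology
    for (i in seq_len(n_cd)) {
      cd <- cd_topology()
      off <- max(top$residue_index)
      top <- cdx_topology(c(top$atom_name, cd$atom_name),
                          c(top$residue_name, cd$residue_name),
                          c(top$residue_index, cd$residue_index + off))
    }
    wt <- cdx_topology(rep("OW", n_w), rep("SOL", n_w), seq_len(n_w))
    top <- cdx_topology(c(top$atom_name, wt$atom_name),
                        c(top$residue_name, wt$residue_name),
                        c(top$residue_index, wt$residue_index +
                            max(top$residue_index)))
    top <- assign_roles(top)
    frames <- lapply(seq_len(n_fr), function(k) {
      cc <- hc
      for (i in seq_len(n_cd)) {
        repeat {
          ctr <- runif(3, 0.8, box[1] - 0.8)
          ax <- rand_unit()
          com <- ctr + 0.05 * ax  # heavy-atom COM of the pseudo-CD
          p_acc <- if (in_shell(com)) 1 else 1 / ratio
          if (runif(1) < p_acc) break
        }
        cc <- rbind(cc, cd_coords(ctr, ax))
      }
      # waters sample the same region as the CD centres, so the two
      # species see identical shell/bulk volumes under the null
      wat <- matrix(runif(3 * n_w, 0.8, box[1] - 0.8), n_w, 3)
      cdx_frame(rbind(cc, wat), box, time = k - 1,
                periodic = rep(FALSE, 3))
    })
    cdx_trajectory(top, frames)
  }
  k_null <- hydration_layer_partition(build(1, 5), shell_width = shell_w)$K
  expect_lt(abs(k_null - 1), 0.5)
  k3 <- hydration_layer_partition(build(3, 6), shell_width = shell_w)$K
  expect_lt(abs(k3 - 3) / 3, 0.15)
})
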