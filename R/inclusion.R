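# Host-guest geometry: detection of protein residues included in
# cyclodextrin cavities, per-residue inclusion frequencies, CD
# self-aggregation, and a hydration-layer partition coefficient.

#' Cavity geometry of one cyclodextrin
#'
#' Centroid (midpoint of the two rim centroids), axis (unit vector from
#' the primary- to the secondary-rim centroid) and mean ring radius
#' (mean distance of the rim atoms from the axis line).
#'
#' @param topology role-assigned [cdx_topology()].
#' @param frame a [cdx_frame()].
#' @param mol_id molecule id of the cyclodextrin.
#' @return list(centroid, axis, radius), class `cdx_cavity_geometry`.
#' @export
cavity_geometry <- function(topology, frame, mol_id) {
  ax <- cd_axes_frame(topology, frame, mol_id)
  centroid <- ax[1, c("cx", "cy", "cz")]
  axis <- ax[1, c("ax", "ay", "az")]
  rim <- which(topology$molecule_id == mol_id &
                 topology$role %in% c("cd_primary_rim", "cd_secondary_rim"))
  rel <- sweep(frame$coords[rim, , drop = FALSE], 2, centroid)
  axial <- as.numeric(rel %*% axis)
  radial <- sqrt(rowSums((rel - axial %o% axis)^2))
  structure(list(centroid = unname(centroid), axis = unname(axis),
                 radius = mean(radial)),
            class = "cdx_cavity_geometry")
}

# Representative point per protein residue: centroid of side-chain heavy
# atoms; CA when the residue has no side-chain heavy atoms (e.g. GLY or
# backbone-only models).
residue_representatives <- function(topology, frame) {
  prot <- select_atoms(topology, "protein")
  res <- sort(unique(topology$residue_index[prot]))
  pts <- matrix(NA_real_, length(res), 3)
  bb_names <- c("N", "CA", "C", "O", "H", "HA", "HN")
  for (k in seq_along(res)) {
    ii <- prot[topology$residue_index[prot] == res[k]]
    sc <- ii[!(topology$atom_name[ii] %in% bb_names) &
               topology$element[ii] != "H"]
    if (!length(sc)) sc <- ii[topology$atom_name[ii] == "CA"]
    if (!length(sc)) sc <- ii
    pts[k, ] <- colMeans(frame$coords[sc, , drop = FALSE])
  }
  list(residue_index = res, points = pts)
}

#' Detect residue inclusion in cyclodextrin cavities
#'
#' A residue is included when its representative point (side-chain
#' heavy-atom centroid; CA for glycine) lies inside the cavity cylinder
#' of any CD: radial offset from the cavity axis below `radial_max` and
#' absolute axial offset from the cavity centre below `axial_max`. A
#' transparent one-point cylinder test, monotone in both thresholds.
#'
#' @param trajectory a [cdx_trajectory()] with protein and CD roles.
#' @param radial_max cylinder radius threshold in nm (default 0.45).
#' @param axial_max half-height threshold in nm (default 0.40).
#' @return data.frame of events: `frame_index`, `cd_id`,
#'   `residue_index`, `radial_offset`, `axial_offset`.
#' @export
detect_inclusions <- function(trajectory, radial_max = 0.45,
                              axial_max = 0.40) {
  top <- trajectory$topology
  mols <- group_molecules(top, "cd")
  out <- list()
  for (fi in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[fi]]
    rep_pts <- residue_representatives(top, fr)
    axes <- cd_axes_frame(top, fr, mols)
    for (k in seq_len(nrow(axes))) {
      ctr <- axes[k, c("cx", "cy", "cz")]
      ax <- axes[k, c("ax", "ay", "az")]
      rel <- sweep(rep_pts$points, 2, ctr)
      axial <- as.numeric(rel %*% ax)
      radial <- sqrt(pmax(0, rowSums(rel^2) - axial^2))
      hit <- which(radial < radial_max & abs(axial) < axial_max)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          frame_index = fi, cd_id = unname(axes[k, "mol"]),
          residue_index = rep_pts$residue_index[hit],
          radial_offset = unname(radial[hit]),
          axial_offset = unname(axial[hit]), row.names = NULL)
    }
  }
  if (!length(out))
    return(data.frame(frame_index = integer(0), cd_id = integer(0),
                      residue_index = integer(0), radial_offset = numeric(0),
                      axial_offset = numeric(0)))
  do.call(rbind, out)
}

#' Per-residue inclusion frequency
#'
#' Fraction of frames in which each residue has at least one inclusion
#' event; several CDs including the same residue in one frame count
#' once, so frequencies are bounded by 1.
#'
#' @param events event table from [detect_inclusions()].
#' @param n_frames total number of frames analysed.
#' @param residue_range integer residue indices to report (defaults to
#'   the range seen in the events).
#' @return data.frame `residue_index`, `frequency`, attr `n_frames`.
#' @export
inclusion_frequency <- function(events, n_frames, residue_range = NULL) {
  if (is.null(residue_range)) {
    residue_range <- if (nrow(events)) seq(min(events$residue_index),
                                           max(events$residue_index))
                     else integer(0)
  }
  freq <- vapply(residue_range, function(r) {
    length(unique(events$frame_index[events$residue_index == r])) / n_frames
  }, numeric(1))
  out <- data.frame(residue_index = residue_range, frequency = freq)
  attr(out, "n_frames") <- n_frames
  out
}

#' Cyclodextrin self-aggregation sizes
#'
#' Two CDs are in contact when any heavy-atom pair is closer than the
#' cutoff (minimum-image on the periodic axes). Aggregates are the
#' connected components of the contact graph; the mean size is the
#' number of CDs divided by the number of aggregates.
#'
#' @param topology,frame the system and one frame.
#' @param contact_cutoff contact distance in nm (default 0.35).
#' @return list(sizes, mean_size, membership).
#' @export
cd_aggregate_sizes <- function(topology, frame, contact_cutoff = 0.35) {
  mols <- group_molecules(topology, "cd")
  n <- length(mols)
  if (!n) stop("no cyclodextrin molecules in topology")
  idx <- lapply(mols, function(m)
    which(topology$molecule_id == m & topology$element != "H"))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- min_cross_distance(frame$coords[idx[[i]], , drop = FALSE],
                            frame$coords[idx[[j]], , drop = FALSE],
                            frame$box, frame$periodic)
    adj[i, j] <- adj[j, i] <- d < contact_cutoff
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  list(sizes = sizes, mean_size = n / comp$no,
       membership = stats::setNames(as.integer(comp$membership), mols))
}

#' Hydration-layer partition coefficient of cyclodextrins
#'
#' K = (n_CD_shell / n_water_shell) / (n_CD_bulk / n_water_bulk), with
#' counts pooled over frames (pooling keeps the ratio defined and
#' stable when single frames hold few shell molecules; the per-frame
#' series is returned for diagnostics). The shell is the region within
#' `shell_width`
#' of any protein heavy atom; a molecule is in the shell when its
#' heavy-atom centre of mass lies in that region. Using the same point
#' criterion for both species keeps the statistic unbiased under the
#' null (uniformly placed CDs and waters give K = 1 regardless of
#' molecular size). K > 1 reads as preferential inclusion of CDs in
#' the hydration layer.
#' Without waters the ratio falls back to volume-based concentrations,
#' with the shell volume estimated by seeded Monte-Carlo integration.
#'
#' @param trajectory a [cdx_trajectory()] with a protein.
#' @param shell_width shell thickness in nm (default 0.6).
#' @param mc_points Monte-Carlo points for the volume fallback.
#' @param seed seed for the volume fallback.
#' @return list(K, per_frame, n_frames_used).
#' @export
hydration_layer_partition <- function(trajectory, shell_width = 0.6,
                                      mc_points = 1e4, seed = 1) {
  top <- trajectory$topology
  prot <- select_atoms(top, "protein", heavy_only = TRUE)
  if (!length(prot)) stop("no protein in topology")
  cd_mols <- group_molecules(top, "cd")
  wat_mols <- group_molecules(top, "water")
  has_water <- length(wat_mols) > 0
  mol_min_dist <- function(fr, mols) {
    P <- fr$coords[prot, , drop = FALSE]
    vapply(mols, function(m) {
      com <- molecule_com(top, fr, m)
      d <- min_image_delta(sweep(P, 2, com), fr$box, fr$periodic)
      sqrt(min(rowSums(d^2)))
    }, numeric(1))
  }
  counts <- lapply(seq_along(trajectory$frames), function(fi) {
    fr <- trajectory$frames[[fi]]
    dcd <- mol_min_dist(fr, cd_mols)
    cs <- sum(dcd < shell_width); cb <- length(dcd) - cs
    if (has_water) {
      dw <- mol_min_dist(fr, wat_mols)
      ws <- sum(dw < shell_width); wb <- length(dw) - ws
    } else {
      vols <- shell_volume_mc(fr, top, prot, shell_width, mc_points,
                              seed + fi)
      ws <- vols$shell; wb <- vols$bulk
    }
    kf <- if (cb > 0 && ws > 0 && wb > 0) (cs / ws) / (cb / wb) else NA_real_
    c(cs = cs, cb = cb, ws = ws, wb = wb, k = kf)
  })
  tot <- Reduce(`+`, lapply(counts, function(x) x[1:4]))
  if (tot[["ws"]] == 0 || tot[["wb"]] == 0)
    stop("shell or bulk is empty over the whole trajectory")
  if (tot[["cb"]] == 0) stop("no cyclodextrin ever found in the bulk")
  K <- (tot[["cs"]] / tot[["ws"]]) / (tot[["cb"]] / tot[["wb"]])
  list(K = K, per_frame = vapply(counts, function(x) x[["k"]], numeric(1)),
       n_frames_used = length(counts))
}

# Monte-Carlo estimate of the shell volume within the liquid region.
shell_volume_mc <- function(frame, topology, prot_idx, shell_width,
                            mc_points, seed) {
  box <- frame$box
  z_top <- max(frame$coords[, 3])
  pts <- with_seed(seed, cbind(runif(mc_points, 0, box[1]),
                               runif(mc_points, 0, box[2]),
                               runif(mc_points, 0, z_top)))
  P <- frame$coords[prot_idx, , drop = FALSE]
  in_shell <- vapply(seq_len(mc_points), function(i) {
    d <- sweep(P, 2, pts[i, ])
    d <- min_image_delta(d, box, frame$periodic)
    min(rowSums(d^2)) < shell_width^2
  }, logical(1))
  vtot <- box[1] * box[2] * z_top
  vs <- vtot * mean(in_shell)
  list(shell = vs, bulk = vtot - vs)
}
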