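# Interface location, normalized density profiles along the interface
# normal (+z), cyclodextrin rim-orientation profiles, and
# proximity-count convergence series.

#' Locate the interface position per frame
#'
#' For an air-water interface the water-density profile of each frame is
#' scanned from the vacuum side: the interface is the upper edge of the
#' highest bin whose density still reaches 50% of the bulk plateau
#' (plateau = median density of occupied bins). For an ice-water
#' interface the position is the maximum z of the explicitly frozen
#' group.
#'
#' @param trajectory a [cdx_trajectory()].
#' @param water_group selection for the liquid (default `"water"`).
#' @param kind `"air"` or `"ice"`.
#' @param bin_width histogram bin width in nm.
#' @return numeric vector, one interface z (nm) per frame.
#' @export
locate_interface <- function(trajectory, water_group = "water",
                             kind = c("air", "ice"), bin_width = 0.1) {
  kind <- match.arg(kind)
  top <- trajectory$topology
  if (kind == "ice") {
    idx <- select_atoms(top, "frozen")
    if (!length(idx)) stop("kind = 'ice' requires a frozen-group tag in the topology")
    return(vapply(trajectory$frames,
                  function(fr) max(fr$coords[idx, 3]), numeric(1)))
  }
  idx <- select_atoms(top, water_group, heavy_only = TRUE)
  if (!length(idx)) stop("water group is empty")
  vapply(trajectory$frames, function(fr) {
    z <- fr$coords[idx, 3]
    if (length(z) < 20)
      stop("too few water atoms to detect a density plateau; add more frames/waters")
    edges <- seq(0, fr$box[3] + bin_width, by = bin_width)
    counts <- graphics::hist(pmin(z, fr$box[3]), breaks = edges,
                             plot = FALSE)$counts
    occ <- counts[counts > 0]
    plateau <- stats::median(occ)
    if (plateau < 2)
      stop("no density plateau detectable; too few waters per bin")
    above <- which(counts >= 0.5 * plateau)
    edges[max(above) + 1L]
  }, numeric(1))
}

#' Normalized number-density profile along z
#'
#' Histograms molecular (heavy-atom) centres of mass along z, averages
#' over frames, divides by bin volume and finally by the mean density
#' over the designated liquid region, so bulk reads 1 and surface
#' enrichment reads directly as values above 1.
#'
#' @param trajectory a [cdx_trajectory()].
#' @param group molecule selection (`"cd"`, `"protein"`, `"water"`, or
#'   atom indices whose molecules are used).
#' @param n_bins number of z bins over `[0, Lz]` (>= 10).
#' @param liquid_region length-2 z range (nm) used for normalization;
#'   default the region below the first frame's located interface.
#' @return object of class `cdx_density_profile`: list with
#'   `bin_edges`, `bin_centers`, `density` (normalized), `counts`
#'   (summed raw counts), `group`, `n_frames`, `liquid_region`.
#' @export
density_profile <- function(trajectory, group, n_bins = 120,
                            liquid_region = NULL) {
  if (n_bins < 10) stop("n_bins must be >= 10")
  top <- trajectory$topology
  mols <- group_molecules(top, group)
  if (!length(mols)) stop("empty group")
  box <- trajectory$frames[[1L]]$box
  edges <- seq(0, box[3], length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  for (fr in trajectory$frames) {
    z <- molecule_com_z(top, fr, mols)
    z <- z %% box[3]
    counts <- counts + graphics::hist(z, breaks = edges, plot = FALSE)$counts
  }
  nf <- n_frames(trajectory)
  binw <- diff(edges)[1]
  dens <- counts / (nf * box[1] * box[2] * binw)   # molecules / nm^3
  if (is.null(liquid_region)) {
    z0 <- locate_interface(trajectory, kind = "air")[1L]
    liquid_region <- c(0, z0)
  }
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  in_liq <- centers >= liquid_region[1] & centers <= liquid_region[2]
  bulk <- mean(dens[in_liq])
  if (!is.finite(bulk) || bulk <= 0) stop("liquid region contains no density")
  structure(list(bin_edges = edges, bin_centers = centers,
                 density = dens / bulk, counts = counts,
                 group = if (is.character(group)) group else "custom",
                 n_frames = nf, liquid_region = liquid_region),
            class = "cdx_density_profile")
}

#' @export
print.cdx_density_profile <- function(x, ...) {
  cat(sprintf("cdx_density_profile of '%s': %d bins, %d frames, peak %.2f at z = %.2f nm\n",
              x$group, length(x$density), x$n_frames, max(x$density),
              x$bin_centers[which.max(x$density)]))
  invisible(x)
}

# Cavity axis (primary -> secondary rim unit vector) and centre for each
# CD molecule in one frame; rows ordered by molecule id.
cd_axes_frame <- function(topology, frame, mol_ids = NULL) {
  if (is.null(mol_ids)) mol_ids <- group_molecules(topology, "cd")
  out <- matrix(NA_real_, length(mol_ids), 7,
                dimnames = list(NULL, c("mol", "cx", "cy", "cz",
                                        "ax", "ay", "az")))
  for (k in seq_along(mol_ids)) {
    m <- mol_ids[k]
    ip <- which(topology$molecule_id == m & topology$role == "cd_primary_rim")
    is <- which(topology$molecule_id == m & topology$role == "cd_secondary_rim")
    if (length(ip) != 7L || length(is) != 14L)
      stop("cyclodextrin molecule ", m, " is missing rim atoms (",
           length(ip), " primary, ", length(is), " secondary)")
    cp <- colMeans(frame$coords[ip, , drop = FALSE])
    cs <- colMeans(frame$coords[is, , drop = FALSE])
    ax <- cs - cp
    ax <- ax / sqrt(sum(ax^2))
    out[k, ] <- c(m, (cp + cs) / 2, ax)
  }
  out
}

#' Rim-orientation profile of cyclodextrins along z
#'
#' For every cyclodextrin in every frame, cos(theta) is the dot product
#' of the cavity axis (primary-rim centroid -> secondary-rim centroid
#' unit vector) with +z; values are binned by the cavity centre's z.
#' cos(theta) near +1 means the secondary rim, hence the cavity opening,
#' points toward the vacuum.
#'
#' @param trajectory a [cdx_trajectory()] with CD role tags.
#' @param n_bins number of z bins over `[0, Lz]`.
#' @return object of class `cdx_orientation_profile`: `bin_edges`,
#'   `bin_centers`, `mean_cos_theta` (NA where a bin holds no CD),
#'   `counts`, `global_mean`.
#' @export
rim_orientation_profile <- function(trajectory, n_bins = 60) {
  top <- trajectory$topology
  if (!any(top$role == "cd_primary_rim"))
    stop("topology has no cyclodextrin role tags; run assign_roles()")
  box <- trajectory$frames[[1L]]$box
  edges <- seq(0, box[3], length.out = n_bins + 1L)
  sums <- numeric(n_bins); cnts <- numeric(n_bins)
  allcos <- numeric(0)
  for (fr in trajectory$frames) {
    ax <- cd_axes_frame(top, fr)
    ct <- ax[, "az"]
    zc <- ax[, "cz"] %% box[3]
    b <- pmin(pmax(findInterval(zc, edges, rightmost.closed = TRUE), 1L), n_bins)
    for (i in seq_along(b)) {
      sums[b[i]] <- sums[b[i]] + ct[i]
      cnts[b[i]] <- cnts[b[i]] + 1
    }
    allcos <- c(allcos, ct)
  }
  mct <- ifelse(cnts > 0, sums / cnts, NA_real_)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
                 mean_cos_theta = mct, counts = cnts,
                 global_mean = mean(allcos)),
            class = "cdx_orientation_profile")
}

#' Per-frame count of cyclodextrins near a reference surface
#'
#' Counts, frame by frame, the CD molecules whose minimum heavy-atom
#' distance to the reference group (protein or frozen ice surface) is
#' below the cutoff. The time series of these counts is the standard
#' convergence check for interfacial adsorption equilibria.
#'
#' @param trajectory a [cdx_trajectory()].
#' @param group counted molecules (default `"cd"`).
#' @param reference `"protein"`, `"frozen"`, or atom indices.
#' @param cutoff distance cutoff in nm (default 2.0).
#' @return integer vector of per-frame counts.
#' @export
proximity_count <- function(trajectory, group = "cd", reference = "protein",
                            cutoff = 2.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  top <- trajectory$topology
  ref_idx <- select_atoms(top, reference, heavy_only = TRUE)
  if (!length(ref_idx)) stop("reference group is empty")
  mols <- group_molecules(top, group)
  mol_idx <- lapply(mols, function(m)
    which(top$molecule_id == m & top$element != "H"))
  vapply(trajectory$frames, function(fr) {
    R <- fr$coords[ref_idx, , drop = FALSE]
    sum(vapply(mol_idx, function(ii) {
      A <- fr$coords[ii, , drop = FALSE]
      min_cross_distance(A, R, fr$box, fr$periodic) < cutoff
    }, logical(1)))
  }, numeric(1))
}
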