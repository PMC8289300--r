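# Collective variables monitored/biased in the enhanced-sampling runs:
# radius of gyration, alpha-helix content, protein-interface distance,
# and the distance-RMSD to a reference structure.

#' Radius of gyration
#'
#' sqrt( sum m_i |r_i - r_com|^2 / sum m_i ) over the selected atoms.
#'
#' @param frame a [cdx_frame()] or coordinate matrix.
#' @param topology the matching [cdx_topology()] (for masses/selection).
#' @param group selection understood by [select_atoms()]; default all.
#' @param mass_weighted use atomic masses (default) or unit weights.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, topology = NULL, group = NULL,
                               mass_weighted = TRUE) {
  X <- frame_coords(frame)
  idx <- if (is.null(group)) seq_len(nrow(X)) else select_atoms(topology, group)
  if (!length(idx)) stop("empty selection")
  w <- if (mass_weighted && !is.null(topology)) topology$mass[idx]
       else rep(1, length(idx))
  X <- X[idx, , drop = FALSE]
  com <- colSums(X * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(X, 2, com)^2)) / sum(w))
}

#' Build a distance-RMSD specification from a reference structure
#'
#' Selects the atom pairs whose *reference* distance lies strictly
#' between the two cutoffs; frames are then always scored on exactly
#' this pair list (the frame's own distances are never re-filtered).
#'
#' @param reference reference frame or coordinate matrix (the native
#'   structure's backbone).
#' @param topology optional topology; with `selection = "backbone"` the
#'   N/CA/C backbone atoms are used.
#' @param selection integer atom indices, or `"backbone"`.
#' @param lower,upper distance cutoffs in nm (defaults 0.1 and 3.0).
#' @return object of class `cdx_drmsd_spec` with the reference
#'   distances and pair list.
#' @export
drmsd_spec <- function(reference, topology = NULL, selection = NULL,
                       lower = 0.1, upper = 3.0) {
  if (lower >= upper) stop("lower cutoff must be < upper cutoff")
  X <- frame_coords(reference)
  idx <- resolve_backbone_selection(selection, topology, nrow(X))
  X <- X[idx, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  pairs <- which(upper.tri(D) & D > lower & D < upper, arr.ind = TRUE)
  if (!nrow(pairs)) stop("cutoffs exclude every atom pair")
  structure(list(selection = idx, i = pairs[, 1], j = pairs[, 2],
                 d_ref = D[pairs], lower = lower, upper = upper),
            class = "cdx_drmsd_spec")
}

resolve_backbone_selection <- function(selection, topology, n) {
  if (is.null(selection)) return(seq_len(n))
  if (identical(selection, "backbone")) {
    if (is.null(topology)) stop("selection = 'backbone' needs a topology")
    return(which(topology$role %in% c("protein_backbone_N",
                                      "protein_backbone_CA",
                                      "protein_backbone_C") |
                   (topology$atom_name == "O" &
                      topology$residue_name %in%
                        default_naming_scheme()$protein_residues)))
  }
  as.integer(selection)
}

#' Distance-RMSD to a reference structure
#'
#' sqrt( (1/P) * sum over the spec's pair list of
#' (d_frame(i,j) - d_ref(i,j))^2 ). Distances are plain (non-periodic)
#' Euclidean distances within each structure, so the value is invariant
#' under rigid motions and needs no superposition.
#'
#' @param frame frame or coordinate matrix matching the spec's atom set.
#' @param spec a [drmsd_spec()].
#' @return dRMSD in nm.
#' @export
drmsd <- function(frame, spec) {
  stopifnot(inherits(spec, "cdx_drmsd_spec"))
  X <- frame_coords(frame)[spec$selection, , drop = FALSE]
  d <- sqrt(rowSums((X[spec$i, , drop = FALSE] - X[spec$j, , drop = FALSE])^2))
  sqrt(mean((d - spec$d_ref)^2))
}

#' Alpha-helix content
#'
#' Sum over all windows of six consecutive residues of a rational
#' switching function of the window's backbone RMSD (after optimal
#' superposition) to the ideal helical template:
#' S(x) = (1 - x^p) / (1 - x^q) with x = RMSD/r0. S(0) = 1 and S
#' decays smoothly to 0, so the value is a continuous count in
#' [0, n_res - 5] of helical six-residue segments.
#'
#' @param frame frame or coordinate matrix.
#' @param topology role-assigned topology (N/CA/C needed per residue).
#' @param r0 switching scale in nm (default 0.08).
#' @param exponents numerator/denominator exponents (default 8, 12).
#' @return dimensionless helical-window count.
#' @export
alpha_helix_content <- function(frame, topology, r0 = 0.08,
                                exponents = c(8, 12)) {
  X <- frame_coords(frame)
  res <- sort(unique(topology$residue_index[startsWith(topology$role,
                                                       "protein_backbone")]))
  if (length(res) < 6) stop("need at least 6 protein residues with backbone")
  template <- helix_backbone_coords(6)
  total <- 0
  n_win <- 0L
  for (w in seq_len(length(res) - 5L)) {
    rr <- res[w:(w + 5L)]
    if (any(diff(rr) != 1L)) next
    idx <- unlist(lapply(rr, function(r) {
      c(which(topology$residue_index == r & topology$role == "protein_backbone_N"),
        which(topology$residue_index == r & topology$role == "protein_backbone_CA"),
        which(topology$residue_index == r & topology$role == "protein_backbone_C"))
    }))
    if (length(idx) != 18L) {
      warning("window at residue ", rr[1], " missing backbone atoms; skipped")
      next
    }
    r <- fit_rmsd(X[idx, , drop = FALSE], template)
    total <- total + switching_function(r / r0, exponents[1], exponents[2])
    n_win <- n_win + 1L
  }
  if (n_win == 0L) stop("no complete six-residue backbone window found")
  total
}

switching_function <- function(x, p = 8, q = 12) {
  # continuous at x = 1 where the ratio is p/q in the limit
  near1 <- abs(x - 1) < 1e-8
  out <- numeric(length(x))
  out[near1] <- p / q
  xn <- x[!near1]
  out[!near1] <- (1 - xn^p) / (1 - xn^q)
  out
}

#' Protein-interface distance
#'
#' Absolute distance along z between the protein centre of mass and the
#' interface position `z0` (see [locate_interface()]).
#'
#' @param frame a [cdx_frame()].
#' @param topology role-assigned topology.
#' @param z0 interface z position (nm).
#' @param group protein selection (default `"protein"`).
#' @return |z_com - z0| in nm.
#' @export
interface_distance <- function(frame, topology, z0, group = "protein") {
  idx <- select_atoms(topology, group, heavy_only = TRUE)
  if (!length(idx)) stop("empty protein selection")
  w <- topology$mass[idx]
  zc <- sum(frame$coords[idx, 3] * w) / sum(w)
  abs(zc - z0)
}

#' Evaluate all collective variables along a trajectory
#'
#' @param trajectory a [cdx_trajectory()] with a protein.
#' @param drmsd_ref optional [drmsd_spec()]; dRMSD column is NA without it.
#' @param interface_kind `"air"` or `"ice"`, passed to
#'   [locate_interface()]; NA interface distance if no water present.
#' @return data.frame of class `cdx_cv_series`: time, rg, alpha,
#'   d_interface, drmsd, weight (1 by default).
#' @export
cv_series <- function(trajectory, drmsd_ref = NULL, interface_kind = "air") {
  top <- trajectory$topology
  has_water <- any(top$role == "water")
  z0 <- if (has_water) locate_interface(trajectory, kind = interface_kind) else NULL
  rows <- lapply(seq_along(trajectory$frames), function(i) {
    fr <- trajectory$frames[[i]]
    data.frame(time = fr$time,
               rg = radius_of_gyration(fr, top, "protein"),
               alpha = alpha_helix_content(fr, top),
               d_interface = if (has_water)
                 interface_distance(fr, top, z0[i]) else NA_real_,
               drmsd = if (!is.null(drmsd_ref)) drmsd(fr, drmsd_ref) else NA_real_,
               weight = 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cdx_cv_series", "data.frame")
  out
}
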