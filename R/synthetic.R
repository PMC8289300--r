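# Synthetic fixtures with planted, analytically known structure: ideal
# helices, pseudo-cyclodextrins, slab trajectories, RMSD-controlled
# conformational ensembles, and a 1-D well-tempered metadynamics toy
# sampler. Every generator is a pure function of (spec, seed).

HELIX_RISE <- 0.15      # nm per residue
HELIX_TWIST <- 100 * pi / 180

# Canonical backbone geometry of an ideal alpha helix; also the template
# of the alpha-helix-content collective variable.
helix_backbone_coords <- function(n_res) {
  i <- seq_len(n_res) - 1L
  phi <- i * HELIX_TWIST
  z <- i * HELIX_RISE
  ca <- cbind(0.23 * cos(phi), 0.23 * sin(phi), z)
  nn <- cbind(0.16 * cos(phi - 0.45), 0.16 * sin(phi - 0.45), z - 0.05)
  cc <- cbind(0.19 * cos(phi + 0.50), 0.19 * sin(phi + 0.50), z + 0.05)
  coords <- matrix(0, 3 * n_res, 3)
  coords[seq(1, 3 * n_res, 3), ] <- nn
  coords[seq(2, 3 * n_res, 3), ] <- ca
  coords[seq(3, 3 * n_res, 3), ] <- cc
  coords
}

#' Generate an ideal alpha-helical backbone
#'
#' Places N, CA, C atoms of `n_res` residues on ideal helix geometry
#' (rise 0.15 nm per residue, 100 degrees twist) and applies a seeded
#' random rigid rotation and translation, so downstream superposition is
#' actually exercised.
#'
#' @param n_res number of residues (>= 6; shorter chains admit no
#'   six-residue helical window).
#' @param seed integer seed for the rigid placement.
#' @param box box lengths, default generous cube.
#' @return list(topology, frame), roles assigned.
#' @export
make_ideal_helix <- function(n_res, seed = 1, box = c(8, 8, 8)) {
  if (n_res < 6) stop("n_res must be >= 6")
  coords <- helix_backbone_coords(n_res)
  coords <- with_seed(seed, {
    rot <- random_rotation_matrix()
    shift <- runif(3, 2, 4)
    sweep(coords %*% t(rot), 2, shift, FUN = "+")
  })
  top <- cdx_topology(atom_name = rep(c("N", "CA", "C"), n_res),
                      residue_name = rep("ALA", 3 * n_res),
                      residue_index = rep(seq_len(n_res), each = 3))
  top <- assign_roles(top)
  list(topology = top, frame = cdx_frame(coords, box, time = 0))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

CD_RING_RADIUS <- 0.5   # nm, stylised pseudo-cyclodextrin
CD_RIM_OFFSET <- 0.2    # nm along the cavity axis

#' Generate a stylised cyclodextrin molecule
#'
#' Seven glucose pseudo-units on a ring of radius 0.5 nm. Each unit has
#' a body atom C1 on the ring plane, the primary-rim atom C6 offset
#' -0.2 nm along the axis and the secondary-rim atoms C2/C3 offset
#' +0.2 nm, so a molecule carries 7 primary-rim and 14 secondary-rim
#' atoms. Real beta-cyclodextrin dimensions are not reproduced; all
#' analysis thresholds are configurable, so a stylised torus suffices.
#'
#' @param center cavity centroid (nm).
#' @param axis cavity axis unit vector, pointing primary -> secondary rim.
#' @param box box lengths.
#' @return list(topology, frame), roles assigned.
#' @export
make_cd_molecule <- function(center = c(0, 0, 0), axis = c(0, 0, 1),
                             box = c(6, 6, 6)) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("axis must be a unit vector")
  coords <- cd_coords(center, axis)
  top <- cd_topology()
  list(topology = assign_roles(top), frame = cdx_frame(coords, box, time = 0))
}

cd_topology <- function() {
  cdx_topology(atom_name = rep(c("C1", "C2", "C3", "C6"), 7),
               residue_name = rep("GLC", 28),
               residue_index = rep(seq_len(7), each = 4))
}

cd_coords <- function(center, axis) {
  uv <- orthonormal_basis(axis)
  theta <- 2 * pi * (seq_len(7) - 1L) / 7
  ring <- function(ang, axial) {
    sweep(CD_RING_RADIUS * (cos(ang) %o% uv$u + sin(ang) %o% uv$v) +
            axial * rep(1, length(ang)) %o% axis, 2, center, FUN = "+")
  }
  coords <- matrix(0, 28, 3)
  coords[seq(1, 28, 4), ] <- ring(theta, 0)                    # C1 body
  coords[seq(2, 28, 4), ] <- ring(theta - 0.12, CD_RIM_OFFSET) # C2 secondary
  coords[seq(3, 28, 4), ] <- ring(theta + 0.12, CD_RIM_OFFSET) # C3 secondary
  coords[seq(4, 28, 4), ] <- ring(theta, -CD_RIM_OFFSET)       # C6 primary
  coords
}

orthonormal_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

#' Specify a planted cyclodextrin z-distribution
#'
#' @param kind `"uniform"` over the liquid region, `"surface_peaked"`
#'   (truncated Gaussian at `peak_z`), or `"bulk_only"` (uniform but
#'   excluding the top 1 nm below the surface).
#' @param n_molecules cyclodextrins per frame.
#' @param peak_z,peak_width Gaussian centre and width (nm) for
#'   `surface_peaked`.
#' @export
profile_spec <- function(kind = c("uniform", "surface_peaked", "bulk_only"),
                         n_molecules = 10, peak_z = NULL, peak_width = 0.3) {
  kind <- match.arg(kind)
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (kind == "surface_peaked") {
    if (is.null(peak_z)) stop("surface_peaked requires peak_z")
    if (peak_width <= 0) stop("peak_width must be > 0")
  }
  structure(list(kind = kind, n_molecules = as.integer(n_molecules),
                 peak_z = peak_z, peak_width = peak_width),
            class = "cdx_profile_spec")
}

#' Specify a planted rim-orientation distribution
#'
#' Orientation is the cosine of the angle between the cavity axis
#' (primary -> secondary rim) and +z.
#'
#' @param kind `"fixed"` (all axes along `axis`), `"isotropic"`, or
#'   `"mean_cos"` (exponentially tilted cos-theta density with the given
#'   mean, the 1-D analogue of a Langevin/von Mises-Fisher alignment).
#' @param mean_cos target mean cosine in (-1, 1) for `"mean_cos"`.
#' @param axis fixed axis for `"fixed"`.
#' @export
orientation_spec <- function(kind = c("isotropic", "fixed", "mean_cos"),
                             mean_cos = NULL, axis = c(0, 0, 1)) {
  kind <- match.arg(kind)
  if (kind == "mean_cos") {
    if (is.null(mean_cos) || abs(mean_cos) >= 1)
      stop("mean_cos must be given, in (-1, 1)")
  }
  structure(list(kind = kind, mean_cos = mean_cos, axis = axis),
            class = "cdx_orientation_spec")
}

# Solve coth(k) - 1/k = m for the tilt parameter of p(c) ~ exp(k c).
langevin_kappa <- function(m) {
  if (abs(m) < 1e-12) return(0)
  f <- function(k) 1 / tanh(k) - 1 / k - m
  uniroot(f, c(sign(m) * 1e-8, sign(m) * 1e4), tol = 1e-12)$root
}

sample_tilted_cos <- function(n, kappa) {
  if (abs(kappa) < 1e-12) return(runif(n, -1, 1))
  u <- runif(n)
  log(u * (exp(kappa) - exp(-kappa)) + exp(-kappa)) / kappa
}

#' Generate a slab trajectory with planted structure
#'
#' Emulates the geometry of slab simulations: a liquid region at the
#' bottom of the box, vacuum above (and optionally a frozen ice layer
#' below the liquid). Cyclodextrin centres are drawn i.i.d. per frame
#' from the planted z-distribution, cavity axes from the planted
#' orientation distribution; placeholder single-site waters fill the
#' liquid region; an optional static helical protein can be embedded.
#'
#' @param n_frames number of frames.
#' @param profile a [profile_spec()].
#' @param orientation an [orientation_spec()].
#' @param box box lengths (nm); `box[3]` must exceed the liquid top by
#'   at least 1 nm of vacuum.
#' @param liquid_depth thickness of the liquid region (nm).
#' @param n_water placeholder waters per frame (uniform in the liquid).
#' @param protein optional `list(n_res=, center=)` for a static helix.
#' @param ice_depth thickness of a frozen slab below the liquid (nm);
#'   0 disables it. Frozen atoms carry the explicit `frozen` tag.
#' @param seed integer seed; the trajectory is a pure function of
#'   arguments and seed.
#' @return a [cdx_trajectory()] with roles assigned.
#' @export
make_slab_trajectory <- function(n_frames, profile, orientation,
                                 box = c(6, 6, 12), liquid_depth = 6,
                                 n_water = 200, protein = NULL,
                                 ice_depth = 0, seed = 1) {
  stopifnot(inherits(profile, "cdx_profile_spec"),
            inherits(orientation, "cdx_orientation_spec"))
  z_lo <- ice_depth
  z_hi <- ice_depth + liquid_depth
  if (box[3] < z_hi + 1) stop("box Lz must exceed liquid top + 1 nm vacuum")
  if (profile$kind == "surface_peaked" &&
      (profile$peak_z <= z_lo || profile$peak_z >= z_hi))
    stop("planted peak_z lies outside the liquid region")

  ncd <- profile$n_molecules
  tops <- list()
  if (!is.null(protein)) {
    ph <- make_ideal_helix(protein$n_res, seed = seed)
    pc <- sweep(ph$frame$coords, 2, colMeans(ph$frame$coords))
    pc <- sweep(pc, 2, protein$center, FUN = "+")
    tops$protein <- ph$topology
  }
  tops$cd <- do.call(rbind, replicate(ncd, cd_topology(), simplify = FALSE))
  tops$wat <- cdx_topology(rep("OW", n_water), rep("SOL", n_water),
                           seq_len(n_water))
  n_ice <- 0L
  if (ice_depth > 0) {
    gx <- seq(0.2, box[1] - 0.2, by = 0.4)
    gy <- seq(0.2, box[2] - 0.2, by = 0.4)
    gz <- rev(seq(ice_depth, 0.1, by = -0.3))  # top layer exactly at ice_depth
    ice_xyz <- as.matrix(expand.grid(gx, gy, gz))
    n_ice <- nrow(ice_xyz)
    tops$ice <- cdx_topology(rep("OW", n_ice), rep("SOL", n_ice),
                             seq_len(n_ice), frozen = rep(TRUE, n_ice))
  }
  top <- do.call(rbind, lapply(unname(tops), as.data.frame))
  top$residue_index <- rebuild_residue_index_from_blocks(tops)
  top <- cdx_topology(top$atom_name, top$residue_name, top$residue_index,
                      frozen = top$frozen)
  top <- assign_roles(top)

  kappa <- if (orientation$kind == "mean_cos")
    langevin_kappa(orientation$mean_cos) else NA_real_

  frames <- with_seed(seed + 1L, lapply(seq_len(n_frames), function(k) {
    blocks <- list()
    if (!is.null(protein)) blocks$protein <- pc
    zcd <- draw_planted_z(profile, ncd, z_lo, z_hi)
    cost <- switch(orientation$kind,
                   fixed = rep(1, ncd),
                   isotropic = runif(ncd, -1, 1),
                   mean_cos = sample_tilted_cos(ncd, kappa))
    phi <- runif(ncd, 0, 2 * pi)
    cd_blocks <- lapply(seq_len(ncd), function(m) {
      ax <- if (orientation$kind == "fixed") orientation$axis else {
        st <- sqrt(pmax(0, 1 - cost[m]^2))
        c(st * cos(phi[m]), st * sin(phi[m]), cost[m])
      }
      ctr <- c(runif(1, 0, box[1]), runif(1, 0, box[2]), zcd[m])
      cd_coords(ctr, ax / sqrt(sum(ax^2)))
    })
    blocks$cd <- do.call(rbind, cd_blocks)
    blocks$wat <- cbind(runif(n_water, 0, box[1]), runif(n_water, 0, box[2]),
                        runif(n_water, z_lo, z_hi))
    if (n_ice > 0L) blocks$ice <- ice_xyz
    cdx_frame(do.call(rbind, blocks), box, time = k - 1)
  }))
  cdx_trajectory(top, frames)
}

rebuild_residue_index_from_blocks <- function(tops) {
  idx <- integer(0)
  off <- 0L
  for (b in tops) {
    idx <- c(idx, b$residue_index + off)
    off <- max(idx)
  }
  idx
}

draw_planted_z <- function(profile, n, z_lo, z_hi) {
  switch(profile$kind,
    uniform = runif(n, z_lo, z_hi),
    bulk_only = runif(n, z_lo, z_hi - 1),
    surface_peaked = {
      out <- numeric(0)
      while (length(out) < n) {
        cand <- rnorm(2 * n, profile$peak_z, profile$peak_width)
        out <- c(out, cand[cand > z_lo & cand < z_hi])
      }
      out[seq_len(n)]
    })
}

#' Perturb a structure to an exact coordinate RMSD
#'
#' Adds isotropic Gaussian displacements, removes their mean, and
#' rescales so the coordinate RMSD to the input equals `target_rmsd`
#' exactly.
#'
#' @param structure list(topology, frame) or an n x 3 coordinate matrix.
#' @param target_rmsd target RMSD in nm (>= 0).
#' @param seed integer seed.
#' @return same type as `structure`.
#' @export
perturb_to_rmsd <- function(structure, target_rmsd, seed = 1) {
  if (target_rmsd < 0) stop("target_rmsd must be >= 0")
  coords <- if (is.list(structure)) structure$frame$coords else frame_coords(structure)
  n <- nrow(coords)
  if (target_rmsd > 0) {
    disp <- with_seed(seed, matrix(rnorm(3 * n), n, 3))
    disp <- sweep(disp, 2, colMeans(disp))
    disp <- disp * (target_rmsd / sqrt(mean(rowSums(disp^2))))
    coords <- coords + disp
  }
  if (is.list(structure)) {
    structure$frame$coords <- coords
    structure
  } else coords
}

#' Double-well potential of the toy sampler
#'
#' `U(s) = k (s^2 - 1)^2` with minima at s = -1, +1 and barrier `k` at
#' s = 0 (kJ/mol).
#'
#' @param s position(s).
#' @param k barrier height in kJ/mol.
#' @export
double_well_potential <- function(s, k = 5) k * (s^2 - 1)^2

double_well_force <- function(s, k) -4 * k * s * (s^2 - 1)

#' Boltzmann density of the toy system
#'
#' The sampler confines the walker with reflecting boundaries at
#' `+/- s_reflect`, so its zero-bias stationary law is the Boltzmann
#' distribution of [double_well_potential()] truncated to that
#' interval. Normalised by quadrature on `grid`.
#'
#' @param grid evaluation points.
#' @param k barrier height (kJ/mol).
#' @param kT thermal energy (kJ/mol).
#' @param s_reflect reflecting-boundary position (nm).
#' @return data.frame `s`, `density` (integrates to 1 on the domain).
#' @export
toy_boltzmann_density <- function(grid, k = 5, kT = 2.494, s_reflect = 2.0) {
  grid <- grid[abs(grid) <= s_reflect]
  u <- double_well_potential(grid, k)
  w <- exp(-(u - min(u)) / kT)
  Z <- sum((w[-1] + w[-length(w)]) / 2 * diff(grid))
  data.frame(s = grid, density = w / Z)
}

#' Well-tempered metadynamics parameters
#'
#' Defaults follow a typical protein parallel-bias setup: bias factor 15,
#' initial Gaussian height 2 kJ/mol, deposition rate 1 hill/ps, kT at
#' 300 K.
#'
#' @param bias_factor well-tempering factor gamma (> 1).
#' @param height initial Gaussian height (kJ/mol).
#' @param rate deposition rate (hills/ps).
#' @param kT thermal energy (kJ/mol); 2.494 at 300 K.
#' @param sigma Gaussian width in CV units.
#' @export
metad_params <- function(bias_factor = 15, height = 2, rate = 1,
                         kT = 2.494, sigma = 0.2) {
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  if (height < 0 || rate <= 0 || kT <= 0 || sigma <= 0)
    stop("height >= 0, rate > 0, kT > 0, sigma > 0 required")
  structure(list(bias_factor = bias_factor, height = height, rate = rate,
                 kT = kT, sigma = sigma), class = "cdx_metad_params")
}

#' Sample a 1-D double well with well-tempered metadynamics
#'
#' Overdamped (Brownian) Langevin dynamics on
#' [double_well_potential()] with Gaussian hills deposited at the
#' well-tempered rate: each hill's height is the initial height scaled
#' by `exp(-V(s)/((gamma-1) kT))`. The bias potential is accumulated on
#' a fixed grid; forces use the grid gradient. With `height = 0` the
#' run is plain Brownian dynamics whose stationary law is the Boltzmann
#' distribution of U — the zero-bias control.
#'
#' @param params a [metad_params()].
#' @param n_steps number of integration steps.
#' @param seed integer seed.
#' @param dt time step (ps).
#' @param k barrier height of the double well (kJ/mol).
#' @param mobility Brownian mobility (nm^2 per kJ/mol per ps); sets the
#'   diffusion constant D = mobility * kT.
#' @param grid bias grid; must cover the region the walker can reach.
#' @param s0 initial position.
#' @param s_reflect reflecting boundary: the walker is reflected back
#'   at `+/- s_reflect`, confining the CV like the wall restraints of
#'   production metadynamics setups (see [toy_boltzmann_density()]).
#' @param store_snapshots keep a copy of the grid bias at each
#'   deposition (memory-heavy; off by default).
#' @return object of class `cdx_toyrun`: list with `time`, `position`,
#'   `bias` (instantaneous V(s_t, t) per step, kJ/mol), `hills`
#'   (data.frame time/center/sigma/height), `params`, `k`, `dt`,
#'   `mobility`, `grid`, `bias_final` (V on the grid at the end) and
#'   optionally `snapshots`.
#' @export
sample_metad_double_well <- function(params, n_steps, seed = 1, dt = 0.01,
                                     k = 5, mobility = 0.5,
                                     grid = seq(-2.5, 2.5, by = 0.005),
                                     s0 = -1, s_reflect = 2.0,
                                     store_snapshots = FALSE) {
  stopifnot(inherits(params, "cdx_metad_params"))
  if (params$kT <= 0) stop("kT must be > 0")
  h <- grid[2] - grid[1]
  gmin <- grid[1]; ng <- length(grid)
  noise_sd <- sqrt(2 * params$kT * mobility * dt)
  if (mobility * dt * (12 * k * s_reflect^2 - 4 * k) > 2)
    stop("divergent step size: reduce dt or mobility for this potential")
  dep_every <- max(1L, as.integer(round(1 / (params$rate * dt))))
  n_hills_max <- n_steps %/% dep_every

  Vgrid <- numeric(ng)
  Fgrid <- numeric(ng)   # -dV/ds on the grid
  s <- s0
  pos <- numeric(n_steps)
  bias <- numeric(n_steps)
  hill_t <- numeric(n_hills_max); hill_c <- numeric(n_hills_max)
  hill_h <- numeric(n_hills_max)
  snaps <- if (store_snapshots) vector("list", n_hills_max) else NULL
  nh <- 0L
  gam1 <- (params$bias_factor - 1) * params$kT
  xi <- with_seed(seed, rnorm(n_steps))

  interp <- function(vals, s) {
    u <- (s - gmin) / h
    i <- floor(u)
    if (i < 1 || i >= ng - 1)
      stop("divergent trajectory: position left the bias grid")
    w <- u - i
    vals[i + 1L] * (1 - w) + vals[i + 2L] * w
  }

  for (t in seq_len(n_steps)) {
    fU <- double_well_force(s, k)
    fB <- if (nh > 0L) interp(Fgrid, s) else 0
    s <- s + mobility * dt * (fU + fB) + noise_sd * xi[t]
    if (!is.finite(s) || abs(s) > 2 * s_reflect)
      stop("divergent step size at step ", t, "; reduce dt or mobility")
    if (s > s_reflect) s <- 2 * s_reflect - s
    if (s < -s_reflect) s <- -2 * s_reflect - s
    if (params$height > 0 && t %% dep_every == 0L) {
      vs <- if (nh > 0L) interp(Vgrid, s) else 0
      ht <- params$height * exp(-vs / gam1)
      nh <- nh + 1L
      hill_t[nh] <- t * dt; hill_c[nh] <- s; hill_h[nh] <- ht
      Vgrid <- Vgrid + ht * exp(-(grid - s)^2 / (2 * params$sigma^2))
      Fgrid[2:(ng - 1)] <- -(Vgrid[3:ng] - Vgrid[1:(ng - 2)]) / (2 * h)
      if (store_snapshots) snaps[[nh]] <- Vgrid
    }
    pos[t] <- s
    bias[t] <- if (nh > 0L) interp(Vgrid, s) else 0
  }
  hills <- data.frame(time = hill_t[seq_len(nh)], center = hill_c[seq_len(nh)],
                      sigma = rep(params$sigma, nh), height = hill_h[seq_len(nh)])
  structure(list(time = dt * seq_len(n_steps), position = pos, bias = bias,
                 hills = hills, params = params, k = k, dt = dt,
                 mobility = mobility, s_reflect = s_reflect,
                 grid = grid, bias_final = Vgrid,
                 snapshots = if (store_snapshots) snaps[seq_len(nh)] else NULL),
            class = "cdx_toyrun")
}
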