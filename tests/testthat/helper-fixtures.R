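# Shared fixture builders for the test suite. All fixtures are generated
# in code, seeded, and small.

# internal geometry builders used to script exact fixtures
cd_topology <- cdslab:::cd_topology
cd_coords <- cdslab:::cd_coords

# a uniformly random proper rotation from the current RNG stream
with_seed_rotation <- function() cdslab:::random_rotation_matrix()

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# A protein+CD system in one frame, with residue `include_res`'s CA
# placed exactly at the cavity centre of the CD.
make_inclusion_system <- function(n_res = 8, include_res = 4,
                                  cd_center = c(2, 2, 2), box = c(6, 6, 6),
                                  seed = 3) {
  h <- make_ideal_helix(n_res, seed = seed, box = box)
  cd <- make_cd_molecule(center = cd_center, box = box)
  top <- cdx_topology(c(h$topology$atom_name, cd$topology$atom_name),
                      c(h$topology$residue_name, cd$topology$residue_name),
                      c(h$topology$residue_index,
                        cd$topology$residue_index + n_res))
  top <- assign_roles(top)
  cc <- rbind(h$frame$coords, cd$frame$coords)
  ca <- which(top$residue_index == include_res & top$atom_name == "CA")
  shift <- cd_center - cc[ca, ]
  np <- 3L * n_res
  cc[seq_len(np), ] <- sweep(cc[seq_len(np), ], 2, shift, FUN = "+")
  cdx_trajectory(top, list(cdx_frame(cc, box)))
}

# CA coordinates of an ideal helix, used as the base structure for
# perturbation ensembles.
helix_ca <- function(n_res = 30, seed = 2) {
  h <- make_ideal_helix(n_res, seed = seed)
  h$frame$coords[h$topology$role == "protein_backbone_CA", , drop = FALSE]
}

# Brute-force independent Q profile oracle: direct double loop over the
# adopted convention (CA-CA internal distances in Angstrom,
# sigma^2 = |i-j|^0.15, |i-j| >= 2). Inputs in nm.
qres_oracle <- function(A, B, sigma_exponent = 0.15, min_sep = 2L) {
  n <- nrow(A)
  q <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; m <- 0L
    for (j in seq_len(n)) {
      if (abs(i - j) < min_sep) next
      da <- 10 * sqrt(sum((A[i, ] - A[j, ])^2))
      db <- 10 * sqrt(sum((B[i, ] - B[j, ])^2))
      acc <- acc + exp(-(da - db)^2 / (2 * abs(i - j)^sigma_exponent))
      m <- m + 1L
    }
    q[i] <- acc / m
  }
  q
}

# Brute-force greedy max-neighbour clustering on an RMSD matrix,
# written independently of daura_cluster (explicit loops, no matrix
# bookkeeping shared with the implementation).
daura_oracle <- function(M, cutoff) {
  n <- nrow(M)
  left <- seq_len(n)
  assign <- integer(n)
  centroids <- integer(0)
  cl <- 0L
  while (length(left)) {
    best <- -1L; best_i <- NA_integer_
    for (i in left) {
      cnt <- 0L
      for (j in left) if (M[i, j] < cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; best_i <- i }   # first max = lowest index
    }
    members <- left[M[best_i, left] < cutoff]
    cl <- cl + 1L
    assign[members] <- cl
    centroids[cl] <- best_i
    left <- setdiff(left, members)
  }
  list(assignment = assign, centroids = centroids)
}

# Boltzmann CDF of the toy double well on the reflecting domain.
toy_boltzmann_cdf <- function(k = 5, kT = 2.494, s_reflect = 2.0) {
  ref <- toy_boltzmann_density(seq(-s_reflect, s_reflect, by = 1e-3),
                               k = k, kT = kT, s_reflect = s_reflect)
  cdf <- cumsum(ref$density) * 1e-3
  stats::approxfun(ref$s, cdf / max(cdf), rule = 2)
}

# Post-burnin CV values and Tiwary-Parrinello weights of one toy run.
toyrun_cv_weights <- function(run, burnin = 0.2) {
  keep <- seq.int(floor(length(run$time) * burnin) + 1L, length(run$time))
  ct <- if (nrow(run$hills)) estimate_ct(run$hills, run$grid,
                                         run$params$bias_factor,
                                         run$params$kT) else NULL
  list(cv = run$position[keep],
       w = frame_weights(run$bias[keep], run$time[keep], ct, run$params$kT))
}

FES_EDGES <- seq(-1.6, 1.6, by = 0.08)

fes_at_stations <- function(cv, w, stations, kT = 2.494) {
  f <- fes(weighted_distribution(cv, w, FES_EDGES), kT)
  vapply(stations, function(s) f$fes[which.min(abs(f$cv - s))], numeric(1))
}

# Station free energies relative to the first station (shift-free).
toy_fes_station_rel <- function(runs, stations) {
  if (inherits(runs, "cdx_toyrun")) runs <- list(runs)
  parts <- lapply(runs, toyrun_cv_weights)
  cv <- unlist(lapply(parts, `[[`, "cv"))
  w <- unlist(lapply(parts, `[[`, "w"))
  v <- fes_at_stations(cv, w, stations)
  v - v[1]
}

# Block-bootstrap SE of the relative station free energies: contiguous
# blocks of frames are resampled within each run, respecting the
# autocorrelation of the dynamics.
toy_fes_bootstrap_se <- function(runs, stations, B = 40, seed = 1,
                                 block_len = 5000L) {
  if (inherits(runs, "cdx_toyrun")) runs <- list(runs)
  parts <- lapply(runs, toyrun_cv_weights)
  reps <- cdslab:::with_seed(seed, {
    sapply(seq_len(B), function(b) {
      cv <- numeric(0); w <- numeric(0)
      for (p in parts) {
        n <- length(p$cv)
        nb <- ceiling(n / block_len)
        starts <- sample.int(n - block_len + 1L, nb, replace = TRUE)
        idx <- unlist(lapply(starts, function(s) s:(s + block_len - 1L)))[1:n]
        cv <- c(cv, p$cv[idx])
        w <- c(w, p$w[idx])
      }
      v <- fes_at_stations(cv, w, stations)
      v - v[1]
    })
  })
  apply(reps, 1, stats::sd)
}

# FES error of a toy run (or list of runs) against the analytic double
# well at given stations.
toy_fes_errors <- function(runs, stations = c(-1, 0, 1), ...) {
  f <- toyrun_fes(runs, ...)$fes
  k <- if (inherits(runs, "cdx_toyrun")) runs$k else runs[[1]]$k
  U <- double_well_potential(f$cv, k)
  U <- U - min(U)
  vapply(stations, function(s) {
    i <- which.min(abs(f$cv - s))
    f$fes[i] - U[i]
  }, numeric(1))
}
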