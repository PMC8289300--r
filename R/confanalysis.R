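# Conformational analysis: GROMOS (Daura) clustering of reweighted
# ensembles, per-residue Q structural-similarity profiles, unstable-patch
# extraction and cross-referencing with inclusion frequencies and
# aggregation-prone regions.

#' Pairwise-RMSD matrix after per-pair superposition
#'
#' @param coords_list list of n x 3 coordinate matrices (same atom set).
#' @param selection optional atom indices used for fit and RMSD.
#' @return symmetric matrix of fitted RMSD values (nm).
#' @export
pairwise_rmsd_matrix <- function(coords_list, selection = NULL) {
  n <- length(coords_list)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    M[i, j] <- M[j, i] <- fit_rmsd(coords_list[[i]], coords_list[[j]],
                                   selection)
  }
  M
}

#' GROMOS (Daura) conformational clustering
#'
#' Greedy neighbour clustering: the frame with the most neighbours
#' (pairwise fitted RMSD below the cutoff) becomes a cluster centroid;
#' it and its neighbours are removed; repeat until no frame remains.
#' Ties on the neighbour count are broken toward the lowest frame
#' index, which makes the result deterministic. Clusters are formed on
#' unweighted RMSD geometry; frame weights (e.g. from metadynamics
#' reweighting) enter only the reported populations.
#'
#' @param frames a [cdx_trajectory()], a list of coordinate matrices,
#'   or a precomputed symmetric RMSD matrix.
#' @param cutoff RMSD cutoff in nm (default 0.1).
#' @param selection atom indices used for the RMSD; default, for a
#'   trajectory input, the N/CA/C backbone.
#' @param weights optional per-frame statistical weights.
#' @return object of class `cdx_cluster_result`: `assignment` (frame ->
#'   cluster id, 1 = most populated), `centroids` (frame index per
#'   cluster), `sizes`, `weighted_fractions`.
#' @export
daura_cluster <- function(frames, cutoff = 0.1, selection = NULL,
                          weights = NULL) {
  M <- if (is.matrix(frames)) {
    frames
  } else {
    coords_list <- if (inherits(frames, "cdx_trajectory")) {
      if (is.null(selection))
        selection <- which(frames$topology$role %in%
                             c("protein_backbone_N", "protein_backbone_CA",
                               "protein_backbone_C"))
      lapply(frames$frames, function(f) f$coords)
    } else frames
    pairwise_rmsd_matrix(coords_list, selection)
  }
  n <- nrow(M)
  if (!n) stop("empty frame set")
  if (is.null(weights)) weights <- rep(1, n)
  neigh <- M < cutoff
  diag(neigh) <- TRUE
  remaining <- rep(TRUE, n)
  assignment <- integer(n)
  centroids <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    counts <- colSums(neigh[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    centre <- which.max(counts)          # which.max takes the lowest index on ties
    members <- which(neigh[, centre] & remaining)
    cl <- cl + 1L
    assignment[members] <- cl
    centroids[cl] <- centre
    remaining[members] <- FALSE
  }
  wfrac <- vapply(seq_len(cl), function(k) sum(weights[assignment == k]),
                  numeric(1)) / sum(weights)
  sizes <- tabulate(assignment, cl)
  ord <- order(wfrac, decreasing = TRUE)
  relabel <- integer(cl)
  relabel[ord] <- seq_len(cl)
  structure(list(assignment = relabel[assignment],
                 centroids = centroids[ord],
                 sizes = sizes[ord],
                 weighted_fractions = wfrac[ord]),
            class = "cdx_cluster_result")
}

#' @export
print.cdx_cluster_result <- function(x, ...) {
  cat(sprintf("cdx_cluster_result: %d clusters over %d frames\n",
              length(x$centroids), length(x$assignment)))
  k <- min(5L, length(x$centroids))
  for (i in seq_len(k))
    cat(sprintf("  cluster %d: centroid frame %d, %d frames, weight %.3f\n",
                i, x$centroids[i], x$sizes[i], x$weighted_fractions[i]))
  invisible(x)
}

#' Per-residue structural similarity (Q profile)
#'
#' For each residue i,
#' q_i = (1/N_i) * sum over j with |i-j| >= `min_separation` of
#' exp( -(r_ij^A - r_ij^B)^2 / (2 sigma_ij^2) ),  sigma_ij^2 = |i-j|^0.15,
#' where r_ij are CA-CA distances within each structure, evaluated in
#' Angstrom: the sequence-separation width law |i-j|^0.15 (of order
#' 1-2) is calibrated on Angstrom distances in the Q_res literature,
#' and only on that scale does the score discriminate sub-nm backbone
#' rearrangements. Internal distances make the score
#' superposition-invariant; 1 means identical local distance patterns,
#' 0 no similarity.
#'
#' @param structure_a,structure_b CA coordinate matrices (n_res x 3), or
#'   `list(topology, frame)` pairs from which CA atoms are extracted.
#' @param sigma_exponent exponent of the sequence-separation width law
#'   (default 0.15).
#' @param min_separation smallest |i-j| entering the sum (default 2:
#'   self and adjacent residues excluded).
#' @return object of class `cdx_qres_profile`: data.frame
#'   `residue_index`, `q`, with the parameters as attributes.
#' @export
qres <- function(structure_a, structure_b, sigma_exponent = 0.15,
                 min_separation = 2L) {
  A <- ca_coords(structure_a)
  B <- ca_coords(structure_b)
  if (nrow(A) != nrow(B)) stop("structures have different residue counts")
  n <- nrow(A)
  if (n < min_separation + 1L) stop("too few residues for the separation rule")
  DA <- as.matrix(stats::dist(A)) * 10  # nm -> Angstrom
  DB <- as.matrix(stats::dist(B)) * 10
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  q <- vapply(seq_len(n), function(i) {
    j <- which(sep[i, ] >= min_separation)
    if (!length(j)) return(NA_real_)
    s2 <- sep[i, j]^sigma_exponent
    mean(exp(-(DA[i, j] - DB[i, j])^2 / (2 * s2)))
  }, numeric(1))
  out <- data.frame(residue_index = seq_len(n), q = q)
  attr(out, "sigma_exponent") <- sigma_exponent
  attr(out, "min_separation") <- min_separation
  class(out) <- c("cdx_qres_profile", "data.frame")
  out
}

ca_coords <- function(x) {
  if (is.list(x) && !is.null(x$topology)) {
    idx <- which(x$topology$role == "protein_backbone_CA")
    if (!length(idx)) stop("structure has no CA atoms")
    x$frame$coords[idx, , drop = FALSE]
  } else frame_coords(x)
}

#' Extract conformationally unstable residues
#'
#' Residues whose Q score falls below the threshold (default 0.5) are
#' flagged as the most unstable patches.
#'
#' @param qres_profile a [qres()] result.
#' @param threshold Q threshold (default 0.5).
#' @return integer vector of 1-based residue indices.
#' @export
unstable_patches <- function(qres_profile, threshold = 0.5) {
  qres_profile$residue_index[!is.na(qres_profile$q) &
                               qres_profile$q < threshold]
}

#' Per-residue unstable-patch frequency across systems
#'
#' Fraction of systems in which each residue is unstable, optionally
#' stratified by a per-system group label (e.g. excipient type). The
#' group-wise frequencies, weighted by group sizes, average back to the
#' pooled frequency.
#'
#' @param patch_sets list of integer residue sets, one per system.
#' @param residue_range integer vector of all residue indices.
#' @param groups optional character vector, one label per system.
#' @return data.frame `residue_index`, `frequency`, plus one
#'   `frequency_<group>` column per group when `groups` is given.
#' @export
patch_frequency <- function(patch_sets, residue_range, groups = NULL) {
  if (!length(patch_sets)) stop("need at least one system")
  for (s in patch_sets)
    if (length(s) && !all(s %in% residue_range))
      stop("patch set contains residues outside residue_range")
  count_in <- function(sets) {
    vapply(residue_range,
           function(r) mean(vapply(sets, function(s) r %in% s, logical(1))),
           numeric(1))
  }
  out <- data.frame(residue_index = residue_range,
                    frequency = count_in(patch_sets))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(patch_sets))
    for (g in unique(groups))
      out[[paste0("frequency_", g)]] <- count_in(patch_sets[groups == g])
  }
  out
}

#' Parse aggregation-prone-region ranges
#'
#' Accepts entries like `"PHE13-CYS17"` or `"ILE56"` (residue name +
#' 1-based index, ranges hyphen-separated), one per line or
#' comma-separated, as produced by sequence-based aggregation
#' predictors.
#'
#' @param x character vector of range strings, or a file path.
#' @return sorted integer vector of residue indices.
#' @export
parse_apr_ranges <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  toks <- trimws(unlist(strsplit(x, "[,\n]")))
  toks <- toks[nzchar(toks)]
  res <- integer(0)
  for (tk in toks) {
    m <- regmatches(tk, gregexpr("[0-9]+", tk))[[1]]
    if (!length(m) || length(m) > 2) stop("cannot parse APR entry: '", tk, "'")
    lo <- as.integer(m[1]); hi <- as.integer(m[length(m)])
    if (hi < lo) stop("descending APR range: '", tk, "'")
    res <- c(res, lo:hi)
  }
  sort(unique(res))
}

#' Cross-reference unstable patches, inclusions and APRs
#'
#' Joins the per-residue unstable-patch frequency with the per-residue
#' cyclodextrin-inclusion frequency and an aggregation-prone-region
#' flag; reports the Spearman rank correlation between the two
#' frequency profiles and the Jaccard overlap between the residues ever
#' unstable and the APR set.
#'
#' @param patch_freq data.frame `residue_index`, `frequency`
#'   ([patch_frequency()]).
#' @param inclusion_freq data.frame `residue_index`, `frequency`
#'   ([inclusion_frequency()]).
#' @param apr_ranges APR residue indices, or strings/file for
#'   [parse_apr_ranges()].
#' @return list with `table` (residue_index, patch_freq,
#'   inclusion_freq, in_apr), `rank_correlation`, `jaccard_apr`.
#' @export
crossref_patches <- function(patch_freq, inclusion_freq, apr_ranges) {
  apr <- if (is.character(apr_ranges)) parse_apr_ranges(apr_ranges)
         else as.integer(apr_ranges)
  res <- patch_freq$residue_index
  if (length(apr) && !all(apr %in% res))
    stop("APR range outside residue span: ",
         paste(setdiff(apr, res), collapse = ", "))
  inc <- inclusion_freq$frequency[match(res, inclusion_freq$residue_index)]
  inc[is.na(inc)] <- 0
  tab <- data.frame(residue_index = res,
                    patch_freq = patch_freq$frequency,
                    inclusion_freq = inc,
                    in_apr = res %in% apr)
  rc <- if (stats::sd(tab$patch_freq) == 0 || stats::sd(tab$inclusion_freq) == 0)
    NA_real_ else stats::cor(tab$patch_freq, tab$inclusion_freq,
                             method = "spearman")
  ever <- res[tab$patch_freq > 0]
  uni <- union(ever, apr)
  jac <- if (length(uni)) length(intersect(ever, apr)) / length(uni) else NA_real_
  list(table = tab, rank_correlation = rc, jaccard_apr = jac)
}
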