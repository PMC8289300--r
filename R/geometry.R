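# Rigid-body superposition and RMSD primitives shared by the collective
# variables, clustering and Q_res modules.

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` over a common atom selection.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm) or `cdx_frame`s.
#' @param selection integer atom indices used for the fit (default all).
#' @return list with `rotation` (3 x 3, det = +1), `translation`
#'   (length 3), `rmsd` (nm over the selection) and `coords`, the full
#'   mobile coordinates after superposition.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  M <- frame_coords(mobile)
  R <- frame_coords(reference)
  if (is.null(selection)) selection <- seq_len(nrow(R))
  if (length(selection) < 3L) stop("need at least 3 atoms to superpose")
  A <- M[selection, , drop = FALSE]
  B <- R[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection atom counts differ")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) atom selection: rotation is underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)
  fitted <- sweep(tcrossprod(sweep(M, 2, ca), rot), 2, cb, FUN = "+")
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - B)^2)))
  list(rotation = rot, translation = cb - as.numeric(rot %*% ca),
       rmsd = rmsd, coords = fitted)
}

frame_coords <- function(x) {
  if (inherits(x, "cdx_frame")) x$coords else as.matrix(x)
}

#' Coordinate RMSD without superposition
#'
#' @param a,b n x 3 coordinate matrices (nm).
#' @return sqrt of the mean squared per-atom displacement.
#' @export
coord_rmsd <- function(a, b) {
  a <- frame_coords(a); b <- frame_coords(b)
  sqrt(mean(rowSums((a - b)^2)))
}

# RMSD after optimal superposition over `selection`.
fit_rmsd <- function(a, b, selection = NULL) {
  kabsch_superpose(a, b, selection)$rmsd
}
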