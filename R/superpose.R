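#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using the atoms in
#' `fit_sel`, by singular value decomposition of the covariance matrix with
#' reflection correction, so the returned rotation is always proper
#' (det R = +1). Rigid-body motion removal is the preliminary step of every
#' RMSD-type observable here.
#'
#' @param mobile n x 3 coordinate matrix to move (A).
#' @param reference n x 3 coordinate matrix to fit onto (A); same atom order.
#' @param fit_sel indices (into rows) used for the fit; default all rows.
#' @return list with `R` (3x3 rotation), `t` (translation such that the fitted
#'   coordinates are `mobile %*% R + t`), `rmsd` (post-fit RMSD over
#'   `fit_sel`, A), and `coords` (all rows of `mobile`, transformed).
#' @export
superpose <- function(mobile, reference, fit_sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(mobile))
  if (length(fit_sel) != length(unique(fit_sel))) {
    stop("fit selection contains duplicate indices")
  }
  m <- mobile[fit_sel, , drop = FALSE]
  r <- reference[fit_sel, , drop = FALSE]
  if (nrow(m) != nrow(r)) stop("fit selections differ in size")
  if (nrow(m) < 3) stop("superposition needs at least 3 fit atoms")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  # collinearity guard: rank of the centered mobile set must be >= 2
  if (qr(mc)$rank < 2) stop("degenerate (collinear) fit geometry")
  H <- crossprod(mc, rc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)   # x_fit = R %*% x ; row form: x %*% t(R)
  Rt <- t(R)
  tvec <- cr - as.vector(cm %*% Rt)
  fitted_sel <- sweep(m %*% Rt, 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((fitted_sel - r)^2)))
  coords <- sweep(mobile %*% Rt, 2, tvec, "+")
  list(R = R, t = tvec, rmsd = rmsd, coords = coords)
}

#' RMSD between two coordinate sets after optimal superposition
#'
#' @param x,y n x 3 coordinate matrices in the same atom order (A).
#' @param fit_sel row indices used both to fit and to measure; default all.
#' @return RMSD in A.
#' @export
rmsd_fit <- function(x, y, fit_sel = NULL) {
  superpose(x, y, fit_sel)$rmsd
}
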