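# Validation and outcome metrics: the normalized mean square error against
# experimental mean and confidence-interval curves, the incision opening
# gap, disc height and lateral bulge, anatomic-axis tensor transforms, and
# the preload formula tying disc cross-section to the dynamic preload.

#' Response curve container
#'
#' A sampled scalar response with optional experimental companions on the
#' same (strictly increasing) abscissa.
#'
#' @param x Abscissa values.
#' @param y_model Model response.
#' @param y_expmean Optional experimental mean.
#' @param y_ci Optional experimental 95 percent confidence bound.
#' @return Object of class `disc_curve` (a data.frame).
#' @export
response_curve <- function(x, y_model, y_expmean = NULL, y_ci = NULL) {
  if (any(diff(x) <= 0)) stop("abscissa must be strictly increasing")
  if (length(y_model) != length(x)) stop("length mismatch")
  df <- data.frame(x = x, y_model = y_model)
  if (!is.null(y_expmean)) {
    if (length(y_expmean) != length(x)) stop("length mismatch")
    df$y_expmean <- y_expmean
  }
  if (!is.null(y_ci)) {
    if (length(y_ci) != length(x)) stop("length mismatch")
    df$y_ci <- y_ci
  }
  structure(df, class = c("disc_curve", "data.frame"))
}

#' Resample a model curve onto an experimental abscissa
#'
#' Linear interpolation of the model response onto the experimental sample
#' points, producing a `disc_curve` ready for [nmse()].
#'
#' @param model_x,model_y Model curve samples.
#' @param exp_x Experimental abscissa (within the model range).
#' @param y_expmean,y_ci Experimental mean and CI bound on `exp_x`.
#' @return A `disc_curve`.
#' @export
resample_to_experiment <- function(model_x, model_y, exp_x, y_expmean, y_ci) {
  ym <- stats::approx(model_x, model_y, xout = exp_x, rule = 2)$y
  response_curve(exp_x, ym, y_expmean, y_ci)
}

#' Normalized mean square error of a model curve
#'
#' `NMSE = sum (Y_model - Y_expmean)^2 / sum (Y_CI - Y_expmean)^2`. Zero for
#' a perfect match of the experimental mean; one when the model deviates
#' exactly as much as the 95 percent confidence bound; values above one
#' indicate a response outside the confidence interval.
#'
#' @param curve A `disc_curve` carrying `y_expmean` and `y_ci`.
#' @return Dimensionless error.
#' @export
nmse <- function(curve) {
  if (is.null(curve$y_expmean) || is.null(curve$y_ci))
    stop("curve must carry experimental mean and CI bound")
  den <- sum((curve$y_ci - curve$y_expmean)^2)
  if (den == 0) stop("degenerate confidence interval: zero denominator")
  sum((curve$y_model - curve$y_expmean)^2) / den
}

#' Opening gap of the released radial cut
#'
#' Euclidean distance between the centroids of the two cut faces at the
#' outer AF edge, measured at mid-height of the deformed configuration.
#'
#' @param mesh A `disc_mesh` with the cut released.
#' @param state The re-equilibrated `disc_state`.
#' @param locus "outer" (default) or "inner": which radial edge of the cut
#'   to measure at.
#' @return Opening gap W_i (mm).
#' @export
opening_gap <- function(mesh, state, locus = c("outer", "inner")) {
  locus <- match.arg(locus)
  if (!isTRUE(mesh$cut_released)) stop("cut not released")
  m <- mesh$sets$cut_master
  d <- mesh$sets$cut_dup
  rref <- sqrt(mesh$nodes[m, 1]^2 + mesh$nodes[m, 2]^2)
  sel <- if (locus == "outer") rref > max(rref) - 1e-6 else rref < min(rref) + 1e-6
  H <- mesh$spec$height
  zref <- mesh$nodes[m, 3]
  dz <- abs(zref - H / 2)
  sel <- sel & dz <= min(dz[sel]) + 1e-6
  pos <- function(ids) {
    mesh$nodes[ids, , drop = FALSE] +
      matrix(state$u[as.vector(t(outer(3 * (ids - 1), 1:3, `+`)))],
             ncol = 3, byrow = TRUE)
  }
  cm <- colMeans(pos(m[sel]))
  cd <- colMeans(pos(d[sel]))
  sqrt(sum((cm - cd)^2))
}

#' Disc height and lateral bulge
#'
#' Height: the median axial distance between paired superior and inferior
#' surface points on the mid-coronal plane. Bulge: per side, the deformed
#' lateral extent of the disc beyond the platen (endplate) edge on the
#' mid-coronal plane.
#'
#' @param mesh A `disc_mesh`.
#' @param state A `disc_state`.
#' @param tol Tolerance (mm) for locating the mid-coronal node line.
#' @return List: `median_height`, `bulge_left`, `bulge_right` (mm).
#' @export
disc_height_and_bulge <- function(mesh, state, tol = 1e-6) {
  nd <- mesh$nodes
  defpos <- nd + matrix(state$u, ncol = 3, byrow = TRUE)
  H <- mesh$spec$height
  midcor <- abs(nd[, 2]) < tol
  top <- intersect(mesh$sets$top, which(midcor))
  bot <- intersect(mesh$sets$bottom, which(midcor))
  # pair by reference x
  key_t <- round(nd[top, 1], 8)
  key_b <- round(nd[bot, 1], 8)
  common <- intersect(key_t, key_b)
  hts <- vapply(common, function(k) {
    defpos[top[match(k, key_t)], 3] - defpos[bot[match(k, key_b)], 3]
  }, 0)
  # bulge: outermost deformed x among mid-coronal nodes vs the platen edge
  mc <- which(midcor)
  plat <- union(top, bot)
  br <- max(defpos[mc, 1]) - max(defpos[plat, 1])
  bl <- max(-defpos[mc, 1]) - max(-defpos[plat, 1])
  list(median_height = stats::median(hts), bulge_left = bl, bulge_right = br)
}

#' Transform tensor fields to anatomic axes
#'
#' Rotates a per-element tensor field from global x/y/z components into the
#' (radial, circumferential, axial) triad of each element, using the local
#' material axes recorded at meshing (e3 = radial, e1 = circumferential,
#' e2 = axial). Trace and determinant are preserved.
#'
#' @param field ne x 3 x 3 array of tensors in global components.
#' @param mesh A `disc_mesh`.
#' @return ne x 3 x 3 array ordered (radial, circumferential, axial).
#' @export
anatomic_transform <- function(field, mesh) {
  ne <- nrow(mesh$elem)
  out <- array(0, dim(field))
  for (e in seq_len(ne)) {
    Tm <- mesh$axes[e, , ]             # rows e1 (circ), e2 (axial), e3 (radial)
    Q <- rbind(Tm[3, ], Tm[1, ], Tm[2, ])
    out[e, , ] <- Q %*% field[e, , ] %*% t(Q)
  }
  out
}

#' Dynamic preload from disc plan-view lengths
#'
#' Cross-sectional area `A = 0.84 L_rl L_ap` and the preload
#' `0.2 MPa * A * 1.5` that establishes physiological nucleus
#' pressurization for the dynamic multiaxial tests.
#'
#' @param L_rl Left-right length (mm).
#' @param L_ap Anterior-posterior length (mm).
#' @return List: `area` (mm^2), `preload` (N).
#' @export
preload_from_lengths <- function(L_rl, L_ap) {
  if (L_rl < 0 || L_ap < 0) stop("lengths must be non-negative")
  A <- 0.84 * L_rl * L_ap
  list(area = A, preload = 0.2 * A * 1.5)
}
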