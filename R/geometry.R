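# Geometric primitives shared by the engine and the analysis layer:
# periodic (minimum-image) distances, signed dihedral angles, and
# optimal-superposition RMSD. All lengths are in Angstrom, angles in degrees.

#' Orthorhombic periodic box
#'
#' Defines the simulation cell used for minimum-image distances and for
#' wrapping coordinates during propagation. Only orthorhombic cells are
#' supported; each axis can be flagged periodic independently. The default
#' matches the membrane-transporter setup this package emulates: a
#' 120 x 120 x 100 A cell, periodic in the membrane plane (x, y) and bounded
#' in z (the membrane normal; the extracellular side is z > 0).
#'
#' @param lengths numeric(3), edge lengths in Angstrom; all > 0.
#' @param periodic logical(3), whether each axis wraps.
#' @return An object of class `periodic_box`.
#' @examples
#' box <- periodic_box()
#' minimum_image_distance(c(1, 0, 0), c(119, 0, 0), box)  # 2, wrapped in x
#' @export
periodic_box <- function(lengths = c(120, 120, 100),
                         periodic = c(TRUE, TRUE, FALSE)) {
  lengths <- as.numeric(lengths)
  periodic <- as.logical(periodic)
  if (length(lengths) != 3L || anyNA(lengths) || any(!is.finite(lengths)) ||
      any(lengths <= 0)) {
    stop("box edge lengths must be three finite positive numbers", call. = FALSE)
  }
  if (length(periodic) != 3L || anyNA(periodic)) {
    stop("periodic flags must be three logicals", call. = FALSE)
  }
  structure(list(lengths = lengths, periodic = periodic),
            class = "periodic_box")
}

#' @export
print.periodic_box <- function(x, ...) {
  cat(sprintf("<periodic_box %g x %g x %g A, periodic: %s>\n",
              x$lengths[1], x$lengths[2], x$lengths[3],
              paste(ifelse(x$periodic, c("x", "y", "z"), "-"), collapse = "")))
  invisible(x)
}

check_vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L) {
    stop(sprintf("%s must have exactly 3 coordinates", what), call. = FALSE)
  }
  if (anyNA(p) || any(!is.finite(p))) {
    stop(sprintf("%s has non-finite coordinates", what), call. = FALSE)
  }
  p
}

#' Minimum-image distance between two points
#'
#' Euclidean distance under the minimum-image convention of an orthorhombic
#' box: on each periodic axis the displacement is wrapped into
#' `[-L/2, L/2]`; non-periodic axes use the plain displacement. With
#' `box = NULL` this is the ordinary Euclidean distance.
#'
#' @param p,q numeric(3) coordinates in Angstrom.
#' @param box a [periodic_box()] or `NULL`.
#' @return Distance in Angstrom (scalar).
#' @export
minimum_image_distance <- function(p, q, box = NULL) {
  p <- check_vec3(p, "p")
  q <- check_vec3(q, "q")
  d <- p - q
  if (!is.null(box)) {
    stopifnot(inherits(box, "periodic_box"))
    per <- box$periodic
    L <- box$lengths
    d[per] <- d[per] - L[per] * round(d[per] / L[per])
  }
  sqrt(sum(d * d))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral (torsion) angle of four points
#'
#' Returns the torsion angle p1-p2-p3-p4 in degrees, in the range
#' `(-180, 180]`, using the IUPAC sign convention (positive = clockwise
#' rotation of the far bond when sighting from p2 towards p3). A planar cis
#' arrangement gives 0, planar trans gives 180. Used for the ligand
#' side-chain C-CA-CB-CG angle that separates the syn (~70 deg) and anti
#' (~180 deg) conformations.
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- check_vec3(p1, "p1"); p2 <- check_vec3(p2, "p2")
  p3 <- check_vec3(p3, "p3"); p4 <- check_vec3(p4, "p4")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 < 1e-12) stop("degenerate dihedral: central bond has zero length", call. = FALSE)
  if (sum(n1 * n1) < 1e-18 || sum(n2 * n2) < 1e-18) {
    stop("degenerate dihedral: three consecutive points are collinear", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Root-mean-square deviation between two conformations of the same point
#' set. With `fit = TRUE` the moving set is first superposed onto the
#' reference by the rigid transform (rotation + translation, no reflection)
#' that minimises the RMSD, computed by singular value decomposition of the
#' covariance matrix. With `fit = FALSE` the plain RMSD of the coordinates
#' as given is returned and the transform is the identity.
#'
#' @param ref,mov numeric matrices (n x 3) with matching row counts.
#' @param fit logical; superpose before measuring?
#' @return A list with `rmsd` (Angstrom), `rotation` (3 x 3, det +1) and
#'   `translation` (length 3): applying `x %*% t(rotation) + translation`
#'   to `mov` gives the superposed coordinates.
#' @export
kabsch_rmsd <- function(ref, mov, fit = TRUE) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  storage.mode(ref) <- "double"; storage.mode(mov) <- "double"
  if (ncol(ref) != 3L || ncol(mov) != 3L) {
    stop("coordinate sets must be n x 3 matrices", call. = FALSE)
  }
  if (nrow(ref) != nrow(mov)) {
    stop(sprintf("point count mismatch: ref has %d, mov has %d",
                 nrow(ref), nrow(mov)), call. = FALSE)
  }
  if (anyNA(ref) || anyNA(mov) || any(!is.finite(ref)) || any(!is.finite(mov))) {
    stop("coordinate sets contain non-finite values", call. = FALSE)
  }
  if (!fit) {
    rmsd <- sqrt(mean(rowSums((ref - mov)^2)))
    return(list(rmsd = rmsd, rotation = diag(3), translation = c(0, 0, 0)))
  }
  n <- nrow(ref)
  if (n < 3L) stop("superposition requires at least 3 points", call. = FALSE)
  cref <- colMeans(ref); cmov <- colMeans(mov)
  P <- sweep(mov, 2, cmov)   # moving, centred
  Q <- sweep(ref, 2, cref)   # reference, centred
  # degenerate (collinear / coincident) sets have covariance rank < 2
  if (sum(svd(Q)$d > 1e-8) < 2L || sum(svd(P)$d > 1e-8) < 2L) {
    stop("degenerate point set: superposition is ill-defined for collinear points",
         call. = FALSE)
  }
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  translation <- as.numeric(cref - R %*% cmov)
  list(rmsd = rmsd, rotation = R, translation = translation)
}

#' Rotate a point about an arbitrary axis
#'
#' Rodrigues rotation of `p` about the axis through `origin` with direction
#' `axis` (right-handed, `angle` in degrees). Exposed because the fixture
#' generator and the dihedral tests build conformers this way.
#'
#' @param p numeric(3) point; `axis` numeric(3) direction (any nonzero length);
#'   `origin` numeric(3); `angle` degrees.
#' @return Rotated numeric(3).
#' @export
rotate_about_axis <- function(p, axis, angle, origin = c(0, 0, 0)) {
  p <- check_vec3(p, "p"); origin <- check_vec3(origin, "origin")
  axis <- check_vec3(axis, "axis")
  na <- sqrt(sum(axis^2))
  if (na < 1e-12) stop("rotation axis has zero length", call. = FALSE)
  k <- axis / na
  th <- angle * pi / 180
  v <- p - origin
  vrot <- v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
  vrot + origin
}
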