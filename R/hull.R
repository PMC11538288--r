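# Convex-hull geometry for acoustic-space occupancy. Point sets are small
# (one point per individual), so the 3D volume uses exact supporting-plane
# enumeration rather than an incremental hull.

#' Convex hull area (2D) or volume (3D) of a point set
#'
#' For \code{dim = 2}, the polygon area of the planar convex hull
#' (shoelace formula on \code{grDevices::chull}). For \code{dim = 3}, the
#' exact hull volume: every supporting plane (a plane through three points
#' with all points on one side) contributes \code{area * distance / 3} by the
#' divergence theorem. Degenerate sets (collinear / coplanar) have zero
#' area/volume and raise a warning, not an error. The volume is invariant to
#' translation and rotation and monotone non-decreasing under adding points.
#'
#' @param pts numeric matrix, one row per point, 2 or 3 columns.
#' @return area (2 columns) or volume (3 columns) in the units of
#'   \code{pts} squared/cubed.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' hullVolume(sq)  # 1
#' @export
hullVolume <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) == 2) hullArea2d(pts)
  else if (ncol(pts) == 3) hullVolume3d(pts)
  else hcStop("holocall_bad_dim", "pts must have 2 or 3 columns, got %d",
              ncol(pts))
}

hullArea2d <- function(pts) {
  if (nrow(pts) < 3) {
    hcWarn("fewer than 3 points: hull area is 0")
    return(0)
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) {
    hcWarn("degenerate (collinear) point set: hull area is 0")
    return(0)
  }
  x <- pts[h, 1]; y <- pts[h, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (a == 0) hcWarn("degenerate (collinear) point set: hull area is 0")
  a
}

hullVolume3d <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4) {
    hcWarn("fewer than 4 distinct points: hull volume is 0")
    return(0)
  }
  o <- colMeans(pts)
  scale <- max(apply(pts, 2, function(c) diff(range(c))), .Machine$double.eps)
  eps <- 1e-9 * scale

  tri <- utils::combn(n, 3)
  a <- pts[tri[1, ], , drop = FALSE]
  b <- pts[tri[2, ], , drop = FALSE]
  cc <- pts[tri[3, ], , drop = FALSE]
  u <- b - a; v <- cc - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nn > eps * scale  # skip collinear triples
  if (!any(ok)) {
    hcWarn("degenerate (collinear) point set: hull volume is 0")
    return(0)
  }
  N <- cbind(nx, ny, nz)[ok, , drop = FALSE] / nn[ok]
  d <- rowSums(N * a[ok, , drop = FALSE])
  # orient every normal away from the centroid
  flip <- (N %*% o) - d > 0
  N[flip, ] <- -N[flip, , drop = FALSE]
  d[flip] <- -d[flip]

  # side test in chunks: plane supports the hull if no point lies outside
  S <- pts %*% t(N) - rep(d, each = n)   # n x T signed distances
  supporting <- colSums(S > eps) == 0
  if (!any(supporting)) {
    hcWarn("degenerate (coplanar) point set: hull volume is 0")
    return(0)
  }
  N <- N[supporting, , drop = FALSE]
  d <- d[supporting]

  key <- apply(round(cbind(N, d / scale), 7), 1, paste, collapse = "|")
  first <- !duplicated(key)
  N <- N[first, , drop = FALSE]
  d <- d[first]

  vol <- 0
  for (f in seq_along(d)) {
    h <- d[f] - sum(N[f, ] * o)          # centroid-to-plane distance (outward)
    if (h <= eps) next                   # coplanar-with-centroid face
    on <- abs(pts %*% N[f, ] - d[f]) <= eps
    face <- pts[on, , drop = FALSE]
    if (nrow(face) < 3) next
    # orthonormal in-plane basis for the 2D area
    u1 <- face[2, ] - face[1, ]
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(N[f, 2] * u1[3] - N[f, 3] * u1[2],
            N[f, 3] * u1[1] - N[f, 1] * u1[3],
            N[f, 1] * u1[2] - N[f, 2] * u1[1])
    p2 <- cbind((face %*% u1), (face %*% u2))
    vol <- vol + hullArea2dQuiet(p2) * h / 3
  }
  if (vol <= eps^3) {
    hcWarn("degenerate (coplanar) point set: hull volume is 0")
    return(0)
  }
  vol
}

hullArea2dQuiet <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Acoustic-space occupancy per taxon
#'
#' Convex-hull volume of each taxon's individuals in the first \code{dim}
#' principal components, plus the two relative occupancy measures: RCHS
#' (volume divided by the taxon's species count) and RCHI (volume divided by
#' its individual count).
#'
#' @param space an [AcousticSpace-class].
#' @param grouping taxon label per individual (same order as the score rows).
#' @param dim 2 or 3 (default 3).
#' @param speciesOf optional species label per individual, used to count
#'   species per taxon; without it RCHS is NA.
#' @return data.frame: taxon, dim, volume, n_species, n_individuals,
#'   rchs, rchi.
#' @export
hullOccupancy <- function(space, grouping, dim = 3, speciesOf = NULL) {
  stopifnot(is(space, "AcousticSpace"))
  sc <- space@scores
  if (length(grouping) != nrow(sc))
    hcStop("holocall_bad_grouping",
           "grouping length %d does not match %d individuals",
           length(grouping), nrow(sc))
  if (!dim %in% c(2, 3))
    hcStop("holocall_bad_dim", "dim must be 2 or 3")
  if (ncol(sc) < dim)
    hcStop("holocall_bad_dim", "space has only %d PCs, need %d", ncol(sc), dim)
  grouping <- as.character(grouping)
  out <- lapply(unique(grouping), function(g) {
    idx <- grouping == g
    vol <- hullVolume(sc[idx, seq_len(dim), drop = FALSE])
    nInd <- sum(idx)
    nSpc <- if (is.null(speciesOf)) NA_integer_
            else length(unique(speciesOf[idx]))
    data.frame(taxon = g, dim = dim, volume = vol,
               n_species = nSpc, n_individuals = nInd,
               rchs = if (!is.na(nSpc) && nSpc > 0) vol / nSpc else NA_real_,
               rchi = if (nInd > 0) vol / nInd else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
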