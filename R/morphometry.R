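#' Least-squares intersection of suspension axes
#'
#' The center of mass of a suspended specimen lies on the vertical line
#' through each suspension point; with two or more coregistered suspension
#' photographs the COM is the common intersection of those lines. With
#' noisy axes the lines are not exactly concurrent, so the COM is taken as
#' the point minimizing the summed squared perpendicular distances to all
#' lines (normal equations of the line-bundle least-squares problem).
#'
#' @param points Matrix (one row per line) of points on each line, 2 or 3
#'   columns.
#' @param directions Matrix of the corresponding line directions (need not
#'   be unit length; normalized internally).
#' @return List with \code{point} (the least-squares intersection) and
#'   \code{rms} (root-mean-square perpendicular distance to the lines).
#' @examples
#' # x = 0, y = 0 and x + y = 1 are not concurrent:
#' intersect_axes(rbind(c(0, 0), c(0, 0), c(1, 0)),
#'                rbind(c(0, 1), c(1, 0), c(1, -1)))$point  # (0.25, 0.25)
#' @export
intersect_axes <- function(points, directions) {
  points <- as.matrix(points); directions <- as.matrix(directions)
  stopifnot(nrow(points) == nrow(directions),
            ncol(points) == ncol(directions), nrow(points) >= 2)
  d <- ncol(points)
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) stop("zero-length direction")
  directions <- directions / nrm
  a <- matrix(0, d, d); b <- numeric(d)
  for (i in seq_len(nrow(points))) {
    p <- proj_complement(directions[i, ])
    a <- a + p
    b <- b + p %*% points[i, ]
  }
  if (rcond(a) < 1e-12)
    stop("all lines (near-)parallel: no unique intersection")
  x <- drop(solve(a, b))
  resid2 <- vapply(seq_len(nrow(points)), function(i) {
    v <- x - points[i, ]
    sum(v^2) - sum(v * directions[i, ])^2
  }, numeric(1))
  list(point = x, rms = sqrt(mean(pmax(resid2, 0))))
}

proj_complement <- function(u) diag(length(u)) - tcrossprod(u)

#' Centroid of a binary voxel mask (center of buoyancy)
#'
#' The center of buoyancy is the unweighted centroid of the segmented
#' swim-bladder volume: the mean X, Y and Z coordinates of the occupied
#' voxels, scaled by the voxel size. Grid input uses zero-based voxel
#' coordinates (voxel \code{[1,1,1]} sits at the origin), so a solid
#' 10-cube with unit voxels has centroid (4.5, 4.5, 4.5).
#'
#' @param mask Either a 3D logical/0-1 array, or an n x 3 matrix of voxel
#'   coordinates (used as given).
#' @param voxel_size Length-1 or length-3 voxel edge lengths.
#' @return Numeric length-3 centroid in physical units.
#' @export
cob_from_mask <- function(mask, voxel_size = 1) {
  voxel_size <- rep_len(voxel_size, 3)
  stopifnot(all(voxel_size > 0))
  if (is.matrix(mask) && ncol(mask) == 3) {
    coords <- mask
  } else {
    stopifnot(length(dim(mask)) == 3)
    idx <- which(mask != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty mask: no occupied voxel")
    coords <- idx - 1
  }
  if (nrow(coords) == 0) stop("empty mask: no occupied voxel")
  colMeans(coords) * voxel_size
}

#' Read a voxel mask
#'
#' Plain-text voxel lists have one \code{x y z} coordinate triple per line
#' (whitespace-separated, \code{#} comments allowed). Multi-page TIFF
#' stacks (one page per z-slice) are read via the \pkg{tiff} package when
#' available and binarized at > 0.
#'
#' @param path File path (\code{.tif}/\code{.tiff} or text).
#' @return An n x 3 coordinate matrix (text input) or a 3D 0/1 array
#'   (TIFF input), both accepted by \code{\link{cob_from_mask}}.
#' @export
read_voxel_mask <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF masks requires the 'tiff' package")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(lapply(pages, function(m) (m > 0) * 1))
    return(arr)
  }
  m <- as.matrix(read.table(path, comment.char = "#"))
  stopifnot(ncol(m) == 3)
  dimnames(m) <- NULL
  m
}

#' Construct a body frame
#'
#' Lateral-view reference geometry used to express COM/COB positions as
#' dimensionless proportions: the snout-to-caudal-peduncle axis for the
#' anterior–posterior direction and the dorsal/ventral extremes for the
#' dorsal–ventral span (dorsal-most point is the origin of the DV axis).
#'
#' @param snout,caudal_peduncle,dorsal_extreme,ventral_extreme 2D (or 3D)
#'   points.
#' @param tl,mbd,mbw Total length, maximum body depth, maximum body width
#'   (same length units); all positive.
#' @return Object of class \code{body_frame}.
#' @export
body_frame <- function(snout, caudal_peduncle, dorsal_extreme,
                       ventral_extreme, tl, mbd, mbw) {
  stopifnot(tl > 0, mbd > 0, mbw > 0,
            !isTRUE(all.equal(snout, caudal_peduncle)))
  structure(list(snout = snout, caudal_peduncle = caudal_peduncle,
                 dorsal_extreme = dorsal_extreme,
                 ventral_extreme = ventral_extreme,
                 tl = tl, mbd = mbd, mbw = mbw),
            class = "body_frame")
}

#' Proportional position of a point within the body frame
#'
#' The anterior–posterior coordinate is the projection of the point onto
#' the snout-to-peduncle axis as a fraction of axis length (snout = 0).
#' The dorsal–ventral coordinate is the perpendicular offset from the
#' dorsal-most point as a fraction of the dorsal–ventral span (dorsal = 0,
#' ventral = 1), measured along the normal to the body axis.
#'
#' @param point 2D (or 3D) point.
#' @param frame A \code{\link{body_frame}}.
#' @return Named numeric: \code{ap}, \code{dv}. Projections outside
#'   \code{[-0.1, 1.1]} of the axis trigger a warning (likely mislabeled
#'   landmark).
#' @export
proportional_position <- function(point, frame) {
  stopifnot(inherits(frame, "body_frame"))
  axis <- frame$caudal_peduncle - frame$snout
  ap <- sum((point - frame$snout) * axis) / sum(axis^2)
  if (ap < -0.1 || ap > 1.1)
    warning(sprintf(
      "point projects at %.2f of the body axis: landmark may be mislabeled",
      ap))
  span <- frame$ventral_extreme - frame$dorsal_extreme
  nrm <- span - axis * sum(span * axis) / sum(axis^2)  # normal component
  if (sum(nrm^2) == 0) stop("degenerate dorsal-ventral span")
  dv <- sum((point - frame$dorsal_extreme) * nrm) / sum(nrm^2)
  c(ap = ap, dv = dv)
}

#' Signed COM minus COB proportional offsets
#'
#' Offsets are COM minus COB on each proportional axis. Because the
#' dorsal–ventral proportions use the dorsal-most point as origin, a COB
#' positioned more ventrally (lower) than the COM yields a negative
#' \code{comcob_dv}. An absolute-value variant of the anterior–posterior
#' offset is also returned (used to ask whether the COB being anterior vs
#' posterior of the COM matters, rather than the separation itself).
#'
#' @param com,cob Length-2 vectors \code{c(ap, dv)} of proportions in
#'   [0, 1].
#' @return Named numeric: \code{comcob_ap}, \code{comcob_dv},
#'   \code{comcob_ap_abs}.
#' @examples
#' com_cob_offsets(c(0.45, 0.40), c(0.50, 0.55))  # -0.05, -0.15
#' @export
com_cob_offsets <- function(com, cob) {
  stopifnot(length(com) == 2, length(cob) == 2,
            all(com >= 0 & com <= 1), all(cob >= 0 & cob <= 1))
  d <- unname(com - cob)
  c(comcob_ap = d[1], comcob_dv = d[2], comcob_ap_abs = abs(d[1]))
}

#' Fineness ratios
#'
#' Total length over maximum body depth (TL/MBD) and over maximum body
#' width (TL/MBW); high values describe elongated, thin bodies.
#'
#' @param frame A \code{\link{body_frame}} (or anything with \code{tl},
#'   \code{mbd}, \code{mbw}).
#' @return Named numeric: \code{fineness_depth}, \code{fineness_width}.
#' @export
fineness <- function(frame) {
  if (frame$mbd <= 0 || frame$mbw <= 0) stop("MBD and MBW must be positive")
  c(fineness_depth = frame$tl / frame$mbd,
    fineness_width = frame$tl / frame$mbw)
}

#' Assemble a per-species morphometrics record
#'
#' One row of the design matrix used by the regression stage: mass,
#' fineness ratios, proportional COM and COB coordinates with their signed
#' offsets, and fin positions. Fin positions are the anterior–posterior
#' proportions of the fin-base landmarks (whether base or insertion
#' midpoint is used for the pectoral fin is configurable upstream; base is
#' the default convention here).
#'
#' @param species Species label.
#' @param mass Mass (kg).
#' @param frame A \code{\link{body_frame}}.
#' @param com,cob Proportional positions \code{c(ap, dv)} from
#'   \code{\link{proportional_position}}.
#' @param pect_fin_ap,caud_fin_ap Fin positions as AP proportions.
#' @return One-row data frame.
#' @export
morphometrics_record <- function(species, mass, frame, com, cob,
                                 pect_fin_ap, caud_fin_ap) {
  stopifnot(mass > 0, pect_fin_ap >= 0, pect_fin_ap <= 1,
            caud_fin_ap >= 0, caud_fin_ap <= 1.1)
  fr <- fineness(frame)
  off <- com_cob_offsets(com, cob)
  data.frame(species = species, mass = mass,
             fineness_depth = unname(fr[1]), fineness_width = unname(fr[2]),
             com_ap = unname(com[1]), com_dv = unname(com[2]),
             cob_ap = unname(cob[1]), cob_dv = unname(cob[2]),
             comcob_ap = unname(off[1]), comcob_dv = unname(off[2]),
             comcob_ap_abs = unname(off[3]),
             pect_fin_ap = pect_fin_ap, caud_fin_ap = caud_fin_ap,
             stringsAsFactors = FALSE)
}
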