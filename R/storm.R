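# STORM post-processing: localization filtering, DBSCAN molecule calling
# (a molecule = cluster of >= min_points localizations within eps), and
# two-channel molecule ratios inside ROIs. All coordinates in nanometers.

#' Filter STORM localizations by photon count and axial position
#'
#' Keeps points with \code{photons >= min_photons} and z in the closed
#' interval \code{[z_min, z_max]} (default the +/-300 nm astigmatic
#' calibration range). Removal counts per criterion are attached as the
#' \code{"filter_log"} attribute.
#'
#' @param cloud A \code{storm_cloud}.
#' @param min_photons Minimum photon count (default 0 = no photon filter).
#' @param z_min,z_max Axial band, nm (defaults -300 and 300).
#' @return Filtered \code{storm_cloud}.
#' @export
filter_localizations <- function(cloud, min_photons = 0,
                                 z_min = -300, z_max = 300) {
  stopifnot(inherits(cloud, "storm_cloud"))
  ok_ph <- cloud$photons >= min_photons
  ok_z <- cloud$points[, 3] >= z_min & cloud$points[, 3] <= z_max
  keep <- ok_ph & ok_z
  out <- storm_cloud(cloud$points[keep, , drop = FALSE],
                     cloud$photons[keep], cloud$channel[keep])
  attr(out, "filter_log") <- c(n_in = length(keep),
                               fail_photons = sum(!ok_ph),
                               fail_z = sum(!ok_z),
                               kept = sum(keep))
  out
}

#' Optional local-density pre-filter
#'
#' Discards localizations with fewer than \code{k} neighbors (excluding
#' the point itself) within radius \code{r}. Off by default in every
#' pipeline; provided for parity with interactive STORM post-processing
#' tools.
#'
#' @param cloud A \code{storm_cloud}.
#' @param k Minimum neighbor count (default 2).
#' @param r Neighborhood radius, nm (default 150).
#' @return Filtered \code{storm_cloud}.
#' @export
filter_local_density <- function(cloud, k = 2L, r = 150) {
  stopifnot(inherits(cloud, "storm_cloud"))
  n <- nrow(cloud$points)
  if (n == 0L) return(cloud)
  counts <- neighbor_counts_cpp(cloud$points, r) - 1L
  keep <- counts >= k
  storm_cloud(cloud$points[keep, , drop = FALSE],
              cloud$photons[keep], cloud$channel[keep])
}

#' Call molecules from a localization cloud by DBSCAN
#'
#' Standard DBSCAN in Euclidean nm coordinates: a core point has at least
#' \code{min_points} localizations (counting itself) within \code{eps};
#' clusters are connected components of core points plus the border points
#' they reach; everything else is noise. Border points reachable from more
#' than one cluster attach to the cluster of their nearest core point (a
#' point-order-invariant rule). Each cluster's unweighted center of mass
#' represents one molecule.
#'
#' @param cloud A \code{storm_cloud} carrying a single channel.
#' @param eps Neighborhood radius, nm (default 100).
#' @param min_points Minimum localizations within \code{eps} including the
#'   point itself (default 3).
#' @param xy_only Cluster on lateral (x, y) distance only, ignoring z
#'   (default FALSE: full 3D metric).
#' @return List: \code{molecules} (data.frame \code{cluster}, \code{x_nm},
#'   \code{y_nm}, \code{z_nm}, \code{n_members}, \code{channel}),
#'   \code{labels} (per-point cluster index, 0 = noise),
#'   \code{n_noise}.
#' @export
dbscan_molecules <- function(cloud, eps = 100, min_points = 3L,
                             xy_only = FALSE) {
  stopifnot(inherits(cloud, "storm_cloud"), eps > 0, min_points >= 1L)
  n <- nrow(cloud$points)
  channel <- if (n > 0L) unique(cloud$channel) else "1"
  if (length(channel) > 1L)
    stop("dbscan_molecules expects a single channel; split the cloud first",
         call. = FALSE)
  empty <- list(molecules = data.frame(cluster = integer(0),
                                       x_nm = numeric(0), y_nm = numeric(0),
                                       z_nm = numeric(0),
                                       n_members = integer(0),
                                       channel = character(0),
                                       stringsAsFactors = FALSE),
                labels = integer(0), n_noise = 0L)
  if (n == 0L) return(empty)
  metric_pts <- if (xy_only) cloud$points[, 1:2, drop = FALSE]
                else cloud$points
  counts <- neighbor_counts_cpp(metric_pts, eps)
  core <- counts >= min_points
  labels <- integer(n)
  eps2 <- eps^2
  nbrs_of <- function(i) {
    d2 <- colSums((t(metric_pts) - metric_pts[i, ])^2)
    which(d2 <= eps2)
  }
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- i
    while (length(frontier)) {
      nxt <- integer(0)
      for (p in frontier) {
        nb <- nbrs_of(p)
        newcore <- nb[core[nb] & labels[nb] == 0L]
        labels[newcore] <- cl
        nxt <- c(nxt, newcore)
      }
      frontier <- unique(nxt)
    }
  }
  # border points: non-core within eps of a core; nearest core decides
  border <- which(!core & labels == 0L)
  for (i in border) {
    d2 <- colSums((t(metric_pts) - metric_pts[i, ])^2)
    cand <- which(core & d2 <= eps2)
    if (length(cand))
      labels[i] <- labels[cand[which.min(d2[cand])]]
  }
  if (cl == 0L) {
    out <- empty
    out$labels <- labels
    out$n_noise <- n
    return(out)
  }
  # renumber clusters by centroid lexicographic order for determinism
  cents <- t(vapply(seq_len(cl), function(k)
    colMeans(cloud$points[labels == k, , drop = FALSE]), numeric(3)))
  ord <- order(cents[, 1], cents[, 2], cents[, 3])
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  cents <- cents[ord, , drop = FALSE]
  sizes <- tabulate(labels, nbins = cl)
  list(molecules = data.frame(cluster = seq_len(cl),
                              x_nm = cents[, 1], y_nm = cents[, 2],
                              z_nm = cents[, 3], n_members = sizes,
                              channel = rep(channel, cl),
                              stringsAsFactors = FALSE),
       labels = labels,
       n_noise = sum(labels == 0L))
}

# even-odd point-in-polygon with boundary counted as inside
point_in_polygon <- function(px, py, vertices, tol = 1e-9) {
  vx <- vertices[, 1]; vy <- vertices[, 2]
  nv <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- nv
    for (k in seq_len(nv)) {
      x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[k]; y2 <- vy[k]
      # on-segment check
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- ((x - x1) * dx + (y - y1) * dy) / len2
        t <- min(max(t, 0), 1)
        if ((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2 <= tol^2)
          return(TRUE)
      } else if ((x - x1)^2 + (y - y1)^2 <= tol^2) {
        return(TRUE)
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

#' Count molecule centers inside an ROI polygon
#'
#' Even-odd (ray casting) rule; centers exactly on the boundary count as
#' inside. The z coordinate is ignored (ROIs are drawn in the lateral
#' plane).
#'
#' @param molecules Molecule set from \code{\link{dbscan_molecules}} (the
#'   \code{molecules} data.frame, or the full list).
#' @param roi An \code{roi_polygon} in nm.
#' @return Integer count.
#' @export
count_molecules_in_roi <- function(molecules, roi) {
  if (is.list(molecules) && !is.data.frame(molecules) &&
      "molecules" %in% names(molecules))
    molecules <- molecules$molecules
  stopifnot(is.data.frame(molecules), inherits(roi, "roi_polygon"))
  v <- roi$vertices
  # degenerate: zero-area polygon
  area2 <- sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                 c(v[-1, 1], v[1, 1]) * v[, 2])
  if (abs(area2) < 1e-12)
    stop(sprintf("degenerate ROI polygon '%s' (zero area)", roi$label),
         call. = FALSE)
  if (nrow(molecules) == 0L) return(0L)
  sum(point_in_polygon(molecules$x_nm, molecules$y_nm, v))
}

#' Two-channel molecule ratio within an ROI
#'
#' Ratio of molecule counts (channel a over channel b) inside one ROI —
#' e.g. membrane estrogen receptor over AMPA receptor molecules in a soma
#' or neurite ROI.
#'
#' @param molecules_a,molecules_b Molecule sets (see
#'   \code{\link{count_molecules_in_roi}}).
#' @param roi An \code{roi_polygon} in nm.
#' @return List: \code{ratio}, \code{n_a}, \code{n_b}, \code{label}.
#' @export
receptor_ratio <- function(molecules_a, molecules_b, roi) {
  n_a <- count_molecules_in_roi(molecules_a, roi)
  n_b <- count_molecules_in_roi(molecules_b, roi)
  if (n_b == 0L)
    stop(sprintf("ROI '%s': zero denominator molecules, ratio undefined",
                 roi$label), call. = FALSE)
  list(ratio = n_a / n_b, n_a = n_a, n_b = n_b, label = roi$label)
}
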