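#' Exact k-nearest-neighbor distances
#'
#' Distances from every point to its `kmax` nearest neighbors (the query point
#' itself excluded), computed by exact brute force under the cloud's boundary
#' convention. Ties are resolved by the order statistic itself: equal distances
#' yield equal radii, and neighbor identity never enters the result.
#'
#' @param cloud a [point_cloud], or a matrix (taken with the `boundary`
#'   argument).
#' @param kmax number of neighbor distances per point.
#' @param boundary used only when `cloud` is a bare matrix.
#' @return An `n x kmax` matrix; column `j` holds the distance to the j-th
#'   nearest neighbor.
#' @export
knn_distances <- function(cloud, kmax, boundary = "hard") {
  cloud <- as_point_cloud(cloud, boundary)
  n <- nrow(cloud$coords)
  kmax <- as.integer(kmax)
  if (kmax < 1L) stop("kmax must be a positive integer")
  if (kmax > n - 1L)
    stop(sprintf("kmax = %d needs more than %d points", kmax, n))
  .knn_dists_cpp(cloud$coords, kmax, cloud$boundary == "periodic")
}

#' Two-scale neighbor radii
#'
#' The distances to the k-th and 2k-th nearest neighbor of every point --- the
#' two order statistics the local dimension estimate is built from. Requires
#' `n > 2k`.
#'
#' @inheritParams knn_distances
#' @param k neighborhood size.
#' @return An object of class `neighbor_radii`: a list with `k`, `r_k` and
#'   `r_2k` (length-n vectors, `r_k <= r_2k` elementwise).
#' @seealso [local_fsa()]
#' @export
knn_radii <- function(cloud, k, boundary = "hard") {
  cloud <- as_point_cloud(cloud, boundary)
  n <- nrow(cloud$coords)
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (n <= 2L * k)
    stop(sprintf("need n > 2k (n = %d, k = %d)", n, k))
  d <- knn_distances(cloud, 2L * k)
  structure(list(k = k, r_k = d[, k], r_2k = d[, 2L * k]),
            class = "neighbor_radii")
}

#' @export
print.neighbor_radii <- function(x, ...) {
  cat(sprintf("neighbor radii: n = %d, k = %d\n", length(x$r_k), x$k))
  invisible(x)
}
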