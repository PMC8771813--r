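#' Point clouds with a boundary convention
#'
#' A point cloud is an \eqn{n \times m} matrix of sample coordinates together
#' with a distance convention: `"hard"` (plain Euclidean) or `"periodic"`
#' (Euclidean on the unit torus, each coordinate difference replaced by its
#' minimum image \eqn{\min(|\Delta|, 1-|\Delta|)}). The periodic convention is
#' only meaningful for data in \eqn{[0,1)^m} and is used to remove edge effects
#' in simulations; clouds with coordinates outside \eqn{[0,1)} are rejected
#' rather than wrapped silently.
#'
#' @param x numeric matrix or data frame, one row per sample point.
#' @param boundary `"hard"` or `"periodic"`.
#' @param label optional free-text label carried along for printing.
#' @return An object of class `point_cloud`: a list with elements `coords`
#'   (numeric matrix), `boundary` and `label`.
#' @examples
#' pc <- point_cloud(matrix(runif(20), 10, 2), boundary = "periodic")
#' dim(as.matrix(pc))
#' @export
point_cloud <- function(x, boundary = c("hard", "periodic"), label = NULL) {
  boundary <- match.arg(boundary)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("point cloud must have at least one row and one column")
  if (!all(is.finite(x)))
    stop("point cloud coordinates must all be finite")
  if (boundary == "periodic" && (any(x < 0) || any(x >= 1)))
    stop("periodic boundary requires all coordinates in [0, 1)")
  structure(list(coords = x, boundary = boundary, label = label),
            class = "point_cloud")
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$coords

#' @export
dim.point_cloud <- function(x) dim(x$coords)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point cloud: %d points in %d coordinates (%s boundary)%s\n",
              nrow(x$coords), ncol(x$coords), x$boundary,
              if (is.null(x$label)) "" else paste0(" - ", x$label)))
  invisible(x)
}

# Coerce matrices / data frames on the fly; boundary applies only then.
as_point_cloud <- function(x, boundary = "hard") {
  if (inherits(x, "point_cloud")) x else point_cloud(x, boundary = boundary)
}

#' Distance between two points under a boundary convention
#'
#' Euclidean distance for `"hard"` boundaries; minimum-image Euclidean distance
#' on the unit torus for `"periodic"`.
#'
#' @param a,b numeric coordinate vectors of equal length.
#' @param boundary `"hard"` or `"periodic"`.
#' @return A nonnegative scalar distance.
#' @examples
#' pair_distance(c(0, 0), c(3, 4), "hard")          # 5
#' pair_distance(0.05, 0.95, "periodic")            # 0.1, wrapping around
#' @export
pair_distance <- function(a, b, boundary = c("hard", "periodic")) {
  boundary <- match.arg(boundary)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("coordinate vectors must have the same length")
  d <- a - b
  if (boundary == "periodic") {
    if (any(a < 0) || any(a >= 1) || any(b < 0) || any(b >= 1))
      stop("periodic boundary requires all coordinates in [0, 1)")
    d <- abs(d)
    d <- pmin(d, 1 - d)
  }
  sqrt(sum(d * d))
}

#' Read or write a point cloud as delimited text
#'
#' One row per point; comma or tab delimited; an optional single header row.
#' The boundary convention is not stored in the file and is declared by the
#' caller (or by a command-line flag).
#'
#' @param path file path.
#' @param boundary distance convention to attach to the cloud.
#' @param header does the file carry a header row?
#' @param sep field delimiter; `""` guesses between comma and tab.
#' @return `read_point_cloud` returns a [point_cloud]; `write_point_cloud`
#'   returns `path` invisibly.
#' @export
read_point_cloud <- function(path, boundary = c("hard", "periodic"),
                             header = FALSE, sep = "") {
  boundary <- match.arg(boundary)
  if (sep == "") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  x <- read.table(path, header = header, sep = sep)
  point_cloud(x, boundary = boundary)
}

#' @param cloud a [point_cloud] (or bare matrix) to write.
#' @rdname read_point_cloud
#' @export
write_point_cloud <- function(cloud, path, sep = ",") {
  x <- if (inherits(cloud, "point_cloud")) cloud$coords else as.matrix(cloud)
  write.table(x, path, sep = sep, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
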