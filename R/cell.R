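#' Construct a unit cell
#'
#' A unit cell is described by its three axis lengths (Angstrom) and three
#' inter-axial angles (degrees).  The object is validated on construction:
#' lengths must be positive, angles must lie strictly inside (0, 180), and
#' the metric-tensor volume must be positive (which excludes impossible
#' angle combinations such as alpha + beta + gamma >= 360).
#'
#' @param a,b,c axis lengths in Angstrom.
#' @param alpha,beta,gamma inter-axial angles in degrees.
#' @return An object of class `"unit_cell"`: a named numeric vector
#'   `(a, b, c, alpha, beta, gamma)`.
#' @examples
#' uc <- unit_cell(40, 50, 60)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  x <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(x)))
    stop("unit cell parameters must be finite numbers")
  if (any(x[1:3] <= 0))
    stop("unit cell lengths must be positive")
  if (any(x[4:6] <= 0) || any(x[4:6] >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees")
  cell <- structure(x, class = "unit_cell")
  if (!is.finite(cell_volume(cell)) || cell_volume(cell) <= 0)
    stop("unit cell angles are geometrically impossible (non-positive volume)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x["a"], x["b"], x["c"], x["alpha"], x["beta"], x["gamma"],
              cell_volume(x)))
  invisible(x)
}

as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(x)
  x <- unlist(x)
  if (length(x) != 6) stop("expected 6 unit-cell parameters")
  unit_cell(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]])
}

#' Direct-space metric tensor of a unit cell
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix `G` with `G[i,j] = a_i . a_j`.
#' @keywords internal
metric_tensor <- function(cell) {
  cell <- as_unit_cell(cell)
  ca <- cos(cell["alpha"] * pi / 180)
  cb <- cos(cell["beta"]  * pi / 180)
  cg <- cos(cell["gamma"] * pi / 180)
  a <- cell["a"]; b <- cell["b"]; c <- cell["c"]
  m <- matrix(c(a * a,      a * b * cg, a * c * cb,
                a * b * cg, b * b,      b * c * ca,
                a * c * cb, b * c * ca, c * c), 3, 3)
  dimnames(m) <- NULL
  m
}

#' Unit-cell volume
#'
#' @param cell a [unit_cell()].
#' @return volume in cubic Angstrom (square root of the metric determinant).
#' @export
cell_volume <- function(cell) {
  d <- det(metric_tensor(cell))
  if (d <= 0) return(NA_real_)
  sqrt(d)
}

#' Resolution (d-spacing) of reflections
#'
#' Computes the d-spacing of one or more Miller indices from the reciprocal
#' metric tensor: `1/d^2 = h' G* h`.  For orthogonal cells this reduces to
#' the familiar `1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2`.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer vector of length 3, or an n x 3 matrix of indices.
#' @return numeric vector of d-spacings in Angstrom.
#' @examples
#' resolution_of(unit_cell(10, 20, 30), c(0, 2, 0))  # 10 A
#' @export
resolution_of <- function(cell, hkl) {
  hkl <- as_hkl_matrix(hkl)
  if (any(rowSums(abs(hkl)) == 0))
    stop("the (0,0,0) index has no resolution")
  gstar <- solve(metric_tensor(cell))
  q <- rowSums((hkl %*% gstar) * hkl)   # 1/d^2
  1 / sqrt(q)
}

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    if (ncol(hkl) != 3) stop("hkl matrix must have 3 columns")
    return(hkl)
  }
  if (length(hkl) != 3) stop("hkl must be a length-3 vector or n x 3 matrix")
  matrix(as.numeric(hkl), 1, 3)
}
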