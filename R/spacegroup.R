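# Symmetry handling: space-group operator lists, mapping of Miller indices
# to a canonical asymmetric-unit representative, and systematic absences.
#
# An operator acts on fractional coordinates as x' = R x + t.  Its action on
# a Miller index (row vector) is h' = h R.  A reflection is systematically
# absent when some operator fixes it (h R = h) while h . t is non-integral.

#' Build a symmetry operator
#'
#' @param rot 3x3 integer rotation part, or a length-9 vector read
#'   row-wise (coordinate-triplet order).
#' @param trans translation as fractions of the cell edges (reduced mod 1).
#' @return operator list `(rot, trans)` for [space_group()].
#' @export
sg_op <- function(rot, trans = c(0, 0, 0)) {
  rot <- if (is.matrix(rot)) {
    matrix(as.integer(rot), 3, 3)
  } else {
    # plain vectors are read row-wise, matching coordinate-triplet order
    matrix(as.integer(rot), 3, 3, byrow = TRUE)
  }
  trans <- as.numeric(trans) %% 1
  list(rot = rot, trans = trans)
}

# built-in operator tables (International Tables settings)
.builtin_sg <- function(symbol) {
  I3 <- diag(3)
  switch(symbol,
    "P1" = list(sg_op(I3)),
    "P21" = list(   # unique axis b
      sg_op(I3),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 0))),
    "C2" = list(    # unique axis b, C-centred
      sg_op(I3),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1)),
      sg_op(I3, c(1 / 2, 1 / 2, 0)),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 0))),
    "P212121" = list(
      sg_op(I3),
      sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(1 / 2, 0, 1 / 2)),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(0, 1 / 2, 1 / 2)),
      sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 0))),
    "P43212" = list(
      sg_op(I3),
      sg_op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      sg_op(c(0, -1, 0, 1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 3 / 4)),
      sg_op(c(0, 1, 0, -1, 0, 0, 0, 0, 1), c(1 / 2, 1 / 2, 1 / 4)),
      sg_op(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 3 / 4)),
      sg_op(c(1, 0, 0, 0, -1, 0, 0, 0, -1), c(1 / 2, 1 / 2, 1 / 4)),
      sg_op(c(0, 1, 0, 1, 0, 0, 0, 0, -1)),
      sg_op(c(0, -1, 0, -1, 0, 0, 0, 0, -1), c(0, 0, 1 / 2))),
    stop("unknown built-in space group symbol: ", symbol,
         " (built-ins: P1, P21, C2, P212121, P43212)")
  )
}

#' Construct a space-group specification
#'
#' Either one of the built-in symbols (`"P1"`, `"P21"`, `"C2"`,
#' `"P212121"`, `"P43212"`) or an explicit operator list may be given; the
#' operator set is validated for group closure, presence of the identity,
#' and translations reduced mod 1.  Friedel merging (treating `(h,k,l)` and
#' `(-h,-k,-l)` as equivalent) is on by default and should be switched off
#' when anomalous differences are of interest.
#'
#' @param symbol text label of the group.
#' @param operators optional list of operators, each a
#'   `list(rot = <3x3 integer matrix>, trans = <length-3 fractions>)` acting
#'   on fractional coordinates; required for non-built-in symbols.
#' @param friedel_merged logical; merge Friedel mates?
#' @return object of class `"space_group"` with elements `symbol`,
#'   `operators`, `friedel_merged`, and a precomputed array of rotation
#'   parts.
#' @examples
#' sg <- space_group("P212121")
#' map_to_asu(c(-1, -2, 3), sg)
#' @export
space_group <- function(symbol, operators = NULL, friedel_merged = TRUE) {
  if (is.null(operators)) operators <- .builtin_sg(symbol)
  operators <- lapply(operators, function(op) sg_op(op$rot, op$trans))
  .check_group(operators)
  structure(list(symbol = symbol,
                 operators = operators,
                 friedel_merged = isTRUE(friedel_merged)),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s: %d operators, Friedel %s\n", x$symbol,
              length(x$operators),
              if (x$friedel_merged) "merged" else "unmerged"))
  invisible(x)
}

# closure under composition, identity present, translations mod 1
.check_group <- function(ops) {
  keys <- vapply(ops, .op_key, "")
  if (anyDuplicated(keys)) stop("duplicate symmetry operators")
  if (!any(vapply(ops, function(op)
    all(op$rot == diag(3)) && all(op$trans == 0), TRUE)))
    stop("operator list lacks the identity")
  for (i in seq_along(ops)) for (j in seq_along(ops)) {
    rot <- ops[[i]]$rot %*% ops[[j]]$rot
    trans <- (as.vector(ops[[i]]$rot %*% ops[[j]]$trans) + ops[[i]]$trans) %% 1
    key <- .op_key(list(rot = rot, trans = trans))
    if (!key %in% keys)
      stop("operator set not closed under composition")
  }
  invisible(TRUE)
}

.op_key <- function(op) {
  paste(c(as.integer(op$rot), round(op$trans %% 1, 9)), collapse = ",")
}

as_space_group <- function(x, friedel_merged = NULL) {
  sg <- if (inherits(x, "space_group")) x else space_group(x)
  if (!is.null(friedel_merged)) sg$friedel_merged <- isTRUE(friedel_merged)
  sg
}

# encode hkl rows into a single orderable number; exact for |index| < 2048
.hkl_key <- function(hkl) {
  (hkl[, 1] + 2048) * 4096^2 + (hkl[, 2] + 2048) * 4096 + (hkl[, 3] + 2048)
}

.hkl_unkey <- function(key) {
  l <- key %% 4096 - 2048
  k <- (key %/% 4096) %% 4096 - 2048
  h <- key %/% 4096^2 - 2048
  cbind(h = h, k = k, l = l)
}

# all rotation images of each row of hkl: returns list of n x 3 matrices
.rot_images <- function(hkl, sg) {
  lapply(sg$operators, function(op) hkl %*% op$rot)
}

#' Map Miller indices to their canonical asymmetric-unit representative
#'
#' The canonical representative of a symmetry orbit is defined as the
#' lexicographically largest `(h, k, l)` among all rotation images (plus
#' Friedel mates when the group merges them).  This choice needs no
#' per-space-group boundary tables and is deterministic.  `map_to_asu` is
#' idempotent.
#'
#' @param hkl length-3 vector or n x 3 matrix of Miller indices.
#' @param sg a [space_group()] (or built-in symbol).
#' @param friedel_merged optional override of the group's Friedel flag.
#' @return a data.frame with columns `h, k, l` (canonical indices) and
#'   `friedel_sign` (+1 when the canonical index is a rotation image of the
#'   input, -1 when it is reached only through the Friedel mate; centric
#'   reflections always get +1).
#' @export
map_to_asu <- function(hkl, sg, friedel_merged = NULL) {
  sg <- as_space_group(sg, friedel_merged)
  hkl <- as_hkl_matrix(hkl)
  plus <- .canon_rot(hkl, sg)
  if (!sg$friedel_merged) {
    return(data.frame(.hkl_unkey(plus), friedel_sign = 1L))
  }
  minus <- .canon_rot(-hkl, sg)
  key <- pmax(plus, minus)
  data.frame(.hkl_unkey(key),
             friedel_sign = ifelse(plus >= minus, 1L, -1L))
}

# canonical key under rotation parts only
.canon_rot <- function(hkl, sg) {
  best <- NULL
  for (im in .rot_images(hkl, sg)) {
    key <- .hkl_key(im)
    best <- if (is.null(best)) key else pmax(best, key)
  }
  best
}

#' Systematic absence test
#'
#' A reflection is systematically absent when some symmetry operator fixes
#' its index (`h R = h`) while the phase shift `h . t` is non-integral.
#' This operator-based rule reproduces the textbook screw-axis and
#' centring absence conditions without per-group tables.
#'
#' @param hkl length-3 vector or n x 3 matrix.
#' @param sg a [space_group()] (or symbol).
#' @return logical vector, `TRUE` for absent reflections.
#' @examples
#' is_absent(c(0, 1, 0), space_group("P21"))  # TRUE: 2_1 screw along b
#' @export
is_absent <- function(hkl, sg) {
  sg <- as_space_group(sg)
  hkl <- as_hkl_matrix(hkl)
  absent <- rep(FALSE, nrow(hkl))
  for (op in sg$operators) {
    im <- hkl %*% op$rot
    fixed <- rowSums(abs(im - hkl)) == 0
    phase <- as.vector(hkl %*% op$trans)
    absent <- absent | (fixed & abs(phase - round(phase)) > 1e-9)
  }
  absent
}

#' All distinct observable images of a reflection orbit
#'
#' Returns the distinct rotation images of each canonical index, together
#' with their Friedel mates.  This is the set of indices under which one
#' unique reflection can appear on the detector.
#'
#' @param hkl n x 3 matrix of (canonical) indices.
#' @param sg a [space_group()].
#' @return data.frame with columns `uid` (row of `hkl` the image belongs
#'   to), `h, k, l`, and `friedel_sign`.
#' @keywords internal
hkl_orbit <- function(hkl, sg) {
  sg <- as_space_group(sg)
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  ims <- .rot_images(hkl, sg)
  all_im <- do.call(rbind, c(ims, lapply(ims, function(m) -m)))
  uid <- rep.int(seq_len(n), times = 2 * length(ims))
  sign <- rep(c(1L, -1L), each = n * length(ims))
  keep <- !duplicated(cbind(uid, .hkl_key(all_im)))
  data.frame(uid = uid[keep], h = all_im[keep, 1], k = all_im[keep, 2],
             l = all_im[keep, 3], friedel_sign = sign[keep])
}

#' Enumerate unique non-absent reflections to a resolution limit
#'
#' Lists the canonical asymmetric-unit indices of every systematically
#' present reflection with `d_min <= d <= d_max`, the denominator needed
#' for completeness calculations.  The index search box uses the exact
#' bound `|h| <= a/d_min` (and likewise for k, l).
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] (Friedel setting of the group is honoured).
#' @param d_min high-resolution limit in Angstrom (> 0).
#' @param d_max low-resolution limit in Angstrom (default `Inf`).
#' @return data.frame with columns `h, k, l, d`, sorted by decreasing `d`.
#' @export
enumerate_unique_hkl <- function(cell, sg, d_min, d_max = Inf) {
  stopifnot(d_min > 0, d_max > d_min)
  cell <- as_unit_cell(cell)
  sg <- as_space_group(sg)
  lim <- floor(cell[1:3] / d_min)
  if (any(lim < 1))
    stop("d_min = ", d_min, " A admits no reflections for this cell")
  grid <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                                l = -lim[3]:lim[3]))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- resolution_of(cell, grid)
  # relative epsilon so reflections sitting exactly on the limit are kept
  keep <- d >= d_min * (1 - 1e-9) & d <= d_max * (1 + 1e-9)
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  canon <- map_to_asu(grid, sg)
  key <- .hkl_key(as.matrix(canon[, c("h", "k", "l")]))
  first <- !duplicated(key)
  uniq <- canon[first, c("h", "k", "l")]
  d <- d[first]
  present <- !is_absent(as.matrix(uniq), sg)
  out <- data.frame(uniq[present, , drop = FALSE], d = d[present])
  out <- out[order(-out$d, out$h, out$k, out$l), ]
  rownames(out) <- NULL
  out
}
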