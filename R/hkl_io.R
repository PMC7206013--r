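# Reflection-observation tables and SHELX-style fixed-width .hkl I/O.
#
# An observation table is a plain data.frame with columns
#   h, k, l        integer Miller indices
#   intensity      arbitrary linear scale
#   sigma          same scale, > 0
#   frame_id       integer >= 0
#   crystal_id     character
# The SHELX HKLF4 record layout is 3I4, 2F8.2 and an optional I4 batch
# (frame) field; a terminating all-zero index record is written on output
# and silently consumed on input.

#' Build an observation table
#'
#' @param h,k,l integer Miller indices (recycled to common length).
#' @param intensity,sigma intensities and standard deviations; `sigma` must
#'   be positive.
#' @param frame_id integer frame number (>= 0), default 0.
#' @param crystal_id character id, default `""`.
#' @return a validated observation data.frame.
#' @export
observation_table <- function(h, k, l, intensity, sigma, frame_id = 0L,
                              crystal_id = "") {
  df <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   intensity = as.numeric(intensity),
                   sigma = as.numeric(sigma),
                   frame_id = as.integer(frame_id),
                   crystal_id = as.character(crystal_id))
  validate_observations(df)
  df
}

validate_observations <- function(df) {
  need <- c("h", "k", "l", "intensity", "sigma", "frame_id", "crystal_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observation table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$sigma)) || any(df$sigma <= 0))
    stop("all sigmas must be finite and positive")
  if (any(df$h == 0 & df$k == 0 & df$l == 0))
    stop("the (0,0,0) index is not a reflection")
  if (any(df$frame_id < 0)) stop("frame ids must be >= 0")
  invisible(df)
}

#' Read a SHELX-style .hkl reflection file
#'
#' Parses fixed-width records `h k l I sigI [batch]` (3I4, 2F8.2, optional
#' I4).  Parsing stops at the conventional all-zero terminator record.
#' Malformed lines (non-numeric fields, non-positive sigma) are skipped and
#' reported, with their line numbers, in the `"diagnostics"` attribute of
#' the result.
#'
#' @param path file to read.
#' @param crystal_id crystal id to assign to all observations.
#' @return observation data.frame; attribute `diagnostics` is a
#'   data.frame `(line, message)` of skipped records (zero rows if clean).
#' @seealso [write_hkl()]
#' @export
read_hkl <- function(path, crystal_id = "") {
  if (!file.exists(path)) stop("cannot read hkl file: ", path)
  lines <- readLines(path, warn = FALSE)
  diag_line <- integer(0); diag_msg <- character(0)
  rows <- vector("list", length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    f <- .parse_hkl_line(ln)
    if (is.character(f)) {
      diag_line <- c(diag_line, i); diag_msg <- c(diag_msg, f)
      next
    }
    if (all(f[1:3] == 0)) break            # terminator record
    if (!is.finite(f[5]) || f[5] <= 0) {
      diag_line <- c(diag_line, i)
      diag_msg <- c(diag_msg, "sigma must be positive")
      next
    }
    n <- n + 1L
    rows[[n]] <- f
  }
  m <- if (n > 0) do.call(rbind, rows[seq_len(n)]) else
    matrix(numeric(0), 0, 6)
  out <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                    l = as.integer(m[, 3]), intensity = m[, 4],
                    sigma = m[, 5], frame_id = as.integer(m[, 6]),
                    crystal_id = rep(as.character(crystal_id), nrow(m)))
  attr(out, "diagnostics") <- data.frame(line = diag_line,
                                         message = diag_msg)
  out
}

# returns numeric vector (h,k,l,I,sig,frame) or a character error message
.parse_hkl_line <- function(ln) {
  if (nchar(ln) < 28) return("record shorter than 3I4+2F8.2")
  fields <- c(substr(ln, 1, 4), substr(ln, 5, 8), substr(ln, 9, 12),
              substr(ln, 13, 20), substr(ln, 21, 28))
  batch <- if (nchar(ln) >= 29) substr(ln, 29, 32) else "0"
  if (!nzchar(trimws(batch))) batch <- "0"
  vals <- suppressWarnings(as.numeric(c(fields, batch)))
  if (anyNA(vals)) return("non-numeric field")
  if (any(vals[1:3] != round(vals[1:3]))) return("non-integer index")
  vals
}

#' Write a SHELX-style .hkl reflection file
#'
#' Inverse of [read_hkl()]: emits 3I4, 2F8.2 plus an I4 batch field (the
#' frame id) and a terminating all-zero record.  Values that do not fit
#' the fixed field widths (indices beyond +-999, intensities beyond the
#' F8.2 range) raise an error rather than silently corrupting columns.
#'
#' @param table observation data.frame (see [observation_table()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hkl <- function(table, path) {
  validate_observations(table)
  if (nrow(table) > 0) {
    if (any(abs(table[, c("h", "k", "l")]) > 999))
      stop("Miller indices beyond +-999 do not fit the I4 field")
    if (any(abs(table$intensity) > 99999.99) || any(table$sigma > 99999.99))
      stop("intensities/sigmas beyond the F8.2 field range")
    if (any(table$frame_id > 9999))
      stop("frame ids beyond 9999 do not fit the I4 batch field")
  }
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f%4d",
                   table$h, table$k, table$l, table$intensity, table$sigma,
                   table$frame_id)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f%4d", 0L, 0L, 0L, 0, 0, 0L)),
             path)
  invisible(path)
}

#' Construct a single-crystal partial dataset
#'
#' Bundles one microcrystal's wedge of observations with its refined unit
#' cell and acquisition geometry (wedge start / width in degrees,
#' wavelength in Angstrom).
#'
#' @param crystal_id character id.
#' @param cell a [unit_cell()].
#' @param observations observation data.frame; its `crystal_id` column is
#'   overwritten with `crystal_id`.
#' @param wedge_start,wedge_width wedge geometry in degrees;
#'   `0 < wedge_width <= 360`.
#' @param wavelength in Angstrom.
#' @return object of class `"crystal_dataset"`.
#' @export
crystal_dataset <- function(crystal_id, cell, observations,
                            wedge_start = 0, wedge_width = 20,
                            wavelength = 0.979) {
  if (!(wedge_width > 0 && wedge_width <= 360))
    stop("wedge_width must lie in (0, 360]")
  observations$crystal_id <- as.character(crystal_id)
  validate_observations(observations)
  structure(list(crystal_id = as.character(crystal_id),
                 cell = as_unit_cell(cell),
                 wedge_start = wedge_start %% 360,
                 wedge_width = wedge_width,
                 wavelength = wavelength,
                 observations = observations),
            class = "crystal_dataset")
}

#' @export
print.crystal_dataset <- function(x, ...) {
  cat(sprintf("crystal %s: %d observations, wedge %.1f-%.1f deg\n",
              x$crystal_id, nrow(x$observations), x$wedge_start,
              x$wedge_start + x$wedge_width))
  print(x$cell)
  invisible(x)
}

#' Write / read a crystal metadata sidecar
#'
#' The sidecar (YAML) records the unit cell, wedge geometry, wavelength and
#' space group next to the plain-text reflection file.  Built-in space
#' groups are stored by symbol; arbitrary groups by an explicit operator
#' list (`rot` row-major integers, `trans` fractions).
#'
#' @param ds a [crystal_dataset()].
#' @param sg a [space_group()].
#' @param path YAML file path.
#' @return `path` invisibly (`write_sidecar`); a list
#'   `(dataset-fields, sg)` for `read_sidecar`.
#' @export
write_sidecar <- function(ds, sg, path) {
  sgspec <- if (tryCatch({.builtin_sg(sg$symbol); TRUE},
                         error = function(e) FALSE)) {
    list(symbol = sg$symbol, friedel_merged = sg$friedel_merged)
  } else {
    list(symbol = sg$symbol, friedel_merged = sg$friedel_merged,
         operators = lapply(sg$operators, function(op)
           list(rot = as.integer(t(op$rot)), trans = op$trans)))
  }
  yaml::write_yaml(list(
    crystal_id = ds$crystal_id,
    cell = as.list(stats::setNames(as.numeric(ds$cell), names(ds$cell))),
    wedge_start = ds$wedge_start,
    wedge_width = ds$wedge_width,
    wavelength = ds$wavelength,
    space_group = sgspec), path)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  y <- yaml::read_yaml(path)
  sgspec <- y$space_group
  sg <- if (is.null(sgspec$operators)) {
    space_group(sgspec$symbol, friedel_merged = isTRUE(sgspec$friedel_merged))
  } else {
    space_group(sgspec$symbol,
                operators = lapply(sgspec$operators, function(op)
                  sg_op(op$rot, op$trans)),
                friedel_merged = isTRUE(sgspec$friedel_merged))
  }
  list(crystal_id = y$crystal_id,
       cell = do.call(unit_cell, y$cell),
       wedge_start = y$wedge_start,
       wedge_width = y$wedge_width,
       wavelength = y$wavelength,
       sg = sg)
}

# pool observations from a list of crystal_dataset objects, attaching s^2
# (= 1/d^2 from each crystal's own cell)
pool_observations <- function(datasets) {
  stopifnot(length(datasets) > 0)
  obs <- do.call(rbind, lapply(datasets, function(ds) {
    o <- ds$observations
    o$s2 <- 1 / resolution_of(ds$cell, as.matrix(o[, c("h", "k", "l")]))^2
    o
  }))
  rownames(obs) <- NULL
  obs
}
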