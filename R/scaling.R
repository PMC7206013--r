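# Iterative relative scaling of partial datasets.
#
# Model: I_obs(h, j) ~ k_j * exp(-2 B_j s^2 / 4) * <I(h)>, where j indexes
# the scaling group (a crystal, or a frame when per-frame scaling is on;
# frames inherit their crystal's B and contribute only a scale).  The fit
# alternates (1) inverse-variance merging of currently inverse-scaled
# intensities to reference means with (2) per-crystal weighted
# least-squares refinement of (k, B): k has a closed form given B, and B
# is refined by 1-D minimisation.  The gauge (overall scale/B origin) is
# fixed by mean(log k) = 0 and mean(B) = 0.

#' Fit per-crystal (optionally per-frame) scale factors
#'
#' @param datasets list of [crystal_dataset()] objects (>= 2).
#' @param sg a [space_group()] used to merge symmetry mates.
#' @param per_frame logical; when `TRUE` each frame gets its own
#'   multiplicative scale (B stays per-crystal).
#' @param max_iter maximum alternating iterations (default 100).
#' @param tol convergence threshold on the largest relative parameter
#'   shift (default 1e-6).
#' @param min_common minimum number of shared unique reflections for two
#'   crystals to count as connected (default 20); the fit refuses
#'   disconnected collections and names the components.
#' @param init optional previous `"scaling_model"` used as warm start
#'   (ids absent from it start at k = 1, B = 0).
#' @return object of class `"scaling_model"`: list with `params` (a
#'   data.frame `crystal_id, frame_id, k, B`; `frame_id` is `NA` for
#'   per-crystal scaling), `gauge`, `convergence` (iterations, final
#'   shift, converged flag), `per_frame`.
#' @examples
#' sim <- simulate_datasets(simulation_config(n_crystals = 3, seed = 1,
#'   cell0 = unit_cell(20, 22, 25), wedge_width = 360, n_outliers = 0))
#' fit <- fit_scales(sim$datasets, sim$config$sg, min_common = 5)
#' coef(fit)
#' @export
fit_scales <- function(datasets, sg, per_frame = FALSE, max_iter = 100,
                       tol = 1e-6, min_common = 20, init = NULL) {
  if (length(datasets) < 2) stop("scaling needs at least 2 crystals")
  sg <- as_space_group(sg)
  obs <- pool_observations(datasets)
  canon <- map_to_asu(as.matrix(obs[, c("h", "k", "l")]), sg)
  uid <- match(.hkl_key(as.matrix(canon[, c("h", "k", "l")])),
               unique(.hkl_key(as.matrix(canon[, c("h", "k", "l")]))))
  .check_connectivity(obs$crystal_id, uid, min_common)

  cry <- factor(obs$crystal_id,
                levels = unique(vapply(datasets, `[[`, "", "crystal_id")))
  cry <- droplevels(cry)
  grp <- if (per_frame) {
    factor(paste(obs$crystal_id, obs$frame_id, sep = "\r"))
  } else cry
  gi <- as.integer(grp)             # scale-group index per observation
  ci <- as.integer(cry)             # crystal index per observation
  n_grp <- nlevels(grp)
  n_cry <- nlevels(cry)
  grp_cry <- ci[match(seq_len(n_grp), gi)]  # crystal of each scale group

  k <- rep(1, n_grp)
  B <- rep(0, n_cry)
  if (!is.null(init)) {
    p <- init$params
    key_init <- if (init$per_frame)
      paste(p$crystal_id, p$frame_id, sep = "\r") else p$crystal_id
    key_now <- if (per_frame) levels(grp) else levels(cry)
    hit <- match(key_now, key_init)
    k[!is.na(hit)] <- p$k[hit[!is.na(hit)]]
    Bc <- p$B[match(levels(cry), p$crystal_id)]
    B[!is.na(Bc)] <- Bc[!is.na(Bc)]
  }

  w0 <- 1 / obs$sigma^2
  I <- obs$intensity
  s2 <- obs$s2
  by_cry <- split(seq_len(nrow(obs)), ci)

  iter <- 0L; shift <- Inf
  while (iter < max_iter && shift > tol) {
    iter <- iter + 1L
    g <- k[gi] * exp(-B[ci] * s2 / 2)
    wm <- g^2 * w0                                   # 1/sigma_corrected^2
    ref <- as.vector(rowsum(wm * I / g, uid) / rowsum(wm, uid))
    r <- ref[uid]

    k_new <- k; B_new <- B
    for (j in seq_len(n_cry)) {
      ii <- by_cry[[j]]
      wj <- w0[ii]; Ij <- I[ii]; rj <- r[ii]; s2j <- s2[ii]
      kfun <- function(bb) {
        e <- exp(-bb * s2j / 2)
        kk <- sum(wj * rj * e * Ij) / sum(wj * rj^2 * e^2)
        max(kk, 1e-9)
      }
      objfun <- function(bb) {
        e <- exp(-bb * s2j / 2)
        kk <- kfun(bb)
        sum(wj * (Ij - kk * e * rj)^2)
      }
      bb <- stats::optimize(objfun, c(-60, 60), tol = 1e-7)$minimum
      B_new[j] <- bb
      if (!per_frame) k_new[j] <- kfun(bb)
    }
    if (per_frame) {
      # closed-form per-frame scale given the crystal B
      e <- exp(-B_new[ci] * s2 / 2)
      num <- as.vector(rowsum(w0 * r * e * I, gi))
      den <- as.vector(rowsum(w0 * r^2 * e^2, gi))
      k_new <- pmax(num / den, 1e-9)
    }

    # gauge: geometric mean of k = 1, mean B = 0 (per crystal)
    k_new <- k_new / exp(mean(log(k_new)))
    B_new <- B_new - mean(B_new)

    shift <- max(abs(k_new - k) / pmax(abs(k), 1e-9),
                 abs(B_new - B) / (1 + abs(B)))
    k <- k_new; B <- B_new
  }

  params <- if (per_frame) {
    lv <- strsplit(levels(grp), "\r", fixed = TRUE)
    data.frame(crystal_id = vapply(lv, `[[`, "", 1),
               frame_id = as.integer(vapply(lv, `[[`, "", 2)),
               k = k, B = B[grp_cry])
  } else {
    data.frame(crystal_id = levels(cry), frame_id = NA_integer_,
               k = k, B = B)
  }
  structure(list(params = params,
                 gauge = "mean(log k) = 0, mean(B) = 0",
                 per_frame = per_frame,
                 convergence = list(iterations = iter, final_shift = shift,
                                    converged = shift <= tol)),
            class = "scaling_model")
}

# breadth-first connectivity over the crystal graph; edge when two
# crystals share >= min_common unique reflections
.check_connectivity <- function(crystal_id, uid, min_common) {
  ids <- unique(crystal_id)
  n <- length(ids)
  if (n < 2) return(invisible(TRUE))
  ci <- match(crystal_id, ids)
  pairs <- unique(cbind(ci, uid))
  # crystal x unique incidence; shared-unique counts via tcrossprod
  inc <- matrix(0, n, max(uid))
  inc[pairs] <- 1
  linked <- tcrossprod(inc) >= min_common
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(linked[v, ] & comp == 0))
    }
  }
  if (max(comp) > 1) {
    parts <- split(ids, comp)
    stop("crystal graph is disconnected at min_common = ", min_common,
         "; components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "))
  }
  invisible(TRUE)
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf("scaling model: %d %s scales, %d crystals; gauge %s\n",
              nrow(x$params), if (x$per_frame) "per-frame" else "per-crystal",
              length(unique(x$params$crystal_id)), x$gauge))
  cat(sprintf("converged: %s after %d iterations (final shift %.2e)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$final_shift))
  invisible(x)
}

#' @export
summary.scaling_model <- function(object, ...) {
  p <- object$params
  cat("scale factors k:\n"); print(summary(p$k))
  cat("relative B (A^2):\n"); print(summary(p$B))
  invisible(object)
}

#' @export
coef.scaling_model <- function(object, ...) object$params

# multiplicative correction g for a set of observations under a model
.scale_g <- function(model, crystal_id, frame_id, s2) {
  p <- model$params
  idx <- if (model$per_frame) {
    match(paste(crystal_id, frame_id), paste(p$crystal_id, p$frame_id))
  } else {
    match(crystal_id, p$crystal_id)
  }
  if (anyNA(idx))
    stop("observations reference crystals/frames absent from the model")
  p$k[idx] * exp(-p$B[idx] * s2 / 2)
}
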