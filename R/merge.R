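# Symmetry-aware merging of scale-corrected observations and the standard
# internal-agreement statistics (R_merge, R_meas, R_pim, CC1/2, mean I/sigma,
# completeness) per resolution shell.

#' Merge scaled observations into unique-reflection intensities
#'
#' Observations are corrected by the scaling model
#' (`I_corr = I / g`, `sigma_corr = sigma / g` with
#' `g = k exp(-B s^2 / 2)`), mapped to canonical asymmetric-unit indices,
#' and combined by inverse-variance weighted means.  Shells partition
#' `(d_max, d_min]` with equal volume in `1/d^3` (default 10 shells).
#' `n_possible` per shell comes from [enumerate_unique_hkl()] on the mean
#' cell of the merged crystals.  CC1/2 is the Pearson correlation of the
#' merged means of two balanced random half-subsets of each multiply
#' measured reflection (split seeded by `split_seed`; with `n_splits > 1`
#' the reported CC1/2 is the mean over splits and its sd is recorded).
#' Statistics that cannot be computed on a shell (no multiply observed
#' reflections, empty shell) are reported as `NA`, never as zeros.
#'
#' @param datasets list of [crystal_dataset()] objects.
#' @param model a [fit_scales()] result covering the same crystals; `NULL`
#'   means unit scales (e.g. a single crystal).
#' @param sg a [space_group()]; its Friedel flag controls whether mates
#'   merge.
#' @param n_shells number of resolution shells (default 10).
#' @param d_min,d_max optional resolution bounds; default to the span of
#'   the observed data.
#' @param split_seed seed of the half-split RNG stream (recorded in the
#'   result).
#' @param n_splits number of seeded half-splits averaged for CC1/2.
#' @return object of class `"merged_set"`: list with `reflections`
#'   (`h, k, l, d, I, sigma, multiplicity`), `shells` (per-shell statistics
#'   with an `overall` attribute row), `overall`, `cell` (mean cell),
#'   `split_seed`, `n_splits`.
#' @export
merge_observations <- function(datasets, model, sg, n_shells = 10,
                               d_min = NULL, d_max = NULL,
                               split_seed = 1, n_splits = 1) {
  sg <- as_space_group(sg)
  obs <- pool_observations(datasets)
  g <- if (is.null(model)) rep(1, nrow(obs)) else
    .scale_g(model, obs$crystal_id, obs$frame_id, obs$s2)
  Ic <- obs$intensity / g
  sc <- obs$sigma / g

  mean_cell <- as_unit_cell(colMeans(t(vapply(datasets, function(ds)
    as.numeric(ds$cell), numeric(6)))))
  canon <- map_to_asu(as.matrix(obs[, c("h", "k", "l")]), sg)
  key <- .hkl_key(as.matrix(canon[, c("h", "k", "l")]))
  ukey <- unique(key)
  uid <- match(key, ukey)
  n_uniq <- length(ukey)
  uhkl <- .hkl_unkey(ukey)
  ud <- resolution_of(mean_cell, uhkl)

  w <- 1 / sc^2
  sw <- as.vector(rowsum(w, uid))
  Im <- as.vector(rowsum(w * Ic, uid)) / sw
  sm <- sqrt(1 / sw)
  mult <- tabulate(uid, n_uniq)

  if (is.null(d_min)) d_min <- min(ud)
  if (is.null(d_max)) d_max <- max(ud)
  if (d_max <= d_min) d_max <- d_min * (1 + 1e-6)  # single-resolution data
  edges <- .shell_edges(d_min, d_max, n_shells)
  shell_of <- .shell_assign(ud, edges)

  refl <- data.frame(h = uhkl[, 1], k = uhkl[, 2], l = uhkl[, 3], d = ud,
                     I = Im, sigma = sm, multiplicity = mult,
                     shell = shell_of)

  # content-derived split keys make CC1/2 invariant to observation order
  # and crystal relabeling
  ukey_obs <- .split_hash(obs$h, obs$k, obs$l, obs$frame_id, obs$intensity)
  shells <- .shell_stats(uid, Ic, Im, mult, refl, edges, mean_cell, sg,
                         d_min, d_max, split_seed, n_splits, ukey_obs)

  # deterministic output order regardless of input order
  ord <- order(-refl$d, refl$h, refl$k, refl$l)
  refl <- refl[ord, ]
  rownames(refl) <- NULL

  structure(list(reflections = refl,
                 shells = shells$table,
                 overall = shells$overall,
                 cell = mean_cell,
                 sg = sg,
                 split_seed = split_seed,
                 n_splits = n_splits),
            class = "merged_set")
}

# equal-volume shell edges in 1/d^3; returned as d values, decreasing
.shell_edges <- function(d_min, d_max, n_shells) {
  lo <- 1 / d_max^3
  hi <- 1 / d_min^3
  s3 <- seq(lo, hi, length.out = n_shells + 1)
  d <- s3^(-1 / 3)
  d[1] <- d_max        # guard fp noise at the extremes
  d[n_shells + 1] <- d_min
  d
}

# shell index for d values given decreasing edge vector (1 = lowest res)
.shell_assign <- function(d, edges) {
  n <- length(edges) - 1
  idx <- findInterval(-d, -edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  pmin(pmax(idx, 1L), n)
}

# order-invariant pseudo-random key per observation, derived from content
.split_hash <- function(h, k, l, frame, intensity) {
  x <- h * 12.9898 + k * 78.233 + l * 37.719 + frame * 53.987 +
    round(intensity * 64) * 0.1031
  (sin(x) * 43758.5453125) %% 1
}

# fresh, mutually decorrelated uniform stream for split s of a seed
.split_u01 <- function(key, split_seed, stream, s) {
  z <- .sub_seed(split_seed, stream, s) / 2147483629
  (sin(key * (761.31 + 311.7 * z) + z * 6179.0 + s * 97.77) *
      43758.5453125) %% 1
}

.shell_stats <- function(uid, Ic, Im, mult, refl, edges, cell, sg,
                         d_min, d_max, split_seed, n_splits, split_key) {
  n_shell <- length(edges) - 1
  shell_obs <- refl$shell[uid]
  multi <- mult[uid] >= 2                    # per-observation flag

  # R-factor numerators/denominators per observation, reflections with n>=2
  dev <- abs(Ic - Im[uid])
  nfac <- mult[uid]
  num_merge <- ifelse(multi, dev, 0)
  num_meas <- ifelse(multi, dev * sqrt(nfac / (nfac - 1)), 0)
  num_pim <- ifelse(multi, dev * sqrt(1 / (nfac - 1)), 0)
  den <- ifelse(multi, Ic, 0)

  possible <- enumerate_unique_hkl(cell, sg, d_min, d_max)
  poss_shell <- .shell_assign(possible$d, edges)

  cc <- .cc_half(uid, Ic, refl$shell, n_shell, split_seed, n_splits,
                 split_key)

  tab <- data.frame(shell = seq_len(n_shell),
                    d_max = edges[seq_len(n_shell)],
                    d_min = edges[-1])
  tab$n_unique <- tabulate(refl$shell, n_shell)
  tab$n_possible <- tabulate(poss_shell, n_shell)
  tab$completeness <- ifelse(tab$n_possible > 0,
                             tab$n_unique / tab$n_possible, NA_real_)
  tab$multiplicity <- ifelse(tab$n_unique > 0,
                             tabulate(shell_obs, n_shell) / tab$n_unique,
                             NA_real_)
  sden <- .sum_by(den, shell_obs, n_shell)
  tab$R_merge <- ifelse(sden != 0, .sum_by(num_merge, shell_obs, n_shell) /
                          sden, NA_real_)
  tab$R_meas <- ifelse(sden != 0, .sum_by(num_meas, shell_obs, n_shell) /
                         sden, NA_real_)
  tab$R_pim <- ifelse(sden != 0, .sum_by(num_pim, shell_obs, n_shell) /
                        sden, NA_real_)
  tab$R_merge[sden == 0] <- NA_real_
  tab$cc_half <- cc$by_shell
  tab$cc_half_sd <- cc$by_shell_sd
  tab$mean_i_over_sigma <- vapply(seq_len(n_shell), function(sh) {
    sel <- refl$shell == sh
    if (!any(sel)) NA_real_ else mean(refl$I[sel] / refl$sigma[sel])
  }, 0)

  oden <- sum(den)
  overall <- data.frame(
    n_unique = nrow(refl),
    n_possible = nrow(possible),
    completeness = if (nrow(possible) > 0) nrow(refl) / nrow(possible)
      else NA_real_,
    multiplicity = length(uid) / nrow(refl),
    R_merge = if (oden != 0 && any(multi)) sum(num_merge) / oden else NA_real_,
    R_meas = if (oden != 0 && any(multi)) sum(num_meas) / oden else NA_real_,
    R_pim = if (oden != 0 && any(multi)) sum(num_pim) / oden else NA_real_,
    cc_half = cc$overall,
    cc_half_sd = cc$overall_sd,
    mean_i_over_sigma = mean(refl$I / refl$sigma))
  list(table = tab, overall = overall)
}

.sum_by <- function(x, idx, n) {
  out <- rep(0, n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- as.vector(s)
  out
}

# balanced random half-splits of each multiply observed reflection;
# returns mean (and sd over splits) of the Pearson correlation of the
# two half means, per shell and overall
.cc_half <- function(uid, Ic, shell_of_uniq, n_shell, split_seed, n_splits,
                     split_key) {
  mult <- tabulate(uid)
  multi_uid <- which(mult >= 2)
  if (length(multi_uid) < 2) {
    return(list(by_shell = rep(NA_real_, n_shell),
                by_shell_sd = rep(NA_real_, n_shell),
                overall = NA_real_, overall_sd = NA_real_))
  }
  sel <- uid %in% multi_uid
  u <- uid[sel]; x <- Ic[sel]; key <- split_key[sel]
  per_shell <- matrix(NA_real_, n_splits, n_shell)
  ov <- rep(NA_real_, n_splits)
  for (s in seq_len(n_splits)) {
    u01 <- .split_u01(key, split_seed, 17L, s)
    o <- order(u, u01)
    half <- (seq_along(o) - .first_pos(u[o])[match(u[o], unique(u[o]))]) %% 2
    hu <- u[o]; hx <- x[o]
    m1 <- .mean_by_key(hx[half == 0], hu[half == 0])
    m2 <- .mean_by_key(hx[half == 1], hu[half == 1])
    common <- intersect(names(m1), names(m2))
    a <- m1[common]; b <- m2[common]
    cu <- as.integer(common)
    if (length(common) >= 2) ov[s] <- stats::cor(a, b)
    sh <- shell_of_uniq[cu]
    for (ss in unique(sh)) {
      i <- sh == ss
      if (sum(i) >= 2 && stats::sd(a[i]) > 0 && stats::sd(b[i]) > 0)
        per_shell[s, ss] <- stats::cor(a[i], b[i])
    }
  }
  list(by_shell = colMeans(per_shell),
       by_shell_sd = apply(per_shell, 2, stats::sd),
       overall = mean(ov),
       overall_sd = stats::sd(ov))
}

.first_pos <- function(sorted_keys) {
  # position of the first occurrence of each distinct value (input sorted)
  which(!duplicated(sorted_keys))
}

.mean_by_key <- function(x, key) {
  s <- rowsum(x, key)
  n <- rowsum(rep(1, length(x)), key)
  stats::setNames(as.vector(s / n), rownames(s))
}

#' @export
print.merged_set <- function(x, ...) {
  o <- x$overall
  cat(sprintf(paste0("merged set: %d unique reflections ",
                     "(completeness %.1f%%, multiplicity %.1f)\n"),
              o$n_unique, 100 * o$completeness, o$multiplicity))
  cat(sprintf("R_merge %.4f  R_meas %.4f  R_pim %.4f  CC1/2 %.4f  <I/sig> %.1f\n",
              o$R_merge, o$R_meas, o$R_pim, o$cc_half, o$mean_i_over_sigma))
  invisible(x)
}

#' Write merged intensities / shell statistics
#'
#' @param merged a [merge_observations()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_merged_hkl <- function(merged, path) {
  r <- merged$reflections
  write_hkl(observation_table(r$h, r$k, r$l, r$I, pmax(r$sigma, 0.01), 0L,
                              "merged"), path)
}

#' @rdname write_merged_hkl
#' @export
write_shell_csv <- function(merged, path) {
  utils::write.csv(merged$shells, path, row.names = FALSE)
  invisible(path)
}

#' Anomalous half-split correlation per shell
#'
#' With Friedel merging off, observations are grouped by
#' (rotation-canonical index, Friedel sign); each group is split into
#' balanced random halves, the half Friedel differences
#' `dI = <I+> - <I->` are formed, and their Pearson correlation across
#' unique reflections is reported per shell (and overall).  Shells with
#' fewer than `min_pairs` usable Friedel pairs are `NA`.
#'
#' @param datasets list of [crystal_dataset()] objects.
#' @param model a [fit_scales()] result (or `NULL` for unit scales).
#' @param sg a [space_group()] with `friedel_merged = FALSE`; merged
#'   groups are rejected.
#' @param n_shells,d_min,d_max,split_seed,n_splits as in
#'   [merge_observations()].
#' @param min_pairs minimum Friedel pairs per shell (default 3).
#' @return list with `by_shell` (data.frame shell, d bounds, n_pairs,
#'   cc_anom) and `overall`.
#' @export
anomalous_cc <- function(datasets, model, sg, n_shells = 10, d_min = NULL,
                         d_max = NULL, split_seed = 1, n_splits = 1,
                         min_pairs = 3) {
  sg <- as_space_group(sg)
  if (sg$friedel_merged)
    stop("anomalous_cc requires a space group with friedel_merged = FALSE")
  obs <- pool_observations(datasets)
  g <- if (is.null(model)) rep(1, nrow(obs)) else
    .scale_g(model, obs$crystal_id, obs$frame_id, obs$s2)
  Ic <- obs$intensity / g

  base <- map_to_asu(as.matrix(obs[, c("h", "k", "l")]), sg,
                     friedel_merged = TRUE)
  key <- .hkl_key(as.matrix(base[, c("h", "k", "l")]))
  ukey <- unique(key)
  uid <- match(key, ukey)
  sign <- base$friedel_sign
  mean_cell <- as_unit_cell(colMeans(t(vapply(datasets, function(ds)
    as.numeric(ds$cell), numeric(6)))))
  ud <- resolution_of(mean_cell, .hkl_unkey(ukey))
  if (is.null(d_min)) d_min <- min(ud)
  if (is.null(d_max)) d_max <- max(ud)
  edges <- .shell_edges(d_min, d_max, n_shells)
  shell_u <- .shell_assign(ud, edges)

  split_key <- .split_hash(obs$h, obs$k, obs$l, obs$frame_id,
                           obs$intensity)
  per_shell <- matrix(NA_real_, n_splits, n_shells)
  npairs_shell <- rep(0L, n_shells)
  ov <- rep(NA_real_, n_splits)
  for (s in seq_len(n_splits)) {
    u01 <- .split_u01(split_key, split_seed, 23L, s)
    gkey <- uid * 2L + (sign > 0)          # (unique, sign) group
    o <- order(gkey, u01)
    half <- (seq_along(o) -
               .first_pos(gkey[o])[match(gkey[o], unique(gkey[o]))]) %% 2
    dI <- matrix(NA_real_, length(ukey), 2)
    for (hh in 0:1) {
      ss <- o[half == hh]
      mp <- .mean_by_key(Ic[ss][sign[ss] > 0], uid[ss][sign[ss] > 0])
      mm <- .mean_by_key(Ic[ss][sign[ss] < 0], uid[ss][sign[ss] < 0])
      common <- intersect(names(mp), names(mm))
      dI[as.integer(common), hh + 1] <- mp[common] - mm[common]
    }
    ok <- stats::complete.cases(dI)
    if (s == 1) npairs_shell <- tabulate(shell_u[ok], n_shells)
    if (sum(ok) >= 2) ov[s] <- stats::cor(dI[ok, 1], dI[ok, 2])
    for (ss in unique(shell_u[ok])) {
      i <- ok & shell_u == ss
      if (sum(i) >= min_pairs && stats::sd(dI[i, 1]) > 0 &&
          stats::sd(dI[i, 2]) > 0)
        per_shell[s, ss] <- stats::cor(dI[i, 1], dI[i, 2])
    }
  }
  list(by_shell = data.frame(shell = seq_len(n_shells),
                             d_max = edges[seq_len(n_shells)],
                             d_min = edges[-1],
                             n_pairs = npairs_shell,
                             cc_anom = colMeans(per_shell)),
       overall = mean(ov))
}
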