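# Assembly of a final dataset from grouped partial datasets:
# completeness-gated group selection, quality ranking, and greedy
# iterative crystal-and-frame rejection driven by a merged-data objective.

#' Select groups passing the completeness gate
#'
#' @param group_stats data.frame with columns `group` and `completeness`
#'   (overall, as a fraction), e.g. built by [assemble()].
#' @param min_completeness gate (default 0.90); selection is strict
#'   (`completeness > min_completeness`), so a group sitting exactly on
#'   the gate is excluded.
#' @return integer vector of selected group ids (possibly empty; an empty
#'   selection is a reportable outcome, not an error).
#' @export
select_groups <- function(group_stats, min_completeness = 0.90) {
  stopifnot(all(c("group", "completeness") %in% names(group_stats)))
  sel <- group_stats$group[!is.na(group_stats$completeness) &
                             group_stats$completeness > min_completeness]
  as.integer(sel)
}

#' Rank selected groups by merged data quality
#'
#' Deterministic ordering: higher overall CC1/2, then higher completeness,
#' then more unique reflections, then smaller group id.  The original
#' arbiter in multi-crystal assembly is the refined R_free of each group's
#' structure; refinement is outside this package's scope, so merged-data
#' quality stands as the proxy (recorded in the assembly report).
#'
#' @param group_stats data.frame with columns `group`, `cc_half`,
#'   `completeness`, `n_unique`.
#' @param selected integer vector of candidate group ids (>= 1).
#' @return the winning group id.
#' @export
rank_groups <- function(group_stats, selected) {
  if (length(selected) < 1)
    stop("cannot rank an empty group selection")
  gs <- group_stats[group_stats$group %in% selected, , drop = FALSE]
  o <- order(-gs$cc_half, -gs$completeness, -gs$n_unique, gs$group)
  as.integer(gs$group[o][1])
}

# merged-data objective for a candidate set of datasets
.reject_objective <- function(datasets, objective, sg, opts, init = NULL) {
  model <- if (length(datasets) >= 2) {
    fit_scales(datasets, sg, max_iter = opts$scale_max_iter,
               tol = opts$scale_tol, min_common = opts$min_common,
               init = init)
  } else NULL
  val <- if (objective == "cc_half") {
    m <- merge_observations(datasets, model, sg, n_shells = opts$n_shells,
                            split_seed = opts$split_seed,
                            n_splits = opts$n_splits)
    m$overall$cc_half
  } else {
    anomalous_cc(datasets, model, sg, n_shells = opts$n_shells,
                 split_seed = opts$split_seed,
                 n_splits = opts$n_splits)$overall
  }
  list(value = val, model = model)
}

#' Greedy iterative crystal and frame rejection
#'
#' Starting from the full set, scales are refit and the objective (overall
#' CC1/2, or overall anomalous CC for the anomalous use-case) is evaluated
#' with each crystal left out in turn; the removal improving the objective
#' most is accepted if the improvement exceeds `tol`, and the loop
#' repeats.  After crystal-level convergence the same greedy loop runs at
#' frame level within the surviving crystals.  Floors (`min_crystals`,
#' `min_frames_per_crystal`) stop degenerate emptying.  Every candidate
#' evaluation is recorded, so the trace replays the full decision path,
#' and the objective is non-decreasing across accepted removals by
#' construction.
#'
#' @param datasets list of [crystal_dataset()] objects.
#' @param sg a [space_group()] (Friedel-unmerged when
#'   `objective = "cc_anom"`).
#' @param objective `"cc_half"` (default) or `"cc_anom"`.
#' @param tol minimum absolute objective improvement to accept a removal
#'   (default 0.001).
#' @param min_crystals floor on surviving crystals (default 3).
#' @param min_frames_per_crystal floor on frames per crystal (default 2).
#' @param levels rejection passes to run, subset of
#'   `c("crystal", "frame")`.
#' @param split_seed,n_splits CC1/2 half-split control (a fixed seed keeps
#'   every candidate evaluation comparable).
#' @param n_shells shells used by the objective merges.
#' @param min_common connectivity threshold passed to [fit_scales()].
#' @param scale_max_iter,scale_tol scaling convergence controls for the
#'   many refits inside the loop.
#' @return list with `datasets` (survivors, frames removed), `merged`
#'   (final [merge_observations()] result), `model` (final scaling
#'   model), `trace` (data.frame: iteration, level, removed id, objective
#'   before/after, crystals and frames remaining), `evaluations` (every
#'   candidate objective), `converged_because`.
#' @export
iterative_reject <- function(datasets, sg, objective = c("cc_half",
                                                         "cc_anom"),
                             tol = 0.001, min_crystals = 3,
                             min_frames_per_crystal = 2,
                             levels = c("crystal", "frame"),
                             split_seed = 1, n_splits = 8, n_shells = 10,
                             min_common = 20, scale_max_iter = 100,
                             scale_tol = 1e-6) {
  objective <- match.arg(objective)
  sg <- as_space_group(sg)
  if (objective == "cc_anom" && sg$friedel_merged)
    stop("cc_anom objective requires friedel_merged = FALSE")
  opts <- list(split_seed = split_seed, n_splits = n_splits,
               n_shells = n_shells, min_common = min_common,
               scale_max_iter = scale_max_iter, scale_tol = scale_tol)
  cur <- datasets
  full <- .reject_objective(cur, objective, sg, opts)
  if (!is.finite(full$value))
    stop("objective '", objective, "' is undefined on the full set")

  trace <- list(); evals <- list(); iter <- 0L
  reason <- NULL
  for (level in levels) {
    repeat {
      iter <- iter + 1L
      cand <- .removal_candidates(cur, level, min_crystals,
                                  min_frames_per_crystal)
      if (length(cand) == 0) { reason <- paste0(level, " floor"); break }
      vals <- rep(NA_real_, length(cand))
      for (ii in seq_along(cand)) {
        reduced <- .apply_removal(cur, level, cand[[ii]])
        vals[ii] <- tryCatch(
          .reject_objective(reduced, objective, sg, opts,
                            init = full$model)$value,
          error = function(e) NA_real_)
        evals[[length(evals) + 1L]] <- data.frame(
          iteration = iter, level = level,
          candidate = .removal_label(cand[[ii]]),
          objective = vals[ii])
      }
      best <- which.max(vals)
      if (length(best) == 0 || !is.finite(vals[best]) ||
          vals[best] - full$value <= tol) {
        reason <- "tolerance"
        break
      }
      cur <- .apply_removal(cur, level, cand[[best]])
      new_full <- .reject_objective(cur, objective, sg, opts,
                                    init = full$model)
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = iter, level = level,
        removed = .removal_label(cand[[best]]),
        objective_before = full$value,
        objective_after = new_full$value,
        n_crystals = length(cur),
        n_frames = sum(vapply(cur, function(ds)
          length(unique(ds$observations$frame_id)), 0L)))
      full <- new_full
    }
  }

  final_model <- if (length(cur) >= 2)
    fit_scales(cur, sg, min_common = min_common) else NULL
  final_merged <- merge_observations(cur, final_model, sg,
                                     n_shells = n_shells,
                                     split_seed = split_seed,
                                     n_splits = n_splits)
  list(datasets = cur,
       merged = final_merged,
       model = final_model,
       objective = objective,
       final_objective = full$value,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iteration = integer(0), level = character(0),
                    removed = character(0),
                    objective_before = numeric(0),
                    objective_after = numeric(0),
                    n_crystals = integer(0), n_frames = integer(0)),
       evaluations = if (length(evals)) do.call(rbind, evals) else NULL,
       converged_because = reason)
}

.removal_candidates <- function(datasets, level, min_crystals,
                                min_frames_per_crystal) {
  if (level == "crystal") {
    if (length(datasets) <= min_crystals) return(list())
    lapply(seq_along(datasets), function(i)
      list(crystal = datasets[[i]]$crystal_id))
  } else {
    out <- list()
    for (ds in datasets) {
      frames <- sort(unique(ds$observations$frame_id))
      if (length(frames) > min_frames_per_crystal)
        for (f in frames)
          out[[length(out) + 1L]] <- list(crystal = ds$crystal_id,
                                          frame = f)
    }
    out
  }
}

.apply_removal <- function(datasets, level, removal) {
  if (level == "crystal") {
    datasets[vapply(datasets, function(ds)
      ds$crystal_id != removal$crystal, TRUE)]
  } else {
    lapply(datasets, function(ds) {
      if (ds$crystal_id == removal$crystal) {
        ds$observations <-
          ds$observations[ds$observations$frame_id != removal$frame, ,
                          drop = FALSE]
      }
      ds
    })
  }
}

.removal_label <- function(removal) {
  if (is.null(removal$frame)) removal$crystal else
    paste0(removal$crystal, ":frame", removal$frame)
}

#' Full assembly of partial microcrystal datasets
#'
#' Runs the whole pipeline: unit-cell variation clustering
#' ([cluster_cells()]), per-group scaling and merging, the completeness
#' gate ([select_groups()]), quality ranking ([rank_groups()]), and greedy
#' iterative rejection ([iterative_reject()]) on the winning group,
#' followed by a final merge.  Deterministic for fixed inputs and
#' `split_seed`.
#'
#' @param datasets list of [crystal_dataset()] objects (>= 2).
#' @param sg a [space_group()].
#' @param max_groups,reject_z,angle_weight clustering controls
#'   (see [cluster_cells()]).
#' @param min_completeness completeness gate (default 0.90).
#' @param objective,tol,min_crystals,min_frames_per_crystal,levels
#'   rejection controls (see [iterative_reject()]).
#' @param split_seed,n_splits,n_shells,min_common merging/scaling controls.
#' @return object of class `"assembly_report"`: list with `grouping`,
#'   `group_stats` (per-group merged statistics), `selected`, `winner`,
#'   `rejection` (the [iterative_reject()] result), `final` (final
#'   [merge_observations()] result), `params`.
#' @export
assemble <- function(datasets, sg, max_groups = 20, reject_z = 3,
                     angle_weight = 1, min_completeness = 0.90,
                     objective = "cc_half", tol = 0.001, min_crystals = 3,
                     min_frames_per_crystal = 2,
                     levels = c("crystal", "frame"), split_seed = 1,
                     n_splits = 8, n_shells = 10, min_common = 20) {
  if (length(datasets) < 2) stop("assembly needs at least 2 datasets")
  sg <- as_space_group(sg)
  grouping <- tryCatch(cluster_cells(datasets, max_groups = max_groups,
                                     reject_z = reject_z,
                                     angle_weight = angle_weight),
                       error = function(e)
                         stop("cell_clustering: ", conditionMessage(e)))
  ids <- vapply(datasets, `[[`, "", "crystal_id")
  surv <- grouping$crystal_id[!grouping$rejected]
  groups <- sort(unique(grouping$group[!grouping$rejected]))

  group_stats <- do.call(rbind, lapply(groups, function(g) {
    members <- grouping$crystal_id[grouping$group == g & !grouping$rejected]
    dsg <- datasets[match(members, ids)]
    res <- tryCatch({
      model <- if (length(dsg) >= 2)
        fit_scales(dsg, sg, min_common = min_common) else NULL
      m <- merge_observations(dsg, model, sg, n_shells = n_shells,
                              split_seed = split_seed, n_splits = n_splits)
      data.frame(group = g, n_crystals = length(dsg),
                 n_unique = m$overall$n_unique,
                 completeness = m$overall$completeness,
                 cc_half = m$overall$cc_half,
                 R_merge = m$overall$R_merge, failed = FALSE,
                 message = "")
    }, error = function(e)
      data.frame(group = g, n_crystals = length(dsg),
                 n_unique = NA_integer_, completeness = NA_real_,
                 cc_half = NA_real_, R_merge = NA_real_, failed = TRUE,
                 message = conditionMessage(e)))
    res
  }))

  selected <- select_groups(group_stats, min_completeness)
  if (length(selected) == 0) {
    return(structure(list(grouping = grouping, group_stats = group_stats,
                          selected = integer(0), winner = NA_integer_,
                          rejection = NULL, final = NULL,
                          params = list(max_groups = max_groups,
                                        min_completeness = min_completeness,
                                        objective = objective, tol = tol,
                                        split_seed = split_seed),
                          note = "no group passed the completeness gate"),
                     class = "assembly_report"))
  }
  winner <- rank_groups(group_stats, selected)
  members <- grouping$crystal_id[grouping$group == winner &
                                   !grouping$rejected]
  rejection <- tryCatch(
    iterative_reject(datasets[match(members, ids)], sg,
                     objective = objective, tol = tol,
                     min_crystals = min_crystals,
                     min_frames_per_crystal = min_frames_per_crystal,
                     levels = levels, split_seed = split_seed,
                     n_splits = n_splits, n_shells = n_shells,
                     min_common = min_common),
    error = function(e) stop("rejection_pipeline: ", conditionMessage(e)))

  structure(list(grouping = grouping, group_stats = group_stats,
                 selected = selected, winner = winner,
                 rejection = rejection, final = rejection$merged,
                 params = list(max_groups = max_groups,
                               min_completeness = min_completeness,
                               objective = objective, tol = tol,
                               split_seed = split_seed)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("assembly report: %d crystals -> %d groups, %d rejected by cell\n",
              nrow(x$grouping),
              length(unique(x$grouping$group[!x$grouping$rejected])),
              sum(x$grouping$rejected)))
  cat(sprintf("groups over completeness gate (> %.0f%%): %s\n",
              100 * x$params$min_completeness,
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "none"))
  if (!is.na(x$winner)) {
    cat(sprintf("winning group: %d (ranked by overall CC1/2)\n", x$winner))
    cat(sprintf("rejection: %d removals (%s); final %d crystals\n",
                nrow(x$rejection$trace), x$rejection$converged_because,
                length(x$rejection$datasets)))
    print(x$final)
  } else cat("note:", x$note, "\n")
  invisible(x)
}
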