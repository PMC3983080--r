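#' Controller run configuration
#'
#' Bundles everything the receding-horizon loop needs: the input space, the
#' dosing grid, the objective spec, the Pareto-front resolution, the
#' adaptive-selection thresholds and the surrogate controls. Can be loaded
#' from a YAML file with [read_run_config()].
#'
#' @param space an [input_space()].
#' @param dose_times dosing grid (min), default `c(3, 8, 13, 18, 23)`.
#' @param spec an [objective_spec()].
#' @param n_pareto utopia-plane points per interval (default 15).
#' @param tol_w,tol_u,max_iter adaptive-selection controls (see
#'   [adapt_and_select()]).
#' @param tol_abs,tol_rel,max_depth sparse-grid surrogate controls.
#' @param use_surrogate logical; FALSE evaluates objectives by direct ODE
#'   simulation throughout.
#' @param windowed logical; TRUE (default) recalibrates weights on the
#'   training-data time window of the current prediction interval, FALSE
#'   uses the whole time course.
#' @param t_final end of the experiment (min, default 30).
#' @return An object of class `run_config`.
#' @export
run_config <- function(space = input_space(), dose_times = dosing_times(),
                       spec = objective_spec(), n_pareto = 15,
                       tol_w = 1e-3, tol_u = NULL, max_iter = 10,
                       tol_abs = 0.01, tol_rel = 0.01, max_depth = 6,
                       use_surrogate = TRUE, windowed = TRUE, t_final = 30) {
  structure(list(space = space, dose_times = dose_times, spec = spec,
                 n_pareto = n_pareto, tol_w = tol_w, tol_u = tol_u,
                 max_iter = max_iter, tol_abs = tol_abs, tol_rel = tol_rel,
                 max_depth = max_depth, use_surrogate = use_surrogate,
                 windowed = windowed, t_final = t_final),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `lower`, `upper`, `dose_times`, `n_pareto`, `tol_w`,
#' `tol_u`, `max_iter`, `tol_abs`, `tol_rel`, `max_depth`,
#' `use_surrogate`, `windowed`, `t_final`, `Q`, `R`, and `targets` (list of
#' `[t_off, p_ss]` pairs, returned as attribute `"targets"`).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  space <- input_space(y$lower %||% c(0, 0), y$upper %||% c(50, 10))
  spec <- objective_spec(Q = y$Q %||% 1, R = y$R %||% 1)
  cfg <- run_config(space = space,
                    dose_times = y$dose_times %||% dosing_times(),
                    spec = spec,
                    n_pareto = y$n_pareto %||% 15,
                    tol_w = y$tol_w %||% 1e-3,
                    tol_u = y$tol_u,
                    max_iter = y$max_iter %||% 10,
                    tol_abs = y$tol_abs %||% 0.01,
                    tol_rel = y$tol_rel %||% 0.01,
                    max_depth = y$max_depth %||% 6,
                    use_surrogate = y$use_surrogate %||% TRUE,
                    windowed = y$windowed %||% TRUE,
                    t_final = y$t_final %||% 30)
  if (!is.null(y$targets)) {
    attr(cfg, "targets") <- do.call(rbind, lapply(y$targets, function(p)
      data.frame(t_off = p[[1]], p_ss = p[[2]])))
  }
  cfg
}

## advance one model from (t0, state) to t1 under a bolus u at t0
.advance_state <- function(model, state, t0, t1, u, space) {
  sched <- if (all(u == 0)) bolus_schedule(space = space) else
    bolus_schedule(t0, u, space = space)
  sim <- simulate_model(model, sched, t_grid = c(t0, t1), state0 = state,
                        t0 = t0)
  sim$states[nrow(sim$states), ]
}

#' Design an open-loop control sequence by receding-horizon optimization
#'
#' The main loop: for each dosing interval, build one log-space tracking
#' objective per prediction model from the model's own current state,
#' generate the Pareto set of candidate boluses with the normalized normal
#' constraint method, select the committed input by Akaike-weighted ranking
#' with iterative weight recalibration, advance every model's state under
#' the committed bolus, and append it to the growing sequence U*. The
#' result is a complete dosing regimen ready to be applied to the plant
#' without measurement feedback.
#'
#' @param models list of prediction models (the bank backing the
#'   controller; a single model gives a single-model controller).
#' @param wmap a `weight_map` over `models`, or NULL to keep weights fixed.
#' @param target a [target_trajectory()].
#' @param cfg a [run_config()].
#' @param w_fixed fixed weight vector (used when `wmap` is NULL; defaults
#'   to equal weights).
#' @return An object of class `control_sequence`: `dose_times`, `doses`
#'   (matrix, one row per interval), `traces` (per-interval
#'   `selection_trace`), `pareto_sets`, and `weights` (committed weight
#'   vector per interval).
#' @export
run_open_loop <- function(models, wmap = NULL, target, cfg = run_config(),
                          w_fixed = NULL) {
  space <- cfg$space
  n_m <- length(models)
  dt <- cfg$dose_times
  n_k <- length(dt)
  width <- if (n_k > 1) dt[n_k] - dt[n_k - 1] else cfg$t_final - dt[1]
  interval_ends <- c(dt[-1], min(cfg$t_final, dt[n_k] + width))

  ## initial states: advance every model uncontrolled from 0 to the first
  ## dosing time
  states <- lapply(models, function(m)
    .advance_state(m, NULL, 0, dt[1], rep(0, space$n_u), space))

  ## first-interval initial weights consider the entire training set
  w <- if (!is.null(w_fixed)) {
    as.numeric(w_fixed) / sum(w_fixed)
  } else if (!is.null(wmap)) {
    as.numeric(wmap$global_weights())
  } else {
    rep(1 / n_m, n_m)
  }

  doses <- matrix(NA_real_, n_k, space$n_u)
  traces <- vector("list", n_k)
  psets <- vector("list", n_k)
  wts <- matrix(NA_real_, n_k, n_m)
  for (k in seq_len(n_k)) {
    interval <- c(dt[k], interval_ends[k])
    objectives <- tryCatch(
      build_objective_surrogates(models, states, target, cfg$spec, interval,
                                 space, tol_abs = cfg$tol_abs,
                                 tol_rel = cfg$tol_rel,
                                 max_depth = cfg$max_depth,
                                 use_surrogate = cfg$use_surrogate),
      error = function(e) stop(sprintf("interval %d [%g, %g] min: %s", k,
                                       interval[1], interval[2],
                                       conditionMessage(e))))
    ps <- generate_pareto_set(objectives, space, n_points = cfg$n_pareto)
    window <- if (cfg$windowed) interval else NULL
    trace <- adapt_and_select(ps, wmap, w0 = w, window = window,
                              tol_w = cfg$tol_w, tol_u = cfg$tol_u,
                              max_iter = cfg$max_iter)
    u_star <- trace$final_u
    doses[k, ] <- u_star
    traces[[k]] <- trace
    psets[[k]] <- ps
    wts[k, ] <- trace$final_weights
    ## committed weights seed the next interval's iteration
    w <- trace$final_weights
    states <- lapply(seq_along(models), function(i)
      .advance_state(models[[i]], states[[i]], dt[k], interval_ends[k],
                     u_star, space))
  }
  structure(list(dose_times = dt, doses = doses, traces = traces,
                 pareto_sets = psets, weights = wts,
                 model_ids = vapply(models, function(m) m$model_id,
                                    character(1)),
                 target = c(t_off = target$t_off, p_ss = target$p_ss)),
            class = "control_sequence")
}

#' @export
print.control_sequence <- function(x, ...) {
  cat(sprintf("<control_sequence> U*: %d interval(s), bank: %s, target (%g, %g)\n",
              length(x$dose_times), paste(x$model_ids, collapse = ","),
              x$target[1], x$target[2]))
  for (k in seq_along(x$dose_times)) {
    cat(sprintf("  t=%5.1f : (%s)  [%s]\n", x$dose_times[k],
                paste(signif(x$doses[k, ], 4), collapse = ", "),
                x$traces[[k]]$terminated_by))
  }
  invisible(x)
}

#' Apply a control sequence to the plant
#'
#' Simulates the designated plant under the full dosing regimen and scores
#' target tracking by the squared error between the plant's normalized
#' output and the target on a 1-min evaluation grid over the experiment.
#'
#' @param plant a calibrated [prediction_model()].
#' @param useq a `control_sequence` (or a plain dose matrix with attribute
#'   dose times).
#' @param target a [target_trajectory()].
#' @param space the [input_space()].
#' @param t_final experiment end (min).
#' @param noise_sd optional observation noise fraction added to the
#'   returned trajectory (does not affect `sq_error`'s evaluation grid
#'   unless `seed` given; default 0 = deterministic plant).
#' @param seed RNG seed when `noise_sd > 0`.
#' @return A list with `t_grid`, `z` (plant output), `r` (target values),
#'   `sq_error` (sum of squared tracking errors).
#' @export
apply_to_plant <- function(plant, useq, target, space = input_space(),
                           t_final = 30, noise_sd = 0, seed = NULL) {
  doses <- useq$doses
  dt <- useq$dose_times
  keep <- rowSums(abs(doses)) > 0
  sched <- if (!any(keep)) bolus_schedule(space = space) else
    bolus_schedule(dt[keep], doses[keep, , drop = FALSE], space = space)
  t_grid <- seq(0, t_final, by = 1)
  sim <- simulate_model(plant, sched, t_grid = t_grid)
  z <- sim$z[, 1]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    z <- z + stats::rnorm(length(z), sd = noise_sd)
  }
  r <- target$value_fn(t_grid)
  list(t_grid = t_grid, z = z, r = r, sq_error = sum((z - r)^2))
}

#' Benchmark sweep over plants, targets and controller classes
#'
#' Rotates the plant role over the bank members: for each plant, the other
#' two members form the prediction bank and weight maps are trained on
#' synthetic dose-response data generated from that plant. For every target
#' in the preset, four controller classes design a regimen applied to the
#' plant: the matched single-model controller (`S_matched`, the plant
#' controls itself — the unrealizable ideal), the two mismatched
#' single-model controllers (`S_mismatched`), the equal-fixed-weight
#' multiple-model controller (`M_eq`), and the adaptive Akaike-weight
#' controller (`M_aw`).
#'
#' @param bank a bank from [make_toy_bank()] (3 members).
#' @param targets data frame of `(t_off, p_ss)` pairs, default
#'   [target_preset()].
#' @param cfg a [run_config()].
#' @param noise_sd,n_timepoints,seed training-data generation settings per
#'   plant (defaults 0.05, 8, `seed`).
#' @param plants subset of plant ids to sweep (default: all members).
#' @return An object of class `benchmark_result`: `results` (tidy data
#'   frame: plant, t_off, p_ss, controller, model_ids, sq_error),
#'   `summary` (mean, standard error and n per controller class),
#'   `reductions` (percent reduction of mean `M_aw` error vs each
#'   comparator class), and `sequences` (list of control sequences).
#' @export
run_benchmark <- function(bank, targets = target_preset(),
                          cfg = run_config(), noise_sd = 0.05,
                          n_timepoints = 31, seed = 1L,
                          plants = names(bank$models)) {
  models <- bank$models
  ids <- names(models)
  stopifnot(length(models) == 3)
  rows <- list()
  seqs <- list()
  for (plant_id in plants) {
    plant <- models[[plant_id]]
    others <- ids[ids != plant_id]
    td <- simulate_training_data(plant, noise_sd = noise_sd,
                                 n_timepoints = n_timepoints, seed = seed,
                                 space = cfg$space)
    wmap <- build_weight_map(models[others], td, space = cfg$space)
    for (r in seq_len(nrow(targets))) {
      target <- target_trajectory(targets$t_off[r], targets$p_ss[r])
      runs <- list(
        list(controller = "S_matched", models = list(plant), wmap = NULL,
             w_fixed = 1),
        list(controller = "S_mismatched", models = models[others[1]],
             wmap = NULL, w_fixed = 1),
        list(controller = "S_mismatched", models = models[others[2]],
             wmap = NULL, w_fixed = 1),
        list(controller = "M_eq", models = models[others], wmap = NULL,
             w_fixed = c(0.5, 0.5)),
        list(controller = "M_aw", models = models[others], wmap = wmap,
             w_fixed = NULL))
      for (run in runs) {
        res <- tryCatch({
          useq <- run_open_loop(run$models, run$wmap, target, cfg,
                                w_fixed = run$w_fixed)
          ap <- apply_to_plant(plant, useq, target, cfg$space, cfg$t_final)
          key <- paste(plant_id, targets$t_off[r], targets$p_ss[r],
                       run$controller,
                       paste(vapply(run$models, function(m) m$model_id,
                                    character(1)), collapse = ""),
                       sep = "_")
          seqs[[key]] <- useq
          data.frame(plant = plant_id, t_off = targets$t_off[r],
                     p_ss = targets$p_ss[r], controller = run$controller,
                     model_ids = paste(vapply(run$models,
                                              function(m) m$model_id,
                                              character(1)), collapse = "+"),
                     sq_error = ap$sq_error, failed = FALSE,
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(plant = plant_id, t_off = targets$t_off[r],
                     p_ss = targets$p_ss[r], controller = run$controller,
                     model_ids = paste(vapply(run$models,
                                              function(m) m$model_id,
                                              character(1)), collapse = "+"),
                     sq_error = NA_real_, failed = TRUE,
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  ok <- results[!results$failed, ]
  agg <- do.call(rbind, lapply(split(ok, ok$controller), function(g) {
    data.frame(controller = g$controller[1], n = nrow(g),
               mean_sq_error = mean(g$sq_error),
               se_sq_error = stats::sd(g$sq_error) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  m_aw <- agg$mean_sq_error[agg$controller == "M_aw"]
  reductions <- vapply(c("S_matched", "S_mismatched", "M_eq"), function(cl) {
    cmp <- agg$mean_sq_error[agg$controller == cl]
    if (length(cmp) == 0 || length(m_aw) == 0) return(NA_real_)
    100 * (1 - m_aw / cmp)
  }, numeric(1))
  structure(list(results = results, summary = agg, reductions = reductions,
                 sequences = seqs),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary, row.names = FALSE)
  cat("percent reduction of M_aw mean sq error vs:\n")
  for (nm in names(x$reductions)) {
    cat(sprintf("  %-13s %6.1f%%\n", nm, x$reductions[[nm]]))
  }
  invisible(x)
}

#' Weight-map sensitivity to training-data volume
#'
#' Trains weight maps on a full and a limited dataset generated from the
#' same plant, reports the lattice fraction at which the two maps rank the
#' models identically, the fraction at which the plant-matched... (for
#' plant-generated data the best-matching member) leads, and the dose
#' differences of the control sequences designed under each map for each
#' target.
#'
#' @param models the prediction bank (list of models).
#' @param full_dataset,limited_dataset two `training_dataset`s from the
#'   same plant with different raw sampling density.
#' @param targets targets to compare regimens on (default: the full
#'   preset).
#' @param cfg a [run_config()].
#' @param n1,n2 ranking lattice resolution.
#' @return A list: `agreement` (fraction), `dose_diff` (per-target max
#'   absolute dose difference), `sequences` (pairs of control sequences).
#' @export
weight_map_sensitivity <- function(models, full_dataset, limited_dataset,
                                   targets = target_preset(),
                                   cfg = run_config(), n1 = 11, n2 = 11) {
  wm_full <- build_weight_map(models, full_dataset, space = cfg$space)
  wm_lim <- build_weight_map(models, limited_dataset, space = cfg$space)
  agreement <- ranking_agreement(wm_full, wm_lim, n1 = n1, n2 = n2)
  dose_diff <- numeric(nrow(targets))
  sequences <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    target <- target_trajectory(targets$t_off[r], targets$p_ss[r])
    s_full <- run_open_loop(models, wm_full, target, cfg)
    s_lim <- run_open_loop(models, wm_lim, target, cfg)
    dose_diff[r] <- max(abs(s_full$doses - s_lim$doses))
    sequences[[r]] <- list(full = s_full, limited = s_lim)
  }
  list(agreement = agreement, dose_diff = dose_diff, sequences = sequences,
       targets = targets)
}

#' Export a control sequence to tidy CSV / JSON
#'
#' @param useq a `control_sequence`.
#' @param path output path (`.csv` or `.json` by extension).
#' @return `path` invisibly.
#' @export
write_control_sequence <- function(useq, path) {
  df <- data.frame(dose_time_min = useq$dose_times, useq$doses)
  names(df)[-1] <- paste0("u", seq_len(ncol(useq$doses)))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
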