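# Pipeline orchestration: simulate a designed experiment, analyze sessions
# end to end, compare groups. Reports embed the effective configuration and
# seeds so every run is exactly reproducible.

default_analysis_params <- function() {
  list(
    lowpass_cutoff = 2, filter_order = 3,
    transient_start_k = 2, transient_end_k = 0.5, transient_iter = 3,
    baseline_window = 30, min_duration = 3,
    tuning_bins = 100, tuning_thresh_k = 2,
    curve_bins = 20, decoder_bins = 20,
    n_splits = 10, train_frac = 0.75, decoder_lambda = 0.01,
    subsample_n = 42, subsample_draws = 10,
    criterion = 0.70, r2_threshold = 0.5,
    n_boot = 100000L
  )
}

#' Simulate a designed experiment to disk
#'
#' Writes one synthetic session per animal for each condition, with per-
#' condition gain multipliers, plus ground-truth CSVs and a manifest.
#'
#' @param conditions Named numeric vector of gain multipliers, e.g.
#'   `c(control = 1, enriched = 2)`.
#' @param n_animals Animals per condition.
#' @param out_dir Output directory.
#' @param config Base [synthetic_config()]; per-animal seeds are derived
#'   from its seed.
#' @return The manifest data frame (`condition`, `animal`, `gain`, `seed`,
#'   `path`), also written to `manifest.csv`, invisibly.
#' @export
run_simulate <- function(conditions, n_animals, out_dir,
                         config = synthetic_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cond in names(conditions)) {
    for (m in seq_len(n_animals)) {
      cfg <- config
      cfg$gain <- config$gain * conditions[[cond]]
      cfg$seed <- derive_seed(config$seed, paste0("animal/", cond, "/", m))
      sim <- simulate_session(cfg)
      sim$session$metadata$condition <- cond
      sim$session$metadata$animal <- sprintf("%s_%02d", cond, m)
      path <- file.path(out_dir, sprintf("session_%s_%02d.dgs", cond, m))
      write_session(sim$session, path)
      write_ground_truth_csv(sim$truth, sub("\\.dgs$", "_truth.csv", path))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, animal = sim$session$metadata$animal,
        gain = cfg$gain, seed = cfg$seed, path = path
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Analyze one session end to end
#'
#' Runs the full single-session pipeline in order: low-pass filtering and
#' significant-transient detection, distance-normalized activity,
#' deconvolution and tuning index, lap-by-bin tuning curves with von Mises
#' fits and cross-validated R^2, position decoding (with neuron
#' subsampling), and bias-corrected Fisher information with discrimination
#' threshold.
#'
#' @param session A `dg_session` or a path readable by [read_session()].
#' @param params Analysis parameters; see `default_analysis_params` values
#'   in the package sources. Entries override the defaults.
#' @param seed Root seed for splits, subsampling, and shuffles.
#' @param decode Run the decoder stage (the slowest stage).
#' @param out_dir Optional directory for CSV/JSON reports.
#' @return A `dg_report`: `neurons` (per-neuron data frame), `summary`
#'   (session-level list), `params`, `seed`.
#' @export
run_analyze <- function(session, params = list(), seed = 1L, decode = TRUE,
                        out_dir = NULL) {
  if (is.character(session)) session <- read_session(session)
  validate_session(session)
  p <- utils::modifyList(default_analysis_params(), params)
  fr <- session$frame_rate
  cfg <- session$metadata$config

  filtered <- lowpass_filter(session$dff, fr, p$lowpass_cutoff, p$filter_order)
  tset <- detect_transients(filtered, fr, p$transient_start_k, p$transient_end_k,
                            p$transient_iter, p$baseline_window, p$min_duration)
  activity <- compute_activity(tset, session)

  tau <- if (!is.null(cfg)) cfg$decay_tau else 1
  rates <- deconvolve(session$dff, tau, fr)
  tun <- tuning_vector(rates, session, p$tuning_bins, p$tuning_thresh_k)

  nn <- n_neurons(session)
  fits <- vector("list", nn)
  r2 <- numeric(nn)
  for (i in seq_len(nn)) {
    curve <- build_tuning_curve(session$dff[i, ], session, p$curve_bins)
    fits[[i]] <- fit_von_mises(curve)
    r2[i] <- cross_validated_r2(curve, p$n_splits, p$train_frac,
                                seed = derive_seed(seed, paste0("cv/", i)))$r2
  }
  neurons <- data.frame(
    neuron = seq_len(nn),
    activity = activity,
    tuning_index = tun$index,
    B = vapply(fits, `[[`, numeric(1), "B"),
    A = vapply(fits, `[[`, numeric(1), "A"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    phi_deg = vapply(fits, `[[`, numeric(1), "phi") * 180 / pi,
    V = peak_width(vapply(fits, `[[`, numeric(1), "k")),
    r2_cv = r2,
    well_fitted = r2 > p$r2_threshold
  )

  tensor <- build_trial_tensor(session, p$decoder_bins)
  sc <- single_cell_fisher_info(tensor)
  neurons$fisher_d2 <- sc$d2

  summary <- list(
    n_neurons = nn, n_laps = max(session$lap_index) + 1L,
    median_activity = stats::median(activity),
    mean_tuning_index = mean(tun$index),
    well_fitted_fraction = mean(neurons$well_fitted),
    mean_r2 = mean(r2),
    mean_single_cell_d2 = mean(sc$d2, na.rm = TRUE),
    condition = session$metadata$condition %||% NA_character_,
    animal = session$metadata$animal %||% NA_character_
  )

  if (decode) {
    sub <- subsample_neurons(tensor, p$subsample_n, p$subsample_draws,
                             seed = derive_seed(seed, "subsample"))
    if (isTRUE(sub$met)) {
      accs <- vapply(seq_along(sub$subsets), function(d) {
        keep <- sub$subsets[[d]]
        sess_d <- session
        sess_d$dff <- session$dff[keep, , drop = FALSE]
        sess_d$raw_f <- NULL
        sess_d$rates <- NULL
        dec <- decode_position(sess_d, n_bins = p$decoder_bins,
                               n_splits = p$n_splits, train_frac = p$train_frac,
                               lambda = p$decoder_lambda,
                               seed = derive_seed(seed, paste0("decode/", d)))
        pop <- population_fisher_info(sub$draws[[d]], dec$weights)
        c(dec$accuracy, pop$J_per_cm2)
      }, numeric(2))
      summary$decoder_accuracy <- mean(accs[1, ])
      summary$population_J_per_cm2 <- mean(accs[2, ])
      summary$subsample_met <- TRUE
    } else {
      dec <- decode_position(session, n_bins = p$decoder_bins,
                             n_splits = p$n_splits, train_frac = p$train_frac,
                             lambda = p$decoder_lambda,
                             seed = derive_seed(seed, "decode/full"))
      pop <- population_fisher_info(tensor, dec$weights)
      summary$decoder_accuracy <- dec$accuracy
      summary$population_J_per_cm2 <- pop$J_per_cm2
      summary$subsample_met <- FALSE
    }
    summary$discrimination_threshold_cm <-
      discrimination_threshold(summary$population_J_per_cm2, p$criterion)
  }

  report <- structure(list(neurons = neurons, summary = summary, params = p,
                           seed = seed), class = "dg_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(neurons, file.path(out_dir, "neurons.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary, params = p, seed = seed,
           package_version = as.character(utils::packageVersion("dgspace"))),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' @export
print.dg_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dg_report> %d neurons, %d laps\n", s$n_neurons, s$n_laps))
  cat(sprintf("  median activity      %.4g dF/F.s/cm\n", s$median_activity))
  cat(sprintf("  mean tuning index    %.3f\n", s$mean_tuning_index))
  cat(sprintf("  well-fitted fraction %.2f (mean R2 %.2f)\n",
              s$well_fitted_fraction, s$mean_r2))
  if (!is.null(s$decoder_accuracy))
    cat(sprintf("  decoder accuracy     %.1f%%\n", 100 * s$decoder_accuracy))
  if (!is.null(s$discrimination_threshold_cm))
    cat(sprintf("  discrim. threshold   %.2f cm\n", s$discrimination_threshold_cm))
  invisible(x)
}

#' Compare conditions across analyzed sessions
#'
#' Pools per-neuron metrics by condition and animal and tests each metric
#' between the two conditions with the nested bootstrap, Bonferroni-adjusted
#' across metrics.
#'
#' @param reports List of `dg_report`s (each must carry condition and animal
#'   metadata in its summary).
#' @param metrics Per-neuron columns to compare.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param out_file Optional JSON report path.
#' @return Data frame: `metric`, `condition_a`, `condition_b`, `observed`,
#'   `p`, `p_adj`.
#' @export
run_compare <- function(reports, metrics = c("activity", "tuning_index", "A",
                                             "r2_cv", "fisher_d2"),
                        n_boot = 10000L, seed = 1L, out_file = NULL) {
  conds <- vapply(reports, function(r) r$summary$condition, character(1))
  animals <- vapply(reports, function(r) r$summary$animal, character(1))
  if (anyNA(conds) || anyNA(animals))
    stop("invalid input: every report needs condition and animal metadata", call. = FALSE)
  u <- unique(conds)
  if (length(u) != 2) stop("run_compare expects exactly two conditions", call. = FALSE)

  pull <- function(cond, metric) {
    idx <- which(conds == cond)
    vals <- lapply(idx, function(i) {
      v <- reports[[i]]$neurons[[metric]]
      v[is.finite(v)]
    })
    names(vals) <- animals[idx]
    nested_sample(vals, cond)
  }
  rows <- lapply(metrics, function(m) {
    t <- nested_bootstrap_test(pull(u[1], m), pull(u[2], m), n_boot = n_boot,
                               seed = derive_seed(seed, paste0("compare/", m)))
    data.frame(metric = m, condition_a = u[1], condition_b = u[2],
               observed = t$observed, p = t$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p, length(metrics))
  if (!is.null(out_file)) {
    jsonlite::write_json(
      list(comparison = out, n_boot = n_boot, seed = seed,
           package_version = as.character(utils::packageVersion("dgspace"))),
      out_file, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
  }
  out
}
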