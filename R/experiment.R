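# Umbrella experiment runner: simulate -> preprocess -> train per input
# configuration -> evaluate -> compare -> uncertainty, with a manifest.

#' Experiment configuration
#'
#' Model defaults mirror [model_config()]; the experiment-level defaults
#' are scaled for desk-size synthetic runs and every stochastic stage has
#' its own seed.  `conditions` is a named list of metadata feature subsets
#' (character vectors; `character(0)` is the time-series-only condition).
#'
#' @param n number of synthetic records.
#' @param data_seed,model_seed,mc_seed seeds for simulation, training and
#'   Monte Carlo dropout.
#' @param conditions named list of feature subsets.
#' @param model `"dual"`, `"earlyfusion"` or `"unet"`.
#' @param mc_passes stochastic passes for the uncertainty stage.
#' @param epsilon stability constant of the relative error.
#' @param alpha significance level of the paired comparisons.
#' @param ... overrides forwarded to [model_config()].
#' @return A named list of class `run_config`.
#' @export
run_config <- function(n = 200L, data_seed = 1L, model_seed = 1L,
                       mc_seed = 1L,
                       conditions = list(timeseries_only = character(0),
                                         all_features = METADATA_FEATURES),
                       model = "dual", mc_passes = 50L, epsilon = 1e-3,
                       alpha = 0.05, ...) {
  structure(list(n = n, data_seed = data_seed, model_seed = model_seed,
                 mc_seed = mc_seed, conditions = conditions, model = model,
                 mc_passes = mc_passes, epsilon = epsilon, alpha = alpha,
                 model_config = model_config(seed = model_seed, ...)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$model_config <- unclass(x$model_config)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  # YAML has no empty character vector; normalize condition entries
  x$conditions <- lapply(x$conditions, as.character)
  mc <- x$model_config
  x$model_config <- NULL
  cfg <- do.call(run_config, c(x[setdiff(names(x), "model_config")]))
  cfg$model_config <- do.call(model_config, mc)
  cfg
}

#' Run a full reconstruction experiment
#'
#' Simulates a dataset, builds windowed pairs for each input configuration,
#' trains one model per condition, evaluates on the held-out test split
#' (including segment-wise correlations), compares every condition against
#' the first one with the paired-test protocol, runs the Monte Carlo
#' dropout uncertainty stage on the last condition's model, and writes all
#' reports plus a manifest to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir artifact directory (created).
#' @param verbose print stage progress?
#' @return The manifest (named list), invisibly; all artifacts are files
#'   under `out_dir`.
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(config = unclass(config), files = character(0),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("ecgrecon")),
                   started = format(Sys.time()))
  add_file <- function(f) manifest$files <<- c(manifest$files, f)

  say("[simulate] n = %d records", config$n)
  ds <- generate_dataset(config$n, seed = config$data_seed)
  write_metadata_sidecar(ds$records, file.path(out_dir, "metadata.csv"),
                         ds$split)
  add_file("metadata.csv")

  fits <- list(); reports <- list()
  for (cname in names(config$conditions)) {
    feats <- config$conditions[[cname]]
    say("[preprocess] condition '%s' (D = %d)", cname, one_hot_dim(feats))
    pairs <- make_windowed_pairs(ds$records, ds$split, features = feats)
    say("[train] condition '%s'", cname)
    fit <- ecg_reconstruct(pairs, model = config$model,
                           config = config$model_config)
    test <- pairs_subset(pairs, "test")
    say("[evaluate] condition '%s' on %d test records", cname, nrow(test$X))
    pred <- predict(fit, test)
    rep <- evaluate_reconstruction(pred, test, segments = TRUE,
                                   label = cname)
    f <- sprintf("report_%s.csv", cname)
    utils::write.csv(cbind(condition = cname, rep$overall),
                     file.path(out_dir, f), row.names = FALSE)
    add_file(f)
    fits[[cname]] <- fit
    reports[[cname]] <- rep
    manifest$conditions[[cname]] <- list(features = feats,
                                         D = one_hot_dim(feats))
  }

  if (length(reports) >= 2) {
    base <- names(reports)[1]
    cmp <- do.call(rbind, lapply(names(reports)[-1], function(cn) {
      cbind(condition = cn,
            compare_models(reports[[cn]], reports[[base]],
                           alpha = config$alpha))
    }))
    utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    add_file("comparison.csv")
  }

  say("[uncertainty] MC dropout, N = %d", config$mc_passes)
  last <- names(fits)[length(fits)]
  fit <- fits[[last]]
  pairs <- make_windowed_pairs(ds$records, ds$split,
                               features = config$conditions[[last]])
  test <- pairs_subset(pairs, "test")
  n_unc <- min(nrow(test$X), 25L)
  profiles <- vector("list", n_unc); errors <- vector("list", n_unc)
  for (i in seq_len(n_unc)) {
    st <- mc_predict(fit, test$X[i, ], test$M[i, ], N = config$mc_passes,
                     seed = config$mc_seed + i)
    profiles[[i]] <- normalize_std(predictive_std(st))
    errors[[i]] <- relative_error(st$mean, test$Y[i, , ],
                                  eps = config$epsilon)
  }
  corr <- uncertainty_error_correlation(profiles, errors)
  utils::write.csv(data.frame(lead = names(corr), correlation = corr),
                   file.path(out_dir, "uncertainty_correlation.csv"),
                   row.names = FALSE)
  add_file("uncertainty_correlation.csv")
  qt <- quantile_error_table(profiles, errors)
  utils::write.csv(qt, file.path(out_dir, "uncertainty_quartiles.csv"),
                   row.names = FALSE)
  add_file("uncertainty_quartiles.csv")
  hm <- file.path(out_dir, "heatmap.png")
  st <- mc_predict(fit, test$X[1, ], test$M[1, ], N = config$mc_passes,
                   seed = config$mc_seed)
  render_heatmap(st$mean, test$Y[1, , ],
                 normalize_std(predictive_std(st))$sigma_norm, hm)
  add_file("heatmap.png")

  manifest$finished <- format(Sys.time())
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
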