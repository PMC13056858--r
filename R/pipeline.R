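#' Run configuration for the end-to-end pipeline
#'
#' One global seed fans out deterministically to per-stage seeds; every
#' stage block collects the parameters of the corresponding stage
#' functions. The configuration round-trips losslessly through YAML.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (`NULL` = keep everything in memory).
#' @param cohort Named list of [cohort_config()] overrides.
#' @param preprocess Named list of [preprocess_config()] overrides.
#' @param peaks Peak-stage parameters: `snr_min`, `window_da`, `tol_ppm`,
#'   `fill`, `min_support`.
#' @param bench Bench parameters: `train_frac`, `crossval_k`.
#' @param explain Explain parameters: `k`, `shap_families`,
#'   `lime_families`, `n_perturb`, `max_eval`.
#' @param evaluate Evaluation parameters: `cluster_k`, `embed_method`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 7L, out_dir = NULL, cohort = list(),
                       preprocess = list(), peaks = list(), bench = list(),
                       explain = list(), evaluate = list()) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
    preprocess = modifyList(preprocess_config(), preprocess),
    peaks = modifyList(list(snr_min = 3, window_da = 200, tol_ppm = 2500,
                            fill = "zero", min_support = 0.25), peaks),
    bench = modifyList(list(train_frac = 0.8, crossval_k = 5), bench),
    explain = modifyList(list(k = 20,
                              shap_families = c("xgboost", "lightgbm",
                                                "random_forest"),
                              lime_families = c("xgboost", "random_forest"),
                              n_perturb = 1000, max_eval = 100,
                              shap_n_perm = 30, shap_max_eval = 50),
                         explain),
    evaluate = modifyList(list(cluster_k = 2, embed_method = "pca"),
                          evaluate)),
    class = "run_config")
}

#' Deterministic per-stage seed derived from the global seed
#' @param seed Global seed.
#' @param stage Stage name.
#' @return An integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 97003) %% 2147483629 + 1)
}

#' Write / read a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(seed = raw$seed %||% 7L, out_dir = raw$out_dir,
             cohort = raw$cohort %||% list(),
             preprocess = raw$preprocess %||% list(),
             peaks = raw$peaks %||% list(),
             bench = raw$bench %||% list(),
             explain = raw$explain %||% list(),
             evaluate = raw$evaluate %||% list())
}

# tiny FNV-style content hash for the manifest
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full workbench end to end
#'
#' Simulate (or accept) a cohort, preprocess every spectrum, detect and
#' align peaks, build the feature matrix, run the differential screen, the
#' eight-family bench, the Gini/SHAP/LIME importances, the core-feature
#' intersection, the simplified-model rebuild with decision curves, and the
#' unsupervised clustering check. Artifacts are persisted under
#' `cfg$out_dir` when set, and a manifest records seeds, the configuration
#' hash and per-stage sizes. Re-running the same configuration reproduces
#' all deterministic artifacts bit-identically.
#'
#' @param cfg A [run_config()].
#' @param cohort Optional pre-built `maldi_cohort` (bypasses simulation);
#'   must carry labels.
#' @return A named list of stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), cohort = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  persist <- function(fn, name) if (!is.null(out)) fn(file.path(out, name))

  if (is.null(cohort)) {
    cc <- do.call(cohort_config,
                  modifyList(cfg$cohort,
                             list(seed = derive_seed(cfg$seed, "simulate"))))
    cohort <- generate_cohort(cc)
  }
  if (!"label" %in% names(cohort$samples)) abort("cohort carries no labels.")
  persist(function(p) write_sample_sheet(cohort$samples, p), "samples.csv")
  if (!is.null(cohort$truth)) {
    persist(function(p) write_ground_truth_json(cohort$truth, p),
            "ground_truth.json")
  }

  pp <- preprocess_all(cohort, cfg$preprocess)
  peaks <- detect_peaks_all(pp, snr_min = cfg$peaks$snr_min,
                            window_da = cfg$peaks$window_da)
  artifact_mzs <- cohort$truth$artifact_mz %||% numeric(0)
  peaks <- filter_matrix_clusters(peaks, artifact_mzs,
                                  tol_ppm = cfg$peaks$tol_ppm)
  bins <- align_peaks(peaks, tol_ppm = cfg$peaks$tol_ppm,
                      sample_ids = cohort$samples$sample_id)
  fm <- build_feature_matrix(bins, sample_ids = cohort$samples$sample_id,
                             labels = cohort$samples, fill = cfg$peaks$fill,
                             min_support = cfg$peaks$min_support)
  persist(function(p) write_feature_matrix(fm, p,
            file.path(out, "labels.csv")), "feature_matrix.csv")

  diff_tbl <- differential_screen(fm)
  persist(function(p) utils::write.csv(as.data.frame(diff_tbl), p,
                                       row.names = FALSE),
          "differential_table.csv")

  split <- stratified_split(cohort$samples, train_frac = cfg$bench$train_frac,
                            seed = derive_seed(cfg$seed, "split"))
  specs <- default_model_specs(seed = derive_seed(cfg$seed, "bench"))
  bench <- train_classifiers(fm, split, specs)
  metrics <- evaluate_classifiers(bench)
  persist(function(p) utils::write.csv(as.data.frame(metrics), p,
                                       row.names = FALSE), "bench_metrics.csv")

  shap <- shap_importance(bench, families = cfg$explain$shap_families,
                          n_perm = cfg$explain$shap_n_perm,
                          max_eval = cfg$explain$shap_max_eval,
                          seed = derive_seed(cfg$seed, "shap"))
  lime <- lime_importance(bench, families = cfg$explain$lime_families,
                          n_perturb = cfg$explain$n_perturb,
                          max_eval = cfg$explain$max_eval,
                          seed = derive_seed(cfg$seed, "lime"))
  gini <- gini_importance(bench)
  persist(function(p) utils::write.csv(
    as.data.frame(bind_rows(gini, shap$table, lime$table)), p,
    row.names = FALSE), "importance_tables.csv")
  core <- select_core_features(shap, lime, k = cfg$explain$k)
  persist(function(p) jsonlite::write_json(
    core[c("shap_top", "lime_top", "shared", "shap_unique", "lime_unique")],
    p, pretty = TRUE), "core_features.json")

  rebuild <- rebuild_on_core(fm, core, split, specs)
  persist(function(p) utils::write.csv(as.data.frame(rebuild$metrics), p,
                                       row.names = FALSE),
          "core_metrics.csv")
  if (!is.null(out)) {
    for (fam in names(rebuild$dca)) {
      utils::write.csv(as.data.frame(rebuild$dca[[fam]]),
                       file.path(out, sprintf("dca_%s.csv", fam)),
                       row.names = FALSE)
    }
  }

  clusters <- cluster_and_embed(fm, features = core,
                                k = cfg$evaluate$cluster_k,
                                seed = derive_seed(cfg$seed, "cluster"),
                                embed_method = cfg$evaluate$embed_method)

  manifest <- list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    stage_seeds = list(simulate = derive_seed(cfg$seed, "simulate"),
                       split = derive_seed(cfg$seed, "split"),
                       bench = derive_seed(cfg$seed, "bench"),
                       shap = derive_seed(cfg$seed, "shap"),
                       lime = derive_seed(cfg$seed, "lime"),
                       cluster = derive_seed(cfg$seed, "cluster")),
    n_spectra = length(cohort$spectra),
    n_peaks = nrow(peaks), n_bins = nrow(bins$bins),
    matrix_dim = dim(feature_values(fm)),
    n_bench_rows = nrow(metrics),
    n_core_shared = length(core$shared))
  persist(function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                           pretty = TRUE), "manifest.json")

  list(cohort = cohort, peaks = peaks, bins = bins, feature_matrix = fm,
       differential = diff_tbl, split = split, bench = bench,
       metrics = metrics, gini = gini, shap = shap, lime = lime,
       core = core, rebuild = rebuild, clusters = clusters,
       manifest = manifest)
}
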