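# End-to-end orchestration: simulate -> extract -> contexts ->
# repeatability -> syndromes, with a run manifest.

#' Run the full analysis pipeline on a synthetic flock
#'
#' Orchestrates the whole workflow at a configurable scale: simulates a
#' flock (behaviour-level by default; trajectory-level with extraction when
#' `route = "trajectory"`), selects context days, builds the six analysis
#' sets, computes the repeatability grid and (optionally) fits the
#' multivariate syndrome model with its eigen axes and extreme profiles.
#' Every source of randomness is derived from `cfg$seed`, so two runs with
#' the same configuration are identical.
#'
#' @param cfg a [flock_config()].
#' @param route `"behaviour"` (statistical generator) or `"trajectory"`
#'   (transition streams plus extraction; slower, exercises every stage).
#' @param n_boot bootstrap replicates for the repeatability grid.
#' @param syndromes fit the multivariate model? (logical)
#' @param mcmc a [multivariate_spec()] used when `syndromes = TRUE`.
#' @param out_dir optional directory: results are written as CSV/YAML.
#' @return list with `behaviours`, `contexts`, `analysis_sets`,
#'   `repeatability`, `syndromes` (or `NULL`), `axes`, `profiles`, `truth`
#'   and a `manifest` (seeds, row counts, drops).
#' @export
run_pipeline <- function(cfg = flock_config(), route = c("behaviour", "trajectory"),
                         n_boot = 0L, syndromes = TRUE,
                         mcmc = multivariate_spec(seed = cfg$seed),
                         out_dir = NULL) {
  route <- match.arg(route)
  sim <- simulate_behaviour_table(cfg)
  if (route == "trajectory") {
    tg <- behaviour_targets(cfg)
    sched <- day_schedule()
    tr <- simulate_transitions(tg, sched, seed = cfg$seed)
    span <- range(tg$date)
    iv <- to_intervals(tr, day_start(span[1]),
                       day_start(span[2] + 1) + sched$lights_on)
    beh <- extract_all(iv, sched, seq(span[1], span[2], by = "day"),
                       feed_response_config(rng_seed = cfg$seed))
    covar_cols <- c("hen_id", "date", "pen", "feed_chain", "class",
                    "treatment", "days_in_barn", "kbf", "mass")
    beh <- merge(beh, sim$behaviours[, covar_cols], by = c("hen_id", "date"))
  } else {
    beh <- sim$behaviours
  }
  contexts <- select_context_days(sim$calendar$dates,
                                  sim$calendar$temperature,
                                  sim$calendar$vaccination_dates)
  sets <- make_analysis_sets(beh, contexts)
  grid <- repeatability_matrix(sets, n_boot = n_boot, seed = cfg$seed)
  syn <- axes <- profiles <- NULL
  if (isTRUE(syndromes)) {
    syn <- fit_multivariate(sets$across_contexts, mcmc)
    axes <- eigen_axes(syn)
    if (any(axes$retained))
      profiles <- project_profiles(beh, axes, syn, seed = cfg$seed)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("aviarytraits")),
    seed = cfg$seed, route = route,
    n_hens = cfg$n_hens, n_days = cfg$n_days,
    n_behaviour_rows = nrow(beh),
    n_missing = vapply(beh[c("vtd", "fdr", "nest_timing", "wg", "sleep_top")],
                       function(x) sum(is.na(x)), integer(1)),
    context_days = lapply(contexts, as.character),
    excluded_days = as.character(attr(contexts, "excluded")),
    set_rows = vapply(sets, nrow, integer(1)),
    skipped_fits = attr(grid, "skipped"),
    omitted_across = attr(sets$across_contexts, "omitted"))
  out <- list(behaviours = beh, contexts = contexts, analysis_sets = sets,
              repeatability = grid, syndromes = syn, axes = axes,
              profiles = profiles, truth = sim$truth, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_behaviours(beh, file.path(out_dir, "behaviours.csv"))
    utils::write.csv(grid, file.path(out_dir, "repeatability.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    yaml::write_yaml(lapply(contexts, as.character),
                     file.path(out_dir, "contexts.yaml"))
    if (!is.null(syn))
      utils::write.csv(syn$pair_summary,
                       file.path(out_dir, "syndrome_correlations.csv"),
                       row.names = FALSE)
    if (!is.null(axes)) {
      ld <- data.frame(trait = rep(rownames(axes$loadings),
                                   ncol(axes$loadings)),
                       component = rep(colnames(axes$loadings),
                                       each = nrow(axes$loadings)),
                       loading = as.vector(axes$loadings),
                       sd = as.vector(axes$loading_sd))
      utils::write.csv(ld, file.path(out_dir, "eigen_axes.csv"),
                       row.names = FALSE)
    }
  }
  out
}
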