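# End-to-end orchestration: ingest a dataset manifest, score every receptor,
# aggregate across receptors, and evaluate against a key-site list.

#' Pipeline configuration
#'
#' Collects the free parameters of the method: the network cutoff, the
#' zero-eigenvalue tolerance, the frame stride for multi-model files, the
#' position whitelist and key-site list, and the seed feeding any stochastic
#' stage (only the domain decomposition restarts are stochastic).
#'
#' @param cutoff mean-distance cutoff in Angstrom (> 0, default 12).
#' @param zero_tol relative zero-eigenvalue threshold (default 1e-9).
#' @param stride keep every stride-th MODEL of multi-model files (>= 1).
#' @param whitelist_path optional whitelist override file.
#' @param sites_path optional key-site list override file.
#' @param seed integer seed.
#' @param mask_disconnecting score network-splitting residues as `NA`.
#' @param partial_as_active count partially active structures as active when
#'   pairing.
#' @return a `mech_config` list.
#' @export
mech_config <- function(cutoff = 12, zero_tol = 1e-9, stride = 1L,
                        whitelist_path = NULL, sites_path = NULL,
                        seed = 0L, mask_disconnecting = FALSE,
                        partial_as_active = FALSE) {
  stopifnot(cutoff > 0, stride >= 1)
  structure(list(cutoff = cutoff, zero_tol = zero_tol,
                 stride = as.integer(stride),
                 whitelist_path = whitelist_path, sites_path = sites_path,
                 seed = as.integer(seed),
                 mask_disconnecting = mask_disconnecting,
                 partial_as_active = partial_as_active),
            class = "mech_config")
}

#' Run the full scoring pipeline over a dataset manifest
#'
#' For every receptor in the manifest: loads the structures, intersects them
#' on the common residue set, computes distance statistics, builds the
#' coupling network and the bridging profile. Profiles are then aligned on
#' shared generic numbers, averaged, and the averaged profile is evaluated
#' with a ROC curve against the key-site list. A coordination-number
#' baseline is computed and evaluated the same way. When `out_dir` is given,
#' per-receptor profile TSVs, the aggregated profile, both ROC curves and a
#' plain-text run log are written there.
#'
#' @param manifest a data.frame from [read_manifest()] (or its file path).
#' @param numbering a numbering map from [load_numbering_map()] (or its file
#'   path), or `NULL` to skip aggregation.
#' @param config a [mech_config()].
#' @param out_dir optional output directory.
#' @param chain_filter optional chain passed to [load_structures()].
#' @return a list: `profiles` (per receptor), `aggregated`, `coordination`,
#'   `roc`, `roc_coordination`, `config`.
#' @export
run_pipeline <- function(manifest, numbering = NULL, config = mech_config(),
                         out_dir = NULL, chain_filter = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(numbering)) numbering <- load_numbering_map(numbering)
  receptors <- unique(manifest$receptor_id)
  profiles <- list()
  coord_profiles <- list()
  for (rec in receptors) {
    rows <- manifest[manifest$receptor_id == rec, , drop = FALSE]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] %s failed: %s", rec, what, conditionMessage(e)))
      })
    }
    models <- stage("ingest",
                    load_structures(rows$path, chain_filter = chain_filter,
                                    stride = config$stride,
                                    state_labels = rows$state))
    ens <- stage("intersect", intersect_residues(models, receptor_id = rec))
    stats <- stage("stats", distance_stats(ens))
    net <- stage("network", build_network(stats, cutoff = config$cutoff))
    profiles[[rec]] <- stage("bridging", bridging_profile(
      net, zero_tol = config$zero_tol,
      mask_disconnecting = config$mask_disconnecting, receptor_id = rec))
    coord_profiles[[rec]] <- coordination_profile(stats, config$cutoff, rec)
  }
  aggregated <- NULL
  coordination <- NULL
  roc <- NULL
  roc_coord <- NULL
  if (!is.null(numbering)) {
    whitelist <- default_whitelist(config$whitelist_path)
    tab <- align_profiles(profiles, numbering, whitelist)
    aggregated <- average_profile(tab)
    ctab <- align_profiles(coord_profiles, numbering, whitelist)
    coordination <- average_profile(ctab)
    sites <- default_key_sites(config$sites_path)
    scores <- stats::setNames(aggregated$mean_score, aggregated$position)
    cscores <- stats::setNames(coordination$mean_score,
                               coordination$position)
    if (any(sites %in% names(scores)) && !all(names(scores) %in% sites)) {
      roc <- roc_curve(scores, sites)
      roc_coord <- roc_curve(cscores, sites)
    }
  }
  result <- list(profiles = profiles, aggregated = aggregated,
                 coordination = coordination, roc = roc,
                 roc_coordination = roc_coord, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, numbering, out_dir)
  result
}

write_pipeline_outputs <- function(result, numbering, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in names(result$profiles)) {
    p <- result$profiles[[rec]]
    gen <- if (!is.null(numbering)) generic_numbers(numbering, rec,
                                                    p$residues)
           else p$residues$generic_number
    write_profile_tsv(p, file.path(out_dir, sprintf("profile_%s.tsv", rec)),
                      generic = gen)
  }
  if (!is.null(result$aggregated)) {
    utils::write.table(result$aggregated,
                       file.path(out_dir, "aggregated_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$coordination)) {
    utils::write.table(result$coordination,
                       file.path(out_dir, "coordination_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$roc)) {
    write_roc_tsv(result$roc, file.path(out_dir, "roc_bridging.tsv"))
  }
  if (!is.null(result$roc_coordination)) {
    write_roc_tsv(result$roc_coordination,
                  file.path(out_dir, "roc_coordination.tsv"))
  }
  cfg <- result$config
  log_lines <- c(
    sprintf("mechbridge %s", as.character(utils::packageVersion("mechbridge"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("cutoff=%g", cfg$cutoff),
    sprintf("zero_tol=%g", cfg$zero_tol),
    sprintf("stride=%d", cfg$stride),
    sprintf("seed=%d", cfg$seed),
    sprintf("mask_disconnecting=%s", cfg$mask_disconnecting),
    sprintf("partial_as_active=%s", cfg$partial_as_active),
    sprintf("receptors=%s", paste(names(result$profiles), collapse = ",")))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
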