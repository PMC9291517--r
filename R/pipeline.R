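# One-command orchestration: generate -> preprocess -> correspond ->
# shape space -> classify -> group statistics, from a single config.

#' Pipeline configuration
#'
#' Aggregates every stage's parameters. Round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort an [cohort_spec()].
#' @param spacing preprocessing target spacing (mm).
#' @param particles particle count M.
#' @param optimizer an [optimizer_config()].
#' @param use_ground_truth_correspondence if `TRUE` (default), bypass the
#'   optimizer and use the generator's exact ground-truth correspondence;
#'   set `FALSE` to run the full optimization path.
#' @param rotate_align enable principal-axis rotation during alignment.
#' @param pca_fraction variance fraction reported for mode counting.
#' @param train_fraction,smote_k,lasso_repeats,subset_fraction,top_modes
#'   classification stage parameters.
#' @param alpha_level significance level for the Hotelling/FDR maps.
#' @param seed master seed; all stage sub-seeds derive from it.
#' @return an `rv_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            spacing = 1.5,
                            particles = 512,
                            optimizer = optimizer_config(M = particles),
                            use_ground_truth_correspondence = TRUE,
                            rotate_align = FALSE,
                            pca_fraction = 0.99,
                            train_fraction = 0.8,
                            smote_k = 5,
                            lasso_repeats = 1000,
                            subset_fraction = 0.8,
                            top_modes = 4,
                            alpha_level = 0.05,
                            seed = 1L) {
  stopifnot(inherits(cohort, "rv_cohort_spec"), inherits(optimizer, "rv_opt_config"))
  if (pca_fraction <= 0 || pca_fraction > 1) abort("pca_fraction must lie in (0, 1]")
  if (alpha_level <= 0 || alpha_level >= 1) abort("alpha_level must lie in (0, 1)")
  if (particles < 1) abort("particles must be >= 1")
  structure(list(cohort = cohort, spacing = spacing, particles = as.integer(particles),
                 optimizer = optimizer,
                 use_ground_truth_correspondence = isTRUE(use_ground_truth_correspondence),
                 rotate_align = isTRUE(rotate_align),
                 pca_fraction = pca_fraction, train_fraction = train_fraction,
                 smote_k = smote_k, lasso_repeats = lasso_repeats,
                 subset_fraction = subset_fraction, top_modes = top_modes,
                 alpha_level = alpha_level, seed = as.integer(seed)),
            class = "rv_pipeline_config")
}

#' @rdname pipeline_config
#' @param config an `rv_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$cohort <- lapply(unclass(config$cohort), function(x) as.list(x))
  plain$cohort$subgroup_fractions <- lapply(config$cohort$subgroup_fractions, as.list)
  plain$optimizer <- unclass(config$optimizer)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- y$cohort
  scal <- function(x) if (is.null(x) || length(x) == 0) NULL else unlist(x)
  cohort <- cohort_spec(group_sizes = unlist(ch$group_sizes),
                        subgroup_fractions = lapply(ch$subgroup_fractions, unlist),
                        deformation = do.call(deformation_params, ch$deformation),
                        noise_sd = scal(ch$noise_sd), rot_sd_deg = scal(ch$rot_sd_deg),
                        voxel_spacing = scal(ch$voxel_spacing),
                        grid_dims = scal(ch$grid_dims), resolution = scal(ch$resolution),
                        seed = scal(ch$seed))
  opt <- do.call(optimizer_config, y$optimizer)
  pipeline_config(cohort = cohort, spacing = y$spacing, particles = y$particles,
                  optimizer = opt,
                  use_ground_truth_correspondence = y$use_ground_truth_correspondence,
                  rotate_align = y$rotate_align, pca_fraction = y$pca_fraction,
                  train_fraction = y$train_fraction, smote_k = y$smote_k,
                  lasso_repeats = y$lasso_repeats, subset_fraction = y$subset_fraction,
                  top_modes = y$top_modes, alpha_level = y$alpha_level, seed = y$seed)
}

log_stage <- function(run_log, stage, ...) {
  msg <- sprintf(...)
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  c(run_log, line)
}

#' Run the full shape-analysis pipeline
#'
#' Executes all stages in order and writes every artifact (masks, particles,
#' loadings, dominance table, classification report, LDV scores, significance
#' maps) under `outdir`, together with the resolved config, its hash, and a
#' run manifest. A second run with the same config reproduces all numeric
#' outputs. Any stage error aborts after writing a `FAILED` marker naming the
#' stage.
#'
#' @param config an [pipeline_config()].
#' @param outdir output directory (created).
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `particles`, `pca`, `classification`, `ldv`, `significance`) and the
#'   manifest of written files.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  cfg_hash <- rlang::hash(config)
  run_log <- character(0)
  files <- character(0)
  stage <- "init"
  on_fail <- function(e) {
    writeLines(c(sprintf("stage: %s", stage), conditionMessage(e)),
               file.path(outdir, "FAILED"))
    abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
  }
  tryCatch({
    stage <- "synthetic_cohort"
    need_masks <- !config$use_ground_truth_correspondence
    cohort <- generate_cohort(config$cohort, voxelize_masks = need_masks)
    run_log <- log_stage(run_log, stage, "%d subjects, seed %d (hash %s)",
                         nrow(cohort$manifest), config$cohort$seed, cfg_hash)
    utils::write.csv(cohort$manifest, file.path(outdir, "cohort_manifest.csv"),
                     row.names = FALSE)
    files <- c(files, "cohort_manifest.csv")

    if (need_masks) {
      stage <- "volume_preprocess"
      dts <- preprocess_masks(cohort$masks, spacing = config$spacing,
                              rotate = config$rotate_align)
      run_log <- log_stage(run_log, stage, "%d masks -> distance transforms at %.2f mm",
                           length(dts), config$spacing)
      stage <- "particle_correspondence"
      ps <- optimize_particles(dts, config$optimizer,
                               subject_ids = cohort$manifest$subject_id)
      run_log <- log_stage(run_log, stage, "optimized %d particles x %d subjects",
                           ps$M, length(ps$subject_ids))
    } else {
      stage <- "particle_correspondence"
      ps <- attach_ground_truth(cohort, M = config$particles)
      run_log <- log_stage(run_log, stage, "ground-truth correspondence, %d particles", ps$M)
    }
    write_particles(ps, file.path(outdir, "particles"))
    files <- c(files, "particles/")

    stage <- "shape_space"
    sm <- shape_matrix(ps, cohort$manifest)
    pca <- fit_pca(sm)
    n99 <- num_modes_for_variance(pca, config$pca_fraction)
    run_log <- log_stage(run_log, stage, "%d modes explain %.0f%% variance",
                         n99, 100 * config$pca_fraction)
    loadings <- pca_loadings(pca, n_modes = n99)
    utils::write.csv(loadings, file.path(outdir, "loadings.csv"), row.names = FALSE)
    utils::write.csv(tidy(pca), file.path(outdir, "eigenvalues.csv"), row.names = FALSE)
    export_mode_shapes(pca, file.path(outdir, "mode_shapes"), n_modes = config$top_modes)
    files <- c(files, "loadings.csv", "eigenvalues.csv", "mode_shapes/")

    stage <- "tr_classifier"
    cls <- classify_pipeline(loadings, train_fraction = config$train_fraction,
                             smote_k = config$smote_k,
                             n_repeats = config$lasso_repeats,
                             subset_fraction = config$subset_fraction,
                             top_modes = config$top_modes,
                             seed = derive_seed(config$seed, 101))
    run_log <- log_stage(run_log, stage,
                         "modes {%s}; acc %.2f prec %.2f rec %.2f f1 %.2f auc %.2f",
                         paste(cls$modes, collapse = ","),
                         cls$report$metrics$accuracy, cls$report$metrics$precision,
                         cls$report$metrics$recall, cls$report$metrics$f1,
                         cls$report$auc)
    report <- c(list(config_hash = cfg_hash, selected_modes = cls$modes,
                     n_modes_99 = n99),
                lapply(glance(cls$report), identity),
                list(dominance = tibble::as_tibble(cls$dominance),
                     roc = cls$report$roc))
    jsonlite::write_json(report, file.path(outdir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    utils::write.csv(cls$report$roc, file.path(outdir, "roc.csv"), row.names = FALSE)
    files <- c(files, "classification_report.json", "roc.csv")

    stage <- "group_statistics"
    contrasts <- list(c("healthy", "control"), c("control", "tr"), c("healthy", "tr"))
    for (ct in contrasts) {
      if (all(ct %in% cohort$manifest$group) &&
          all(table(cohort$manifest$group)[ct] >= 2)) {
        sig <- hotelling_map(ps, cohort$manifest, ct[1], ct[2],
                             alpha = config$alpha_level)
        arrows <- mean_difference_arrows(sm, ct[1], ct[2])
        f <- sprintf("significance_%s_vs_%s.csv", ct[1], ct[2])
        write_significance_csv(sig, arrows, file.path(outdir, f))
        files <- c(files, f)
        run_log <- log_stage(run_log, stage, "%s vs %s: %d/%d significant points",
                             ct[1], ct[2], sum(sig$significant), nrow(sig))
      }
    }
    ldv <- NULL
    sub_tabs <- table(cohort$manifest$group, cohort$manifest$subgroup)
    for (sg in c("phtn", "chf")) {
      ok <- all(c("tr", "control") %in% cohort$manifest$group) &&
        "phtn" %in% colnames(sub_tabs) && sg %in% colnames(sub_tabs) &&
        sub_tabs["tr", sg] >= 2 && sub_tabs["control", sg] >= 2
      if (ok) {
        keep <- cohort$manifest$subgroup == sg
        sub_ps <- new_particle_system(ps$points[keep, , , drop = FALSE],
                                      cohort$manifest$subject_id[keep])
        sub_sm <- shape_matrix(sub_ps, cohort$manifest[keep, ])
        ldv <- ldv_scores(sub_sm, "tr", "control")
        f <- sprintf("ldv_scores_%s.csv", sg)
        utils::write.csv(ldv$scores, file.path(outdir, f), row.names = FALSE)
        files <- c(files, f)
        run_log <- log_stage(run_log, stage, "LDV (%s): overlap fraction %.2f",
                             sg, overlap_fraction(ldv))
      }
    }
    stage <- "finalize"
    manifest <- tibble::tibble(file = files, config_hash = cfg_hash)
    utils::write.csv(manifest, file.path(outdir, "run_manifest.csv"), row.names = FALSE)
    writeLines(run_log, file.path(outdir, "run.log"))
    invisible(list(cohort = cohort, particles = ps, pca = pca,
                   classification = cls, ldv = ldv, manifest = manifest,
                   config_hash = cfg_hash))
  }, error = on_fail)
}
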