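#' Run the screen arc: simulate -> normalize -> batch-correct -> rank
#'
#' Reproduces the drug-screen analysis end-to-end on synthetic data with
#' known spiked hits: negative-binomial plate screen, stable-gene
#' normalization, log2 transform, PCA batch diagnostic, empirical-Bayes
#' location/scale correction keyed on plate, and combined-score compound
#' ranking against same-plate DMSO controls.
#'
#' @param config list (or YAML path) with optional blocks `screen`
#'   (arguments of [screen_sim_config()]), `signature` (name, genes,
#'   direction), `top_k`, and `seed` (overrides the screen seed).
#' @param out_dir optional directory; when given, writes ranking.csv,
#'   wells.csv, diagnostics.json and a manifest with content hashes.
#' @return List: `ranking` (with `true_hit` flag), `truth`, `diagnostics`
#'   (pre/post batch R2, hit recovery), `manifest`.
#' @export
run_screen_arc <- function(config = list(), out_dir = NULL) {
  config <- load_config(config)
  sc_args <- config$screen %||% list()
  if (!is.null(config$seed)) sc_args$seed <- config$seed
  cfg <- do.call(screen_sim_config, sc_args)
  sig <- if (is.null(config$signature)) {
    gene_signature("chemokine", c("CXCL1", "CXCL2"), "down")
  } else {
    gene_signature(config$signature$name %||% "custom",
                   config$signature$genes,
                   config$signature$direction %||% "down")
  }
  top_k <- config$top_k %||% 10L

  sim <- gen_screen(cfg)
  norm <- normalize_stable(sim$screen$counts, sim$screen$panel)
  logv <- log2p1(norm$values)
  plates <- sim$screen$wells$plate_id
  if (cfg$n_plates > 1L) {
    diag_pre <- pca_batch_diag(logv, plates, k = 3L, log_transform = FALSE)
    model <- combat_fit(logv, plates)
    corrected <- combat_adjust(logv, plates, model)
    diag_post <- pca_batch_diag(corrected, plates, k = 3L,
                                log_transform = FALSE)
  } else {
    # single plate: nothing to diagnose or correct
    model <- NULL
    corrected <- logv
    diag_pre <- diag_post <- list(batch_assoc_r2 = NA_real_)
  }
  ranking <- rank_compounds(corrected, sim$screen$wells, sim$screen$panel,
                            sig, top_k = top_k)
  ranking$true_hit <- ranking$compound_id %in% sim$truth$hit_ids

  diagnostics <- list(
    pc1_batch_r2_pre = unname(diag_pre$batch_assoc_r2[1]),
    pc1_batch_r2_post = unname(diag_post$batch_assoc_r2[1]),
    hits_in_top_k = sum(ranking$true_hit[seq_len(top_k)]),
    n_true_hits = length(sim$truth$hit_ids)
  )
  manifest <- list(seed = cfg$seed, params = unclass(cfg),
                   signature = unclass(sig), top_k = top_k)
  if (!is.null(out_dir)) {
    manifest$files <- write_outputs(out_dir, list(
      ranking.csv = ranking,
      wells.csv = sim$screen$wells,
      diagnostics.json = diagnostics
    ))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ranking = ranking, truth = sim$truth, diagnostics = diagnostics,
       manifest = manifest)
}

#' Run the cell arc: simulate -> QC -> classify -> score -> associate
#'
#' Generates a reference and a held-out query cohort, trains the projection
#' classifier on the reference, predicts MDSCs in the query, scores the
#' chemokine signature, stratifies patients, and computes the association
#' battery: composition chi-square, Mann-Whitney MDSC-fraction comparison,
#' Spearman correlation of per-patient tumor chemokine expression with the
#' predicted MDSC share of myeloid cells, ROC of the score against
#' simulated response, and a KM/log-rank survival comparison.
#'
#' @param config list (or YAML path) with optional blocks `scrna`
#'   (arguments of [sc_sim_config()]), `survival`, `response`, and `seed`.
#' @param out_dir optional output directory (tables + manifest).
#' @return List of result tables and statistics; see Details in the vignette.
#' @export
run_cell_arc <- function(config = list(), out_dir = NULL) {
  config <- load_config(config)
  seed <- config$seed %||% 1L
  sc_args <- config$scrna %||% list()
  ref_args <- sc_args; ref_args$seed <- seed + 1L
  qry_args <- sc_args; qry_args$seed <- seed + 2L
  ref <- gen_scrna(do.call(sc_sim_config, ref_args))
  qry <- gen_scrna(do.call(sc_sim_config, qry_args))

  ref_cells <- lognormalize(filter_cells(ref$cells, min_genes = 50L))
  qry_cells <- lognormalize(filter_cells(qry$cells, min_genes = 50L))

  model <- train_celltype_model(ref_cells, seed = seed)
  pred <- predict_celltype(model, project_cells(model, qry_cells))
  truth_types <- qry_cells$cell_meta$cell_type
  mdsc_truth <- truth_types == "MDSC"
  mdsc_pred <- pred$label == "MDSC"
  precision <- if (any(mdsc_pred)) mean(truth_types[mdsc_pred] == "MDSC") else NA
  recall <- mean(mdsc_pred[mdsc_truth])

  sig <- gene_signature("chemokine", c("CXCL1", "CXCL2"), "down")
  chemo <- patient_aggregate(qry_cells, sig$genes, cell_subset = "tumor")
  meta <- qry_cells$cell_meta
  myeloid <- pred$label %in% c("MDSC", "myeloid")
  mdsc_frac <- tapply(mdsc_pred[myeloid], meta$patient[myeloid], mean)
  common <- intersect(names(chemo), names(mdsc_frac))
  assoc <- correlate(chemo[common], mdsc_frac[common], "spearman")

  pat_group <- stratify(chemo[common])
  mw <- group_compare(mdsc_frac[common], pat_group)
  cell_group <- pat_group[match(meta$patient, names(pat_group))]
  keep <- !is.na(cell_group)
  comp <- composition_test(cell_group[keep], pred$label[keep])

  resp <- do.call(gen_response, c(config$response %||% list(),
                                  list(seed = seed + 3L)))
  roc <- roc_auc(resp$score, 1L - resp$response)  # high score -> non-response
  surv <- do.call(gen_survival, c(config$survival %||%
                                    list(hazard_ratio = 2),
                                  list(seed = seed + 4L)))
  lr <- logrank_test(surv)
  km <- km_estimate(surv)

  out <- list(
    mdsc_precision = precision, mdsc_recall = recall,
    chemokine_by_patient = chemo, mdsc_fraction = mdsc_frac,
    association = assoc, mannwhitney = mw, composition = comp,
    roc = roc, logrank = lr, km = km,
    prediction = data.frame(cell_id = meta$cell_id, patient = meta$patient,
                            true_type = truth_types, predicted = pred$label,
                            stringsAsFactors = FALSE)
  )
  if (!is.null(out_dir)) {
    manifest <- list(seed = seed,
                     stats = list(mdsc_precision = precision,
                                  mdsc_recall = recall,
                                  spearman_rho = assoc$estimate,
                                  auc = roc$auc, logrank_p = lr$p))
    manifest$files <- write_outputs(out_dir, list(
      predictions.csv = out$prediction,
      patient_table.csv = data.frame(patient = common,
                                     chemokine = chemo[common],
                                     mdsc_fraction = mdsc_frac[common],
                                     group = pat_group[common])
    ))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Accept a list or a YAML file path.
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

# Write tables/JSON into out_dir, return name -> md5 map.
write_outputs <- function(out_dir, objects) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(objects)) {
    path <- file.path(out_dir, nm)
    if (grepl("\\.json$", nm)) {
      jsonlite::write_json(objects[[nm]], path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(objects[[nm]], path, row.names = FALSE)
    }
    paths[nm] <- path
  }
  hashes <- tools::md5sum(paths)
  stats::setNames(as.list(hashes), names(objects))
}
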