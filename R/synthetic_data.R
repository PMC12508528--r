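#' Configuration for the synthetic plate screen
#'
#' Describes a pooled probe-capture drug screen laid out on multi-well plates:
#' each plate carries its own DMSO control wells, compounds are seeded in
#' replicate wells, and a known subset of "hit" compounds down-regulates the
#' signature genes (CXCL1/CXCL2 by default) by `hit_log2fc` log2 units.
#' Counts are negative binomial; each plate adds a location shift on the log2
#' mean (`batch_shift_sd`) and a multiplicative dispersion scale
#' (`batch_scale_sd`), the two components a location/scale batch correction
#' can remove.
#'
#' @param n_compounds number of library compounds.
#' @param n_hits number of true hit compounds (must be `<= n_compounds`).
#' @param hit_log2fc log2 fold change applied to signature-probe means of hit
#'   wells; negative means down-regulation.
#' @param replicates_per_compound treated wells per compound. The screen this
#'   emulates does not document its replicate count; 3 is the package default
#'   and is configurable.
#' @param wells_per_plate,n_dmso_per_plate plate geometry; at least 2 DMSO
#'   wells per plate are required (fold changes are undefined otherwise).
#' @param n_probes,n_stable probe panel size and how many probes are flagged
#'   stable (housekeeping-like size-factor anchors).
#' @param batch_shift_sd SD of the per-plate additive shift on log2 means.
#' @param batch_scale_sd SD (log scale) of the per-plate dispersion multiplier.
#' @param nb_dispersion negative-binomial dispersion (1/size); > 0.
#' @param baseline_mean typical per-probe baseline count.
#' @param n_plates number of plates; computed from the library size when `NULL`.
#' @param seed integer RNG seed.
#' @return An object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_compounds = 200L, n_hits = 5L,
                              hit_log2fc = -1.5, replicates_per_compound = 3L,
                              wells_per_plate = 384L, n_dmso_per_plate = 16L,
                              n_probes = 40L, n_stable = 33L,
                              batch_shift_sd = 0.5, batch_scale_sd = 0.2,
                              nb_dispersion = 0.1, baseline_mean = 500,
                              n_plates = NULL, seed = 1L) {
  stop_if_not_count(n_compounds, "n_compounds")
  stop_if_not_count(n_hits, "n_hits", min = 0L)
  stop_if_not_count(replicates_per_compound, "replicates_per_compound")
  stop_if_not_count(wells_per_plate, "wells_per_plate", min = 3L)
  stop_if_not_count(n_probes, "n_probes", min = 3L)
  stop_if_not_count(n_stable, "n_stable")
  if (n_dmso_per_plate < 2L) {
    stop("n_dmso_per_plate must be >= 2: per-plate fold changes are undefined ",
         "with fewer than 2 DMSO control wells", call. = FALSE)
  }
  if (n_hits > n_compounds) stop("n_hits must be <= n_compounds", call. = FALSE)
  if (n_stable > n_probes - 2L) {
    stop("n_probes must exceed n_stable + 2 (signature probes)", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (n_dmso_per_plate >= wells_per_plate) {
    stop("n_dmso_per_plate must leave room for treated wells", call. = FALSE)
  }
  treated_per_plate <- wells_per_plate - n_dmso_per_plate
  need_plates <- ceiling(n_compounds * replicates_per_compound /
                           treated_per_plate)
  if (is.null(n_plates)) n_plates <- need_plates
  if (n_plates < need_plates) {
    stop(sprintf("n_plates = %d cannot hold %d treated wells", n_plates,
                 n_compounds * replicates_per_compound), call. = FALSE)
  }
  structure(list(
    n_plates = as.integer(n_plates), wells_per_plate = as.integer(wells_per_plate),
    n_dmso_per_plate = as.integer(n_dmso_per_plate),
    n_compounds = as.integer(n_compounds), n_hits = as.integer(n_hits),
    hit_log2fc = hit_log2fc, n_probes = as.integer(n_probes),
    n_stable = as.integer(n_stable), batch_shift_sd = batch_shift_sd,
    batch_scale_sd = batch_scale_sd, nb_dispersion = nb_dispersion,
    baseline_mean = baseline_mean,
    replicates_per_compound = as.integer(replicates_per_compound),
    seed = as.integer(seed)
  ), class = "screen_sim_config")
}

# Random fixed-length ACGT sequences; used for the synthetic probe panel.
random_probe_seqs <- function(n, len = 30L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Build a synthetic probe panel
#'
#' Probes are random 30-mers. The first two non-stable probes capture the
#' signature genes CXCL1 and CXCL2; `n_stable` probes are flagged as stable
#' normalization anchors; the remainder are filler genes.
#'
#' @param n_probes,n_stable panel size and stable count.
#' @param probe_len probe length in nucleotides.
#' @param seed RNG seed.
#' @return A `data.frame` with columns `probe_id`, `sequence`, `gene`,
#'   `is_stable` (the probe-panel contract used throughout the package).
#' @export
make_probe_panel <- function(n_probes = 40L, n_stable = 33L, probe_len = 30L,
                             seed = 1L) {
  stop_if_not_count(n_probes, "n_probes", min = 3L)
  with_seed(seed, {
    genes <- c("CXCL1", "CXCL2",
               sprintf("STB%02d", seq_len(n_stable)),
               if (n_probes > n_stable + 2L)
                 sprintf("FIL%02d", seq_len(n_probes - n_stable - 2L)))
    data.frame(
      probe_id = sprintf("probe_%03d", seq_len(n_probes)),
      sequence = random_probe_seqs(n_probes, probe_len),
      gene = genes,
      is_stable = genes %in% sprintf("STB%02d", seq_len(n_stable)),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a plate-based signature screen
#'
#' Generates a well-by-probe negative-binomial count table with per-plate
#' batch effects, per-plate DMSO control wells, and a spiked set of hit
#' compounds whose signature-probe means are multiplied by `2^hit_log2fc`.
#' Stable probes are never affected by compound treatment.
#'
#' @param cfg a [screen_sim_config()].
#' @return A list with elements
#'   * `screen`: list with `counts` (well x probe matrix), `wells`
#'     (well_id, plate_id, compound_id, is_dmso) and `panel`;
#'   * `truth`: list with `hit_ids`, the per-plate log2 shifts and dispersion
#'     scales actually drawn.
#' @export
gen_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  with_seed(cfg$seed, {
    panel <- make_probe_panel(cfg$n_probes, cfg$n_stable,
                              seed = sample.int(1e6, 1))
    sig_probes <- panel$gene %in% c("CXCL1", "CXCL2")

    compound_ids <- sprintf("C%04d", seq_len(cfg$n_compounds))
    hit_ids <- if (cfg$n_hits > 0) sample(compound_ids, cfg$n_hits) else character()

    treated_per_plate <- cfg$wells_per_plate - cfg$n_dmso_per_plate
    treat_wells <- rep(compound_ids, each = cfg$replicates_per_compound)
    # Scatter replicates across plates so plate and compound are not confounded.
    treat_wells <- sample(treat_wells)

    wells <- do.call(rbind, lapply(seq_len(cfg$n_plates), function(p) {
      lo <- (p - 1L) * treated_per_plate + 1L
      hi <- min(p * treated_per_plate, length(treat_wells))
      cmpd <- if (lo <= length(treat_wells)) treat_wells[lo:hi] else character()
      n_w <- length(cmpd) + cfg$n_dmso_per_plate
      data.frame(
        well_id = sprintf("P%02d_W%03d", p, seq_len(n_w)),
        plate_id = sprintf("P%02d", p),
        compound_id = c(rep("DMSO", cfg$n_dmso_per_plate), cmpd),
        is_dmso = c(rep(TRUE, cfg$n_dmso_per_plate), rep(FALSE, length(cmpd))),
        stringsAsFactors = FALSE
      )
    }))

    baseline <- cfg$baseline_mean * rlnorm(cfg$n_probes, 0, 0.5)
    # plate batch effect: probe-specific additive shift on the log2 mean
    # (what a per-batch per-probe location correction removes), plus a
    # plate-wide dispersion multiplier (the scale component)
    plate_shift <- matrix(rnorm(cfg$n_plates * cfg$n_probes, 0,
                                cfg$batch_shift_sd),
                          nrow = cfg$n_plates,
                          dimnames = list(sprintf("P%02d", seq_len(cfg$n_plates)),
                                          panel$probe_id))
    plate_scale <- exp(rnorm(cfg$n_plates, 0, cfg$batch_scale_sd)) # dispersion x
    names(plate_scale) <- rownames(plate_shift)

    n_w <- nrow(wells)
    mu <- matrix(rep(baseline, each = n_w), nrow = n_w)
    mu <- mu * 2^plate_shift[wells$plate_id, , drop = FALSE]
    is_hit_well <- wells$compound_id %in% hit_ids
    if (any(is_hit_well) && any(sig_probes)) {
      mu[is_hit_well, sig_probes] <- mu[is_hit_well, sig_probes] * 2^cfg$hit_log2fc
    }
    disp <- cfg$nb_dispersion * plate_scale[wells$plate_id]
    counts <- matrix(
      rnbinom(n_w * cfg$n_probes, mu = as.vector(mu),
              size = rep(1 / disp, cfg$n_probes)),
      nrow = n_w,
      dimnames = list(wells$well_id, panel$probe_id)
    )

    list(
      screen = list(counts = counts, wells = wells, panel = panel),
      truth = list(hit_ids = sort(hit_ids), plate_shift = plate_shift,
                   plate_scale = plate_scale)
    )
  })
}

#' Emit synthetic reads realizing a well-by-probe count table
#'
#' For every well/probe cell, emits exactly the tabulated number of reads,
#' each a copy of the probe sequence with independent per-base substitution
#' probability `mismatch_rate`. Read names encode the well id
#' (`<well>:<serial>`), so demultiplexed re-counting can be checked against
#' the source table.
#'
#' @param panel probe panel data.frame (`probe_id`, `sequence`).
#' @param counts well x probe count matrix (columns named by probe_id).
#' @param mismatch_rate per-base substitution probability in `[0, 0.25)`.
#' @param seed RNG seed.
#' @return Named list (one element per well) of named character vectors of
#'   read sequences; names are read ids.
#' @export
gen_reads <- function(panel, counts, mismatch_rate = 0, seed = 1L) {
  if (nrow(panel) == 0L) stop("empty probe panel", call. = FALSE)
  if (mismatch_rate < 0 || mismatch_rate >= 0.25) {
    stop("mismatch_rate must be in [0, 0.25)", call. = FALSE)
  }
  stopifnot(!is.null(colnames(counts)), !is.null(rownames(counts)))
  seqs <- panel$sequence[match(colnames(counts), panel$probe_id)]
  if (anyNA(seqs)) stop("counts columns not all present in panel", call. = FALSE)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("panel sequences must share one length", call. = FALSE)
  bases <- c("A", "C", "G", "T")

  with_seed(seed, {
    out <- lapply(rownames(counts), function(w) {
      n_per_probe <- counts[w, ]
      total <- sum(n_per_probe)
      if (total == 0) return(stats::setNames(character(), character()))
      reads <- rep(seqs, times = n_per_probe)
      if (mismatch_rate > 0) {
        mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                      nrow = total, byrow = TRUE)
        hit <- matrix(stats::runif(total * len) < mismatch_rate, nrow = total)
        if (any(hit)) {
          idx <- which(hit)
          cur <- mat[idx]
          # substitute with one of the three other bases, uniformly
          sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1), character(1))
          mat[idx] <- sub
        }
        reads <- apply(mat, 1, paste, collapse = "")
      }
      stats::setNames(reads, sprintf("%s:%06d", w, seq_len(total)))
    })
    stats::setNames(out, rownames(counts))
  })
}

#' Write per-well reads as FASTQ
#'
#' @param reads output of [gen_reads()].
#' @param dir output directory; one `<well>.fastq` per well.
#' @return Invisibly, the written file paths.
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reads), function(w) {
    path <- file.path(dir, paste0(w, ".fastq"))
    r <- reads[[w]]
    if (length(r) == 0) {
      file.create(path)
      return(path)
    }
    x <- Biostrings::DNAStringSet(r)
    names(x) <- names(r)
    qual <- Biostrings::PhredQuality(
      vapply(width(x), function(wd) strrep("I", wd), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
    path
  }, character(1))
  invisible(paths)
}

#' Configuration for the synthetic single-cell cohort
#'
#' Emulates a multi-patient tumor scRNA-seq cohort with four cell types
#' (tumor, T cell, MDSC, other myeloid). Each patient carries a latent
#' chemokine activity that multiplies tumor-cell CXCL1/CXCL2 means, and the
#' patient's MDSC share of the myeloid compartment is
#' `plogis(intercept + mdsc_link_slope * activity)` - the positive coupling
#' between tumor chemokine expression and MDSC infiltration that the package
#' is designed to recover.
#'
#' @param n_patients,cells_per_patient cohort size.
#' @param n_genes number of genes (>= 60).
#' @param mdsc_link_slope logit-scale slope linking latent chemokine activity
#'   to the MDSC fraction; 0 means no coupling.
#' @param mdsc_intercept logit of the baseline MDSC share of myeloid cells.
#' @param program_log2fc marker up-regulation (log2) defining each cell-type
#'   program; separation >= 2 gives cleanly classifiable types.
#' @param markers_per_type marker genes per cell-type program.
#' @param nb_dispersion NB dispersion of counts.
#' @param response_slope logit-scale slope linking activity to the probability
#'   of being a non-expander (NEs) under checkpoint blockade.
#' @param cell_type_programs optional gene x type matrix of mean profiles;
#'   built internally when `NULL`.
#' @param seed RNG seed.
#' @return An object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_patients = 30L, cells_per_patient = 100L,
                          n_genes = 1000L, mdsc_link_slope = 2,
                          mdsc_intercept = qlogis(0.25),
                          program_log2fc = 3, markers_per_type = 50L,
                          nb_dispersion = 0.3, response_slope = 1.5,
                          cell_type_programs = NULL, seed = 1L) {
  stop_if_not_count(n_patients, "n_patients", min = 2L)
  stop_if_not_count(cells_per_patient, "cells_per_patient", min = 10L)
  stop_if_not_count(n_genes, "n_genes", min = 60L)
  if (!is.null(cell_type_programs)) {
    if (any(cell_type_programs < 0)) stop("profiles must be non-negative", call. = FALSE)
    if (all(cell_type_programs == 0)) stop("degenerate all-zero profile", call. = FALSE)
    need <- c("tumor", "Tcell", "MDSC", "myeloid")
    if (!all(need %in% colnames(cell_type_programs))) {
      stop("cell_type_programs must include tumor, Tcell, MDSC, myeloid",
           call. = FALSE)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    cells_per_patient = as.integer(cells_per_patient),
    n_genes = as.integer(n_genes), mdsc_link_slope = mdsc_link_slope,
    mdsc_intercept = mdsc_intercept, program_log2fc = program_log2fc,
    markers_per_type = as.integer(markers_per_type),
    nb_dispersion = nb_dispersion, response_slope = response_slope,
    cell_type_programs = cell_type_programs, seed = as.integer(seed)
  ), class = "sc_sim_config")
}

# Gene universe: CXCL1/2, 13 mitochondrial genes (MT- prefix), type markers,
# filler. Returns list(genes, programs, marker_sets).
default_cell_programs <- function(cfg) {
  types <- c("tumor", "Tcell", "MDSC", "myeloid")
  mito <- sprintf("MT-G%02d", 1:13)
  n_mark <- cfg$markers_per_type
  marker_sets <- stats::setNames(lapply(seq_along(types), function(i) {
    sprintf("%s_MK%03d", toupper(types[i]), seq_len(n_mark))
  }), types)
  n_named <- 2L + length(mito) + n_mark * length(types)
  if (cfg$n_genes < n_named + 10L) {
    stop("n_genes too small for the default programs", call. = FALSE)
  }
  genes <- c("CXCL1", "CXCL2", mito, unlist(marker_sets),
             sprintf("FILLER%04d", seq_len(cfg$n_genes - n_named)))
  base <- rlnorm(length(genes), meanlog = log(0.3), sdlog = 1)
  names(base) <- genes
  base[mito] <- base[mito] * 2          # mito genes a bit hot, as in real cells
  programs <- matrix(rep(base, length(types)), ncol = length(types),
                     dimnames = list(genes, types))
  for (ty in types) {
    programs[marker_sets[[ty]], ty] <- programs[marker_sets[[ty]], ty] *
      2^cfg$program_log2fc
  }
  # CXCL1/2 are tumor-cell chemokines: expressed in tumor, near-silent elsewhere
  programs[c("CXCL1", "CXCL2"), ] <- 0.02
  programs[c("CXCL1", "CXCL2"), "tumor"] <- 2
  list(genes = genes, programs = programs, marker_sets = marker_sets)
}

#' Simulate a multi-patient single-cell cohort with MDSC coupling
#'
#' @param cfg an [sc_sim_config()].
#' @return A list with
#'   * `cells`: a [cell_data()] object (counts, cell/gene metadata; per-cell
#'     metadata carries `patient`, true `cell_type`, `response` (Es/NEs) and
#'     `subtype`);
#'   * `truth`: `true_cell_types`, per-patient `true_mdsc_fraction` (share of
#'     myeloid cells), `activity` (latent chemokine activity),
#'     `true_response_prob` (P(NEs)).
#' @export
gen_scrna <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(cfg$seed, {
    prog <- if (is.null(cfg$cell_type_programs)) {
      default_cell_programs(cfg)
    } else {
      list(genes = rownames(cfg$cell_type_programs),
           programs = cfg$cell_type_programs, marker_sets = NULL)
    }
    genes <- prog$genes
    types <- colnames(prog$programs)

    activity <- rnorm(cfg$n_patients)                 # latent chemokine activity
    mdsc_frac <- plogis(cfg$mdsc_intercept + cfg$mdsc_link_slope * activity)
    p_nes <- plogis(cfg$response_slope * activity)    # high chemokine -> NEs
    patients <- sprintf("PT%02d", seq_len(cfg$n_patients))
    response <- ifelse(stats::runif(cfg$n_patients) < p_nes, "NEs", "Es")
    subtype <- sample(c("TNBC", "HER2+", "ER+"), cfg$n_patients, replace = TRUE)

    per_patient <- lapply(seq_len(cfg$n_patients), function(i) {
      # fixed tumor/T share; myeloid compartment split by the MDSC fraction
      p_type <- c(tumor = 0.4, Tcell = 0.2,
                  MDSC = 0.4 * mdsc_frac[i], myeloid = 0.4 * (1 - mdsc_frac[i]))
      ty <- sample(types, cfg$cells_per_patient, replace = TRUE,
                   prob = p_type[types])
      mu <- prog$programs[, ty, drop = FALSE]
      tum <- ty == "tumor"
      if (any(tum)) {
        mu[c("CXCL1", "CXCL2"), tum] <- mu[c("CXCL1", "CXCL2"), tum] *
          2^activity[i]
      }
      libsize <- rlnorm(cfg$cells_per_patient, 0, 0.3)
      mu <- sweep(mu, 2, libsize, "*")
      cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                            size = 1 / cfg$nb_dispersion),
                    nrow = length(genes))
      list(counts = cnt, type = ty)
    })

    counts <- do.call(cbind, lapply(per_patient, `[[`, "counts"))
    type <- unlist(lapply(per_patient, `[[`, "type"))
    cell_pat <- rep(patients, each = cfg$cells_per_patient)
    colnames(counts) <- sprintf("%s_c%04d", cell_pat,
                                unlist(lapply(per_patient,
                                              function(x) seq_along(x$type))))
    rownames(counts) <- genes

    cells <- cell_data(
      counts = counts,
      cell_meta = data.frame(
        cell_id = colnames(counts), patient = cell_pat, cell_type = type,
        response = response[match(cell_pat, patients)],
        subtype = subtype[match(cell_pat, patients)],
        stringsAsFactors = FALSE
      )
    )
    truth <- list(
      true_cell_types = stats::setNames(type, colnames(counts)),
      true_mdsc_fraction = stats::setNames(mdsc_frac, patients),
      activity = stats::setNames(activity, patients),
      true_response_prob = stats::setNames(p_nes, patients)
    )
    list(cells = cells, truth = truth)
  })
}

#' Simulate a two-group survival cohort
#'
#' Event times are exponential; the "high" group's hazard is
#' `hazard_ratio` times baseline. Censoring is independent exponential with
#' rate chosen so that roughly `censor_rate` of baseline subjects are
#' censored. A continuous biomarker `score` separates the groups
#' (Normal around +1 for high, -1 for low) so cutoff-scanning code can be
#' exercised against known structure.
#'
#' @param n total subjects (split evenly; `n >= 4`).
#' @param hazard_ratio hazard multiplier for the high group (> 0).
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param baseline_hazard events per time unit in the low group.
#' @param seed RNG seed.
#' @return A `data.frame`: subject_id, time, event (1 event / 0 censored),
#'   score, group.
#' @export
gen_survival <- function(n = 200L, hazard_ratio = 1, censor_rate = 0.2,
                         baseline_hazard = 0.1, seed = 1L) {
  stop_if_not_count(n, "n", min = 4L)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    n_high <- n %/% 2L
    group <- c(rep("high", n_high), rep("low", n - n_high))
    rate <- ifelse(group == "high", baseline_hazard * hazard_ratio,
                   baseline_hazard)
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
      t_cens <- rexp(n, c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      score = rnorm(n, ifelse(group == "high", 1, -1), 0.25),
      group = group,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate signature scores with a linked binary treatment response
#'
#' Response probability is `plogis(-slope * score)`: patients with a high
#' signature score are less likely to respond, the direction a chemokine/MDSC
#' signature shows under checkpoint blockade.
#'
#' @param n_patients number of patients (>= 10).
#' @param slope logistic slope linking score to non-response; 0 gives AUC 0.5.
#' @param seed RNG seed.
#' @return A `data.frame`: patient_id, score, response (1 responder / 0 not),
#'   true_prob (P(response)).
#' @export
gen_response <- function(n_patients = 200L, slope = 1, seed = 1L) {
  stop_if_not_count(n_patients, "n_patients", min = 10L)
  with_seed(seed, {
    score <- rnorm(n_patients)
    p <- plogis(-slope * score)
    data.frame(
      patient_id = sprintf("R%04d", seq_len(n_patients)),
      score = score,
      response = as.integer(stats::runif(n_patients) < p),
      true_prob = p,
      stringsAsFactors = FALSE
    )
  })
}
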