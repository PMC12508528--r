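test_that("generators are deterministic under a fixed seed", {
  cfg <- screen_sim_config(n_compounds = 20, n_hits = 2, seed = 7)
  a <- gen_screen(cfg); b <- gen_screen(cfg)
  expect_identical(a, b)

  cfg2 <- sc_sim_config(n_patients = 4, cells_per_patient = 30,
                        n_genes = 250, seed = 3)
  expect_identical(gen_scrna(cfg2)$cells$counts, gen_scrna(cfg2)$cells$counts)

  expect_identical(gen_survival(n = 50, seed = 5), gen_survival(n = 50, seed = 5))
  expect_identical(gen_response(n_patients = 40, seed = 5),
                   gen_response(n_patients = 40, seed = 5))
})

test_that("screen config enforces its invariants", {
  expect_error(screen_sim_config(n_dmso_per_plate = 1), "fold changes")
  expect_error(screen_sim_config(n_compounds = 5, n_hits = 6), "n_hits")
  expect_error(screen_sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(screen_sim_config(n_compounds = 1000, n_plates = 1),
               "cannot hold")
})

test_that("gen_screen spikes hits on signature probes and flags DMSO wells", {
  cfg <- screen_sim_config(n_compounds = 40, n_hits = 4, hit_log2fc = -3,
                           baseline_mean = 2000, seed = 2)
  sim <- gen_screen(cfg)
  w <- sim$screen$wells
  expect_equal(sum(w$is_dmso), cfg$n_plates * cfg$n_dmso_per_plate)
  expect_length(sim$truth$hit_ids, 4)
  sig_probes <- sim$screen$panel$probe_id[
    sim$screen$panel$gene %in% c("CXCL1", "CXCL2")]
  hit_wells <- w$compound_id %in% sim$truth$hit_ids
  # signature probes strongly depressed in hit wells, stable probes untouched
  expect_lt(mean(sim$screen$counts[hit_wells, sig_probes]),
            0.4 * mean(sim$screen$counts[!hit_wells & !w$is_dmso, sig_probes]))
  stable <- sim$screen$panel$probe_id[sim$screen$panel$is_stable]
  rel <- mean(sim$screen$counts[hit_wells, stable]) /
    mean(sim$screen$counts[!hit_wells, stable])
  expect_gt(rel, 0.9); expect_lt(rel, 1.1)
})

test_that("zero hit effect leaves hit wells statistically ordinary", {
  cfg <- screen_sim_config(n_compounds = 500, n_hits = 10, hit_log2fc = 0,
                           replicates_per_compound = 3, seed = 21)
  sim <- gen_screen(cfg)
  norm <- normalize_stable(sim$screen$counts, sim$screen$panel)
  rk <- rank_compounds(log2(norm$values + 1), sim$screen$wells,
                       sim$screen$panel,
                       gene_signature("sig", c("CXCL1", "CXCL2")), top_k = 5)
  # top 1% should contain ~ 10 * 0.01 = 0.1 true "hits"; 3+ would be wild
  expect_lte(sum(rk$compound_id[1:5] %in% sim$truth$hit_ids), 2)
})

test_that("gen_reads conserves counts and encodes wells; mutation behaves", {
  panel <- make_probe_panel(n_probes = 6, n_stable = 3, seed = 4)
  counts <- matrix(rpois(12, 20), 2, 6,
                   dimnames = list(c("W1", "W2"), panel$probe_id))
  reads <- gen_reads(panel, counts, mismatch_rate = 0, seed = 9)
  expect_equal(vapply(reads, length, integer(1)),
               setNames(rowSums(counts), rownames(counts)))
  # round trip: exact re-count reproduces the table
  expect_equal(oracle_exact_count(reads, panel),
               matrix(as.integer(counts), 2, 6, dimnames = dimnames(counts)))
  expect_true(all(grepl("^W[12]:", unlist(lapply(reads, names)))))

  # at 1% per-base error on 30-mers, <= 3 mismatches covers P(X<=3) of reads
  big <- matrix(2000L, 1, 6, dimnames = list("W1", panel$probe_id))
  noisy <- gen_reads(panel, big, mismatch_rate = 0.01, seed = 10)
  res <- count_reads(noisy, panel, max_mismatches = 3)
  p_keep <- pbinom(3, 30, 0.01)
  expect_gte(sum(res$counts) / sum(big), 0.99)
  expect_gte(sum(res$counts) / sum(big), p_keep - 0.005)

  f1 <- withr::local_tempdir()
  f2 <- withr::local_tempdir()
  write_reads_fastq(gen_reads(panel, counts, 0.05, seed = 3), f1)
  write_reads_fastq(gen_reads(panel, counts, 0.05, seed = 3), f2)
  expect_identical(readLines(file.path(f1, "W1.fastq")),
                   readLines(file.path(f2, "W1.fastq")))
})

test_that("scrna coupling between chemokine activity and MDSC share works", {
  rho_at <- function(slope, seed) {
    sim <- gen_scrna(sc_sim_config(n_patients = 30, cells_per_patient = 40,
                                   n_genes = 300, mdsc_link_slope = slope,
                                   seed = seed))
    suppressWarnings(cor(sim$truth$activity, sim$truth$true_mdsc_fraction,
                         method = "spearman"))
  }
  expect_gt(rho_at(2, 11), 0.5)
  # with no coupling the fraction is constant across patients -> NA or ~0
  sim0 <- gen_scrna(sc_sim_config(n_patients = 30, cells_per_patient = 40,
                                  n_genes = 300, mdsc_link_slope = 0,
                                  seed = 12))
  expect_true(sd(sim0$truth$true_mdsc_fraction) == 0)
  # and the *realized* per-patient MDSC share is uncorrelated with activity
  realized <- tapply(sim0$truth$true_cell_types == "MDSC",
                     sim0$cells$cell_meta$patient, mean)
  rho <- suppressWarnings(
    cor(sim0$truth$activity[names(realized)], realized, method = "spearman"))
  expect_lt(abs(rho), 0.3)
})

test_that("gen_scrna rejects degenerate profiles", {
  prog <- matrix(0, 5, 4,
                 dimnames = list(letters[1:5],
                                 c("tumor", "Tcell", "MDSC", "myeloid")))
  expect_error(sc_sim_config(cell_type_programs = prog), "degenerate")
})

test_that("gen_survival encodes the requested hazard structure", {
  tab <- gen_survival(n = 2000, hazard_ratio = 3, censor_rate = 0, seed = 8)
  expect_true(all(tab$event == 1))
  m_high <- median(tab$time[tab$group == "high"])
  m_low <- median(tab$time[tab$group == "low"])
  expect_gt(m_low / m_high, 2)  # 3x hazard ~ 1/3 median survival
  cens <- gen_survival(n = 2000, hazard_ratio = 1, censor_rate = 0.3, seed = 8)
  expect_gt(mean(cens$event == 0), 0.2)
  expect_lt(mean(cens$event == 0), 0.4)
  expect_error(gen_survival(n = 3), ">= 4")
  expect_error(gen_survival(n = 10, censor_rate = 1), "censor_rate")
})

test_that("gen_response AUC is 0.5 under the null and grows with slope", {
  null <- gen_response(n_patients = 200, slope = 0, seed = 14)
  expect_lt(abs(roc_auc(null$score, 1L - null$response)$auc - 0.5), 0.1)
  steep <- gen_response(n_patients = 200, slope = 8, seed = 14)
  expect_gt(roc_auc(steep$score, 1L - steep$response)$auc, 0.9)
})
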