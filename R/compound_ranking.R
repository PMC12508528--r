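#' Define a gene signature
#'
#' @param name signature name.
#' @param genes unique gene symbols.
#' @param direction `"down"` when the screen seeks down-regulators (default),
#'   `"up"` otherwise.
#' @return A `signature` object.
#' @export
gene_signature <- function(name, genes, direction = c("down", "up")) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("signature needs >= 1 gene", call. = FALSE)
  if (anyDuplicated(genes)) stop("signature genes must be unique", call. = FALSE)
  structure(list(name = name, genes = genes, direction = direction),
            class = "gene_signature")
}

#' Read a signature from JSON
#'
#' Expects an object with fields `name`, `genes`, `direction`.
#' @param path JSON file.
#' @return A [gene_signature()].
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_signature(x$name, x$genes, x$direction %||% "down")
}

# Average probe columns belonging to one gene; returns a well-length vector.
gene_values <- function(values, panel, gene) {
  probes <- panel$probe_id[panel$gene == gene]
  probes <- intersect(probes, colnames(values))
  if (length(probes) == 0L) {
    stop(sprintf("gene '%s' has no probe in the value table", gene),
         call. = FALSE)
  }
  rowMeans(values[, probes, drop = FALSE])
}

# Pooled-variance two-sample t with a variance floor; returns c(t, p).
pooled_t <- function(x, y, var_floor = 1e-6) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  sp2 <- max(sp2, var_floor)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, p = max(p, .Machine$double.xmin))
}

#' Per-compound per-gene fold change versus same-plate DMSO
#'
#' log2 fold change = mean(treated log2 values) minus the mean of the
#' same-plate DMSO log2 values, averaged over plates when a compound's
#' replicates span plates (each treated well is compared to its own plate's
#' DMSO mean). Significance is a two-sample pooled-variance Student's t test
#' of treated versus DMSO well values. A single-replicate compound gets
#' p = 1 and t = 0 with `flagged = TRUE`.
#'
#' @param values corrected well x probe matrix on log2 scale.
#' @param wells well metadata (well_id, plate_id, compound_id, is_dmso)
#'   aligned with `values` rows.
#' @param panel probe panel (maps probes to genes).
#' @param compound compound id.
#' @param gene gene symbol.
#' @param var_floor pooled-variance floor keeping t finite.
#' @return List: log2fc, t_stat, p_value, n_treat, n_ctrl, flagged.
#' @export
fold_change <- function(values, wells, panel, compound, gene,
                        var_floor = 1e-6) {
  stopifnot(nrow(values) == nrow(wells))
  v <- gene_values(values, panel, gene)
  tr <- wells$compound_id == compound & !wells$is_dmso
  if (!any(tr)) stop(sprintf("compound '%s' has no treated well", compound),
                     call. = FALSE)
  plates <- unique(wells$plate_id[tr])
  ctrl <- wells$is_dmso & wells$plate_id %in% plates
  if (!any(ctrl)) {
    stop(sprintf("no DMSO wells on plate(s) of compound '%s'", compound),
         call. = FALSE)
  }
  dmso_mean <- tapply(v[ctrl], wells$plate_id[ctrl], mean)
  if (any(tapply(ctrl, wells$plate_id, sum)[plates] < 2L)) {
    stop(sprintf("plate(s) of compound '%s' have < 2 DMSO wells", compound),
         call. = FALSE)
  }
  lfc <- mean(v[tr] - dmso_mean[wells$plate_id[tr]])
  n_treat <- sum(tr); n_ctrl <- sum(ctrl)
  if (n_treat < 2L) {
    return(list(log2fc = lfc, t_stat = 0, p_value = 1, n_treat = n_treat,
                n_ctrl = n_ctrl, flagged = TRUE))
  }
  tp <- pooled_t(v[tr], v[ctrl], var_floor)
  list(log2fc = lfc, t_stat = unname(tp["t"]), p_value = unname(tp["p"]),
       n_treat = n_treat, n_ctrl = n_ctrl, flagged = FALSE)
}

#' Combined signature score for one compound
#'
#' Score = mean over signature genes of (-log10 p) x (-log2FC) x dir, with
#' dir = +1 for a down-regulation signature (so genes moving down with small
#' p contribute positively) and -1 for an up signature. Monotone in both the
#' evidence (-log10 p) and the effect size for concordant genes; a gene
#' moving against the signature direction subtracts.
#'
#' @param per_gene named list (gene -> list(log2fc, p_value)) covering every
#'   signature gene.
#' @param sig a [gene_signature()].
#' @return Numeric score (larger = stronger signature-concordant regulation).
#' @export
score_compound <- function(per_gene, sig) {
  stopifnot(inherits(sig, "gene_signature"))
  missing <- setdiff(sig$genes, names(per_gene))
  if (length(missing)) {
    stop("missing signature gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir <- if (sig$direction == "down") 1 else -1
  contrib <- vapply(sig$genes, function(g) {
    e <- per_gene[[g]]
    (-log10(e$p_value)) * (-e$log2fc) * dir
  }, numeric(1))
  mean(contrib)
}

#' Score and rank every compound in a screen
#'
#' Vectorized driver: computes per-gene fold changes and pooled-t p values
#' for all compounds against their same-plate DMSO controls, combines them
#' with [score_compound()]'s formula, and ranks. Ties are broken by smaller
#' mean p, then lexicographic compound id, so the order is deterministic.
#'
#' @param values corrected log2 well x probe matrix.
#' @param wells well metadata aligned with rows of `values`.
#' @param panel probe panel.
#' @param sig a [gene_signature()].
#' @param top_k hits to call (default 10).
#' @param var_floor pooled-variance floor.
#' @return `data.frame` with compound_id, per-gene log2fc/t/p columns, score,
#'   mean_p, rank, hit flag, plus BH-adjusted p columns for reporting.
#' @export
rank_compounds <- function(values, wells, panel, sig, top_k = 10L,
                           var_floor = 1e-6) {
  stopifnot(nrow(values) == nrow(wells))
  compounds <- sort(unique(wells$compound_id[!wells$is_dmso]))
  if (top_k > length(compounds)) stop("top_k exceeds compound count", call. = FALSE)
  dir <- if (sig$direction == "down") 1 else -1

  gene_mats <- lapply(sig$genes, function(g) gene_values(values, panel, g))
  names(gene_mats) <- sig$genes

  res <- data.frame(compound_id = compounds, stringsAsFactors = FALSE)
  contrib <- matrix(0, length(compounds), length(sig$genes),
                    dimnames = list(compounds, sig$genes))
  pmat <- contrib
  cmpd_idx <- split(seq_len(nrow(wells))[!wells$is_dmso],
                    wells$compound_id[!wells$is_dmso])

  for (g in sig$genes) {
    v <- gene_mats[[g]]
    dmso_by_plate <- tapply(v[wells$is_dmso], wells$plate_id[wells$is_dmso],
                            mean)
    dmso_vals_by_plate <- split(v[wells$is_dmso],
                                wells$plate_id[wells$is_dmso])
    lfc <- numeric(length(compounds)); tt <- lfc; pp <- lfc
    for (i in seq_along(compounds)) {
      idx <- cmpd_idx[[compounds[i]]]
      plates <- unique(wells$plate_id[idx])
      lfc[i] <- mean(v[idx] - dmso_by_plate[wells$plate_id[idx]])
      if (length(idx) < 2L) {
        tt[i] <- 0; pp[i] <- 1
      } else {
        ctrl <- unlist(dmso_vals_by_plate[plates], use.names = FALSE)
        tp <- pooled_t(v[idx], ctrl, var_floor)
        tt[i] <- tp["t"]; pp[i] <- tp["p"]
      }
    }
    res[[paste0(g, "_log2fc")]] <- lfc
    res[[paste0(g, "_t")]] <- tt
    res[[paste0(g, "_p")]] <- pp
    res[[paste0(g, "_p_adj")]] <- stats::p.adjust(pp, "BH")
    contrib[, g] <- (-log10(pp)) * (-lfc) * dir
    pmat[, g] <- pp
  }
  res$score <- rowMeans(contrib)
  res$mean_p <- rowMeans(pmat)
  ord <- order(-res$score, res$mean_p, res$compound_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$hit <- res$rank <= top_k
  rownames(res) <- NULL
  res
}
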