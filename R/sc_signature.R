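#' Container for single-cell expression data
#'
#' Lightweight holder for a gene x cell count matrix with aligned per-cell
#' and per-gene metadata. Mitochondrial genes are flagged from the symbol
#' prefix (`MT-` human / `mt-` mouse by default, case-sensitive).
#'
#' @param counts gene x cell non-negative matrix (dense or sparse); rownames
#'   are gene symbols, colnames cell ids.
#' @param cell_meta per-cell `data.frame`; must have one row per column of
#'   `counts` (a `cell_id` column is added from colnames if absent).
#' @param gene_meta optional per-gene `data.frame`; a `mito` flag is derived
#'   from `mito_prefix` when absent.
#' @param lognorm optional gene x cell normalized matrix.
#' @param mito_prefix regular expression anchored at the symbol start.
#' @return An object of class `cell_data`.
#' @export
cell_data <- function(counts, cell_meta = NULL, gene_meta = NULL,
                      lognorm = NULL, mito_prefix = "^(MT-|mt-)") {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs gene rownames and cell colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = colnames(counts), stringsAsFactors = FALSE)
  }
  if (nrow(cell_meta) != ncol(counts)) {
    stop("cell_meta rows must align with counts columns", call. = FALSE)
  }
  if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- colnames(counts)
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(symbol = rownames(counts), stringsAsFactors = FALSE)
  }
  if (is.null(gene_meta$mito)) {
    gene_meta$mito <- grepl(mito_prefix, gene_meta$symbol)
  }
  structure(list(counts = counts, lognorm = lognorm, cell_meta = cell_meta,
                 gene_meta = gene_meta), class = "cell_data")
}

#' @export
print.cell_data <- function(x, ...) {
  cat(sprintf("cell_data: %d genes x %d cells (%s)\n", nrow(x$counts),
              ncol(x$counts),
              if (is.null(x$lognorm)) "counts only" else "log-normalized"))
  invisible(x)
}

#' Quality-control filter on cells
#'
#' Keeps cells detecting at least `min_genes` genes AND with a mitochondrial
#' count fraction of at most `max_mito_frac`; the conventional exclusion of
#' cells expressing fewer than 200 genes or over 30% mitochondrial content.
#'
#' @param data a [cell_data()].
#' @param min_genes minimum detected genes (count > 0).
#' @param max_mito_frac maximum mitochondrial count fraction.
#' @return Filtered `cell_data`; attribute `"filter_report"` lists kept and
#'   per-criterion dropped counts.
#' @export
filter_cells <- function(data, min_genes = 200L, max_mito_frac = 0.30) {
  stopifnot(inherits(data, "cell_data"))
  detected <- Matrix::colSums(data$counts > 0)
  total <- Matrix::colSums(data$counts)
  mito <- data$gene_meta$mito
  mito_frac <- if (any(mito)) {
    Matrix::colSums(data$counts[mito, , drop = FALSE]) / pmax(total, 1)
  } else {
    rep(0, ncol(data$counts))
  }
  low_genes <- detected < min_genes
  high_mito <- mito_frac > max_mito_frac
  keep <- !low_genes & !high_mito
  report <- list(kept = sum(keep), dropped_low_genes = sum(low_genes),
                 dropped_high_mito = sum(high_mito), total = length(keep))
  if (!any(keep)) {
    stop(sprintf("all %d cells dropped (low genes: %d, high mito: %d)",
                 report$total, report$dropped_low_genes,
                 report$dropped_high_mito), call. = FALSE)
  }
  out <- cell_data(data$counts[, keep, drop = FALSE],
                   cell_meta = data$cell_meta[keep, , drop = FALSE],
                   gene_meta = data$gene_meta,
                   lognorm = if (is.null(data$lognorm)) NULL else
                     data$lognorm[, keep, drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Library-size log normalization
#'
#' `lognorm = log(1 + scale * count / cell_total)` (natural log), equalizing
#' cell totals before the log.
#'
#' @param data a [cell_data()] (filter zero-total cells first).
#' @param scale library-size target (default 1e4).
#' @return The `cell_data` with its `lognorm` slot filled.
#' @export
lognormalize <- function(data, scale = 1e4) {
  stopifnot(inherits(data, "cell_data"))
  total <- Matrix::colSums(data$counts)
  if (any(total == 0)) {
    stop("zero-total cell(s): ",
         paste(utils::head(colnames(data$counts)[total == 0], 5),
               collapse = ", "), call. = FALSE)
  }
  ln <- log1p(sweep(as.matrix(data$counts), 2, total, "/") * scale)
  dimnames(ln) <- dimnames(data$counts)
  data$lognorm <- ln
  data
}

#' Gene-module score with binned control genes
#'
#' All genes are binned into `nbin` expression bins by across-cell mean of
#' the log-normalized values; for each signature gene, `nctrl` control genes
#' are drawn (seeded) from the same bin. The per-cell score is the mean over
#' signature genes minus the mean over the pooled control genes, so a score
#' of 0 means "no enrichment beyond expression-matched background".
#'
#' @param data log-normalized [cell_data()].
#' @param sig a [gene_signature()] or character vector of genes.
#' @param nbin number of equal-frequency expression bins (default 24).
#' @param nctrl control genes per signature gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return Named per-cell numeric scores; attributes record the signature
#'   name, missing genes and parameters.
#' @export
module_score <- function(data, sig, nbin = 24L, nctrl = 100L, seed = 1L) {
  stopifnot(inherits(data, "cell_data"))
  if (is.null(data$lognorm)) data <- lognormalize(data)
  genes <- if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
  if (nbin < 2L) stop("nbin must be >= 2", call. = FALSE)
  present <- intersect(genes, rownames(data$lognorm))
  if (length(present) == 0L) {
    stop("no signature gene found in data; missing: ",
         paste(genes, collapse = ", "), call. = FALSE)
  }
  x <- data$lognorm
  avg <- rowMeans(x)
  # equal-frequency bins; jitter-free via rank with random tie-break under seed
  score <- with_seed(seed, {
    rk <- rank(avg, ties.method = "random")
    bin <- cut(rk, breaks = nbin, labels = FALSE, include.lowest = TRUE)
    names(bin) <- rownames(x)
    ctrl <- unique(unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[g]]
      pool <- setdiff(pool, g)
      if (length(pool) == 0L) return(character())
      sample(pool, min(nctrl, length(pool)))
    })))
    sig_mean <- colMeans(x[present, , drop = FALSE])
    ctrl_mean <- if (length(ctrl)) colMeans(x[ctrl, , drop = FALSE]) else 0
    sig_mean - ctrl_mean
  })
  attr(score, "signature") <- if (inherits(sig, "gene_signature")) sig$name else "custom"
  attr(score, "missing_genes") <- setdiff(genes, present)
  attr(score, "params") <- list(nbin = nbin, nctrl = nctrl, seed = seed)
  score
}

#' Split units into high/low groups
#'
#' Median rule: strictly above the median is `high`, at or below is `low`.
#' Threshold rule: strictly above `cutoff` is `high`.
#'
#' @param scores per-unit numeric vector.
#' @param rule `"median"` or `"threshold"`.
#' @param cutoff numeric cutoff for the threshold rule.
#' @return Factor with levels `low`, `high`, named like `scores`.
#' @export
stratify <- function(scores, rule = c("median", "threshold"), cutoff = NULL) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stop("need >= 2 units", call. = FALSE)
  cut_at <- if (rule == "median") {
    if (length(unique(scores)) == 1L) {
      stop("all scores identical; use rule = 'threshold'", call. = FALSE)
    }
    stats::median(scores)
  } else {
    if (is.null(cutoff)) stop("threshold rule needs a cutoff", call. = FALSE)
    cutoff
  }
  out <- factor(ifelse(scores > cut_at, "high", "low"),
                levels = c("low", "high"))
  names(out) <- names(scores)
  out
}

#' Compare cell-type composition between groups
#'
#' Builds a group x type contingency table and applies Pearson's chi-square
#' test without continuity correction; per-group type proportions are
#' returned alongside.
#'
#' @param labels per-cell group factor (two groups).
#' @param types per-cell annotated type.
#' @return List: `table`, `proportions` (rows sum to 1), `chisq`, `df`, `p`,
#'   `warning` (set when an expected cell is below 1).
#' @export
composition_test <- function(labels, types) {
  stopifnot(length(labels) == length(types))
  tab <- table(labels, types)
  if (nrow(tab) < 2L || any(rowSums(tab) == 0)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (ncol(tab) < 2L) stop("need >= 2 cell types", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expected < 1)) {
    sprintf("%d expected cell(s) below 1; chi-square approximation is weak",
            sum(expected < 1))
  } else {
    NULL
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  props <- sweep(tab, 1, rowSums(tab), "/")
  list(table = tab, proportions = props,
       chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = if (unname(ct$statistic) == 0) 1 else unname(ct$p.value),
       warning = warn)
}

#' Mann-Whitney comparison of two groups
#'
#' Exact null distribution when both groups have at most `exact_max` units
#' and the data are tie-free; normal approximation with tie correction (no
#' continuity correction) otherwise. An all-tied comparison, where the
#' normal approximation is 0/0, returns U = n1*n2/2 and p = 1.
#'
#' @param values per-unit numeric vector.
#' @param labels two-level factor aligned with `values`; U counts pairs won
#'   by the first level.
#' @param exact_max exact-branch size limit (default 8 per group).
#' @return List: `U`, `p` (two-sided), `method`.
#' @export
group_compare <- function(values, labels, exact_max = 8L) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels", call. = FALSE)
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  ties <- anyDuplicated(values) > 0L
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    return(list(U = unname(U), p = wt$p.value, method = "exact"))
  }
  # normal approximation with tie correction
  nn <- n1 + n2
  tie_tab <- table(values)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) /
                              (nn * (nn - 1)))
  if (sigma2 <= 0) {
    return(list(U = unname(U), p = 1, method = "degenerate"))
  }
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = unname(U), p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Pearson or Spearman correlation with test
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `p`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length x, y with n >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Per-patient mean expression over a cell subset
#'
#' Averages log-normalized expression of `genes` over each patient's cells in
#' `cell_subset` (an annotated-type filter); patients with no cell in the
#' subset are dropped with a warning.
#'
#' @param data log-normalized [cell_data()] whose `cell_meta` has `patient`
#'   and `cell_type` columns.
#' @param genes gene symbols (averaged together).
#' @param cell_subset types to keep; `NULL` keeps all cells.
#' @return Named per-patient means.
#' @export
patient_aggregate <- function(data, genes, cell_subset = NULL) {
  stopifnot(inherits(data, "cell_data"))
  if (is.null(data$lognorm)) data <- lognormalize(data)
  genes <- intersect(genes, rownames(data$lognorm))
  if (length(genes) == 0L) stop("no requested gene present", call. = FALSE)
  keep <- if (is.null(cell_subset)) {
    rep(TRUE, ncol(data$lognorm))
  } else {
    data$cell_meta$cell_type %in% cell_subset
  }
  if (!any(keep)) stop("cell subset is empty", call. = FALSE)
  pat_all <- unique(data$cell_meta$patient)
  v <- colMeans(data$lognorm[genes, keep, drop = FALSE])
  agg <- tapply(v, data$cell_meta$patient[keep], mean)
  out <- stats::setNames(as.numeric(agg), names(agg))
  lost <- setdiff(pat_all, names(out))
  if (length(lost)) {
    warning("patient(s) with no cell in subset dropped: ",
            paste(lost, collapse = ", "))
  }
  out[!is.na(out)]
}

#' Spot-level coexpression of two genes
#'
#' A spot coexpresses the pair when both transcripts are present
#' (count > 0 for both).
#'
#' @param spots spot x gene count matrix.
#' @param gene_a,gene_b gene symbols (columns of `spots`).
#' @return List: `label` (per-spot factor none/a_only/b_only/both) and
#'   `fraction` (share of spots labelled both).
#' @export
spot_coexpression <- function(spots, gene_a, gene_b) {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(spots)) stop(sprintf("gene '%s' absent", g), call. = FALSE)
  }
  a <- spots[, gene_a] > 0
  b <- spots[, gene_b] > 0
  label <- factor(ifelse(a & b, "both",
                         ifelse(a, "a_only", ifelse(b, "b_only", "none"))),
                  levels = c("none", "a_only", "b_only", "both"))
  names(label) <- rownames(spots)
  list(label = label, fraction = mean(a & b))
}
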