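#' Per-sample z-score of a gene signature
#'
#' Centers each gene at its across-sample mean and scales by the sample SD,
#' then averages over the signature genes; full standardization keeps genes
#' on a common scale before averaging. Zero-variance genes are dropped with
#' a warning; an all-constant signature is an error.
#'
#' @param values sample x gene matrix (n >= 3 samples).
#' @param genes signature gene symbols (columns of `values`), or a
#'   [gene_signature()].
#' @return Named per-sample z vector.
#' @export
zscore_signature <- function(values, genes) {
  if (inherits(genes, "gene_signature")) genes <- genes$genes
  if (nrow(values) < 3L) stop("need >= 3 samples", call. = FALSE)
  genes <- intersect(genes, colnames(values))
  if (length(genes) == 0L) stop("no signature gene in matrix", call. = FALSE)
  x <- values[, genes, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(genes[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0L) stop("all signature genes constant", call. = FALSE)
  }
  z <- scale(x)
  stats::setNames(rowMeans(z), rownames(values))
}

#' ROC curve and AUC
#'
#' AUC is computed through the Mann-Whitney identity with midrank tie
#' handling: AUC = U / (n1 * n2), where U counts pairs in which a positive
#' outranks a negative (ties count 1/2). The curve sweeps the unique scores
#' as thresholds, descending ("positive" = score above threshold).
#'
#' @param scores per-subject numeric predictor.
#' @param labels binary outcome (coercible to 0/1; 1 = positive class).
#' @return List: `thresholds` (descending), `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)                      # midranks
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1L] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0L] >= t), numeric(1))
  list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Kaplan-Meier product-limit estimate per group
#'
#' Wraps the standard product-limit estimator; subjects censored at an event
#' time are counted at risk for that time.
#'
#' @param table survival `data.frame` with `time`, `event` and (optionally)
#'   `group` columns.
#' @param group optional per-subject group overriding `table$group`; `NULL`
#'   with no group column estimates one curve.
#' @return Named list of per-group curves, each with `time` (ascending event
#'   times), `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(table, group = NULL) {
  group <- group %||% table$group %||% rep("all", nrow(table))
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  sf <- survival::survfit(survival::Surv(table$time, table$event) ~ g,
                          data = data.frame(g = group))
  strata <- if (is.null(sf$strata)) {
    stats::setNames(length(sf$time), paste0("g=", unique(group)))
  } else {
    sf$strata
  }
  idx <- rep(names(strata), strata)
  out <- lapply(split(seq_along(sf$time), idx), function(i) {
    list(time = sf$time[i], n_risk = sf$n.risk[i], n_event = sf$n.event[i],
         surv = sf$surv[i])
  })
  names(out) <- sub("^g=", "", names(out))
  out
}

#' Log-rank (Mantel-Cox) test
#'
#' Unweighted observed-minus-expected over the pooled event times, with the
#' standard hypergeometric variance under ties; chi-square with 1 degree of
#' freedom, two-sided p.
#'
#' @param table survival `data.frame` (`time`, `event`).
#' @param group two-level per-subject group (defaults to `table$group`).
#' @return List: `chisq`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(table, group = NULL) {
  group <- group %||% table$group
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank needs exactly 2 groups", call. = FALSE)
  if (sum(table$event) == 0) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(table$time, table$event) ~ g,
                           data = data.frame(g = g))
  chisq <- unname(sd$chisq)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       observed = stats::setNames(sd$obs, levels(g)),
       expected = stats::setNames(sd$exp, levels(g)))
}

#' Scan for the survival cutoff minimizing the log-rank p
#'
#' Every unique score between the 25th and 75th percentile is tried as a
#' high/low cutoff (strictly above = high); the returned `p_at_cutoff` is
#' the minimum over the scan and is therefore an optimized quantity, NOT a
#' valid nominal p value - it is always flagged, and a permutation-adjusted
#' p (re-running the scan on label-permuted data) is available.
#'
#' @param table survival `data.frame` with `time`, `event`, `score`.
#' @param n_perm permutations for the adjusted p (0 skips it).
#' @param window quantile window of candidate cutoffs (default c(0.25, 0.75)).
#' @param seed RNG seed for the permutations.
#' @return List: `cutoff`, `p_at_cutoff`, `optimized` (always TRUE), `scan`
#'   (data.frame of cutoff, p), `perm_p` (or NA).
#' @export
best_cutoff <- function(table, n_perm = 0L, window = c(0.25, 0.75), seed = 1L) {
  if (nrow(table) < 10L) stop("need >= 10 subjects", call. = FALSE)
  q <- stats::quantile(table$score, window)
  cand <- sort(unique(table$score))
  cand <- cand[cand >= q[1] & cand <= q[2]]
  # a cutoff at the largest candidate would empty the high group
  cand <- cand[cand < max(table$score)]
  if (length(cand) < 2L) stop("fewer than 2 candidate cutoffs", call. = FALSE)
  scan_p <- function(scores) {
    vapply(cand, function(ct) {
      grp <- ifelse(scores > ct, "high", "low")
      if (length(unique(grp)) < 2L) return(NA_real_)
      logrank_test(table, grp)$p
    }, numeric(1))
  }
  ps <- scan_p(table$score)
  best <- which.min(ps)
  min_p <- ps[best]
  perm_p <- NA_real_
  if (n_perm > 0L) {
    perm_min <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        min(scan_p(sample(table$score)), na.rm = TRUE)
      }, numeric(1))
    })
    perm_p <- (1 + sum(perm_min <= min_p)) / (n_perm + 1)
  }
  list(cutoff = cand[best], p_at_cutoff = min_p, optimized = TRUE,
       scan = data.frame(cutoff = cand, p = ps), perm_p = perm_p)
}

#' Immunohistochemistry H-score
#'
#' H = sum over intensity levels 0..3 of (level x percent of cells at that
#' level); range 0-300.
#'
#' @param fractions length-4 vector of percentages at intensities 0, 1, 2, 3;
#'   must sum to 100 (within 0.1).
#' @return The H-score.
#' @export
h_score <- function(fractions) {
  if (length(fractions) != 4L || any(fractions < 0)) {
    stop("fractions must be 4 non-negative percentages", call. = FALSE)
  }
  if (abs(sum(fractions) - 100) > 0.1) {
    stop("fractions must sum to 100", call. = FALSE)
  }
  sum(0:3 * fractions)
}

#' Caliper tumor volume
#'
#' volume (mm^3) = width^2 (mm^2) x length (mm) / 2, with width the smaller
#' dimension; swapped arguments are corrected with a warning.
#'
#' @param width,length caliper measurements in mm (both > 0).
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(width, length) {
  if (any(c(width, length) <= 0)) stop("dimensions must be > 0", call. = FALSE)
  if (width > length) {
    warning("width > length; swapping to enforce the convention")
    tmp <- width; width <- length; length <- tmp
  }
  width^2 * length / 2
}
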