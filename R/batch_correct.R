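#' PCA diagnostic of batch structure
#'
#' Computes principal components of the log2(value + 1), probe-centered
#' well-by-probe matrix and, for each PC, the R-squared of a one-way ANOVA of
#' the PC scores on the batch label. Large R-squared on leading PCs indicates
#' batch-dominated variation.
#'
#' @param values well x probe matrix of normalized (non-log) values.
#' @param batches per-well batch label (e.g. plate id).
#' @param k number of PCs to report.
#' @param log_transform log2(x+1)-transform before PCA (default TRUE; set
#'   FALSE when `values` is already on log scale).
#' @return List with `pc_scores` (well x k), `variance_explained` and
#'   `batch_assoc_r2` (per PC).
#' @export
pca_batch_diag <- function(values, batches, k = 5L, log_transform = TRUE) {
  stopifnot(nrow(values) == length(batches))
  if (length(unique(batches)) < 2L) {
    stop("batch association is undefined with a single batch", call. = FALSE)
  }
  k <- min(k, nrow(values) - 1L, ncol(values))
  x <- if (log_transform) log2p1(values) else values
  x <- scale(x, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  b <- factor(batches)
  r2 <- apply(scores, 2, function(s) summary(stats::lm(s ~ b))$r.squared)
  list(pc_scores = scores, variance_explained = ve,
       batch_assoc_r2 = stats::setNames(r2, colnames(scores)))
}

# ML (1/n) variance over a vector.
var_ml <- function(x) mean((x - mean(x))^2)

# Moment-matched inverse-gamma hyperparameters for the scale prior.
ig_aprior <- function(d) {
  m <- mean(d); v <- var_ml(d)
  (2 * v + m^2) / v
}
ig_bprior <- function(d) {
  m <- mean(d); v <- var_ml(d)
  (m * v + m^3) / v
}

#' Fit an empirical-Bayes location/scale batch model
#'
#' Standardizes each probe (removing the batch-design grand mean and optional
#' covariate fit, dividing by the pooled SD), estimates per-batch per-probe
#' location and scale effects, and shrinks them toward batch-level normal and
#' inverse-gamma priors using the standard moment-matched iterative
#' empirical-Bayes estimates. Variances use maximum-likelihood (1/n)
#' denominators so that a single-batch fit is exactly the identity transform;
#' degenerate priors (no across-probe spread in the batch estimates) fall
#' back to the unshrunk estimates.
#'
#' @param values well x probe matrix on log scale (log2 of normalized counts).
#' @param batches per-well batch label.
#' @param covariates optional numeric design matrix of biological covariates
#'   to protect (no intercept; batch design is added internally).
#' @param conv convergence tolerance of the iterative EB solve.
#' @param max_iter iteration cap.
#' @return A `batch_model` list: `grand_mean`, `pooled_var` (per probe),
#'   `gamma_star`, `delta2_star` (batch x probe), `batch_levels`,
#'   `beta` (covariate coefficients), `constant_probes`.
#' @export
combat_fit <- function(values, batches, covariates = NULL, conv = 1e-4,
                       max_iter = 100L) {
  stopifnot(is.matrix(values), nrow(values) == length(batches))
  b <- factor(batches)
  n_b <- table(b)
  if (any(n_b < 2L)) {
    stop("every batch needs >= 2 wells: ",
         paste(names(n_b)[n_b < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(values)
  levels_b <- levels(b)

  constant <- apply(values, 2, function(x) var_ml(x) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant probe(s) pass through uncorrected")
  }
  work <- values[, !constant, drop = FALSE]
  if (ncol(work) == 0L) stop("all probes constant", call. = FALSE)

  # batch indicator design built directly (model.matrix rejects 1 level)
  design_b <- matrix(0, n, length(levels_b))
  design_b[cbind(seq_len(n), as.integer(b))] <- 1
  design <- if (is.null(covariates)) design_b else cbind(design_b, covariates)
  fit <- stats::lm.fit(design, work)
  coefs <- fit$coefficients
  batch_means <- coefs[seq_along(levels_b), , drop = FALSE]
  beta <- if (is.null(covariates)) NULL else {
    coefs[-seq_along(levels_b), , drop = FALSE]
  }
  grand_mean <- as.numeric(n_b / n) %*% batch_means   # 1 x probes
  pooled_var <- colMeans(fit$residuals^2)             # ML denominator
  if (any(pooled_var == 0)) {
    stop("probe(s) with zero residual variance inside batches", call. = FALSE)
  }

  stand_mean <- matrix(grand_mean, n, ncol(work), byrow = TRUE)
  if (!is.null(beta)) stand_mean <- stand_mean + covariates %*% beta
  z <- (work - stand_mean) / matrix(sqrt(pooled_var), n, ncol(work),
                                    byrow = TRUE)

  gamma_hat <- rowsum(z, b) / as.numeric(n_b)
  delta2_hat <- rowsum(z^2, b) / as.numeric(n_b) - gamma_hat^2
  delta2_hat <- pmax(delta2_hat, 1e-12)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_along(levels_b)) {
    g <- gamma_hat[i, ]; d <- delta2_hat[i, ]
    g_bar <- mean(g); tau2 <- var_ml(g)
    v_d <- var_ml(d)
    degen_g <- tau2 < 1e-12
    degen_d <- v_d < 1e-12
    a_pr <- if (degen_d) NA else ig_aprior(d)
    b_pr <- if (degen_d) NA else ig_bprior(d)
    zi <- z[b == levels_b[i], , drop = FALSE]
    ni <- nrow(zi)
    g_new <- g; d_new <- d
    if (!degen_g || !degen_d) {
      change <- 1
      iter <- 0L
      while (change > conv && iter < max_iter) {
        g_old <- g_new; d_old <- d_new
        if (!degen_g) {
          g_new <- (ni * tau2 * g + d_new * g_bar) / (ni * tau2 + d_new)
        }
        if (!degen_d) {
          ss <- colSums((zi - matrix(g_new, ni, ncol(zi), byrow = TRUE))^2)
          d_new <- (0.5 * ss + b_pr) / (ni / 2 + a_pr - 1)
        }
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                      abs(d_new - d_old) / pmax(abs(d_old), 1e-8))
        iter <- iter + 1L
      }
    }
    gamma_star[i, ] <- g_new
    delta2_star[i, ] <- d_new
  }

  structure(list(
    grand_mean = stats::setNames(as.numeric(grand_mean), colnames(work)),
    pooled_var = pooled_var,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    batch_levels = levels_b, beta = beta,
    probes = colnames(work),
    constant_probes = colnames(values)[constant]
  ), class = "batch_model")
}

#' Apply a fitted batch model
#'
#' Corrected value = (standardized - gamma*) / sqrt(delta2*) x pooled SD +
#' grand mean (+ covariate fit). Probes flagged constant at fit time pass
#' through unchanged.
#'
#' @param values well x probe log-scale matrix.
#' @param batches per-well batch label; every label must exist in the model.
#' @param model a `batch_model` from [combat_fit()].
#' @param covariates covariate design used at fit time, if any.
#' @return Corrected matrix, same dimensions as `values`.
#' @export
combat_adjust <- function(values, batches, model, covariates = NULL) {
  stopifnot(inherits(model, "batch_model"), nrow(values) == length(batches))
  b <- as.character(batches)
  unseen <- setdiff(unique(b), model$batch_levels)
  if (length(unseen)) {
    stop("unseen batch label(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  out <- values
  probes <- model$probes
  work <- values[, probes, drop = FALSE]
  n <- nrow(work)
  stand_mean <- matrix(model$grand_mean, n, length(probes), byrow = TRUE)
  if (!is.null(model$beta)) {
    if (is.null(covariates)) stop("model was fit with covariates", call. = FALSE)
    stand_mean <- stand_mean + covariates %*% model$beta
  }
  sdv <- matrix(sqrt(model$pooled_var), n, length(probes), byrow = TRUE)
  z <- (work - stand_mean) / sdv
  idx <- match(b, model$batch_levels)
  z_adj <- (z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta2_star[idx, , drop = FALSE])
  out[, probes] <- z_adj * sdv + stand_mean
  out
}
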