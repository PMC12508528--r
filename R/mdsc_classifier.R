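#' Train a reference-projection cell-type classifier
#'
#' Log-normalizes the annotated reference, standardizes genes, decomposes by
#' truncated PCA, selects for each class the PCs whose scores differ between
#' the class and the rest (two-sided Wilcoxon, BH-adjusted p < `alpha`), and
#' fits a one-vs-rest probabilistic linear (ridge-logistic) classifier on the
#' selected PC scores. The query is later projected into this space with the
#' reference centering/scaling and loadings - never re-fit.
#'
#' @param reference a [cell_data()] whose `cell_meta$cell_type` holds the
#'   training labels.
#' @param n_pcs number of principal components (default 30).
#' @param alpha BH-adjusted significance level of the informative-PC test.
#' @param prob_threshold minimum winning probability for assignment;
#'   cells below it are `unassigned` (default 0.55).
#' @param min_cells_per_class floor on class size.
#' @param lambda ridge penalty of the per-class logistic fits.
#' @param seed RNG seed (kept for interface stability; the fit itself is
#'   deterministic).
#' @return A `projection_model`: gene_list, center, scale, loadings,
#'   selected_pcs, classifier_params, classes, prob_threshold, train_scores.
#' @export
train_celltype_model <- function(reference, n_pcs = 30L, alpha = 0.05,
                                 prob_threshold = 0.55,
                                 min_cells_per_class = 20L, lambda = 0.01,
                                 seed = 1L) {
  stopifnot(inherits(reference, "cell_data"))
  labels <- reference$cell_meta$cell_type
  if (is.null(labels)) stop("reference cell_meta needs a cell_type column", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  n_per <- table(labels)
  if (any(n_per < min_cells_per_class)) {
    stop("class(es) below the cell floor: ",
         paste(names(n_per)[n_per < min_cells_per_class], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(reference$lognorm)) reference <- lognormalize(reference)
  x <- t(reference$lognorm)                       # cells x genes
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  gene_list <- colnames(x)
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  xs <- sweep(sweep(x, 2, center, "-"), 2, scl, "/")
  n_pcs <- min(n_pcs, nrow(xs) - 1L, ncol(xs))
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x

  selected <- list()
  params <- list()
  for (cl in classes) {
    is_cl <- labels == cl
    p <- apply(scores, 2, function(s) {
      stats::wilcox.test(s[is_cl], s[!is_cl], exact = FALSE)$p.value
    })
    sel <- which(stats::p.adjust(p, "BH") < alpha)
    if (length(sel) == 0L) {
      stop(sprintf("no informative PC for class '%s'; try larger n_pcs", cl),
           call. = FALSE)
    }
    selected[[cl]] <- sel
    # glmnet requires >= 2 columns; a constant 0 column carries coef 0
    xx <- scores[, sel, drop = FALSE]
    pad <- ncol(xx) == 1L
    if (pad) xx <- cbind(xx, 0)
    fit <- glmnet::glmnet(xx, factor(is_cl, levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = TRUE)
    cf <- as.numeric(fit$beta)
    if (pad) cf <- cf[1]
    params[[cl]] <- list(intercept = as.numeric(fit$a0), coef = cf)
  }
  structure(list(
    gene_list = gene_list, center = center, scale = scl,
    loadings = pc$rotation, selected_pcs = selected,
    classifier_params = params, classes = classes,
    prob_threshold = prob_threshold, n_pcs = n_pcs,
    train_scores = scores, seed = as.integer(seed)
  ), class = "projection_model")
}

#' Project query cells into the reference PCA space
#'
#' Aligns the query to the model's gene list by symbol (genes missing from
#' the query contribute 0 after centering, i.e. are imputed at the reference
#' mean), applies the reference centering/scaling and loadings. Errors when
#' fewer than `min_overlap` of the model genes are present.
#'
#' @param model a `projection_model`.
#' @param query a [cell_data()].
#' @param min_overlap minimum fraction of model genes required (default 0.5).
#' @return cell x PC score matrix.
#' @export
project_cells <- function(model, query, min_overlap = 0.5) {
  stopifnot(inherits(model, "projection_model"), inherits(query, "cell_data"))
  if (is.null(query$lognorm)) query <- lognormalize(query)
  present <- intersect(model$gene_list, rownames(query$lognorm))
  frac <- length(present) / length(model$gene_list)
  if (frac < min_overlap) {
    stop(sprintf("only %.0f%% of model genes present in query (floor %.0f%%)",
                 100 * frac, 100 * min_overlap), call. = FALSE)
  }
  n_cells <- ncol(query$lognorm)
  xs <- matrix(0, n_cells, length(model$gene_list),
               dimnames = list(colnames(query$lognorm), model$gene_list))
  xq <- t(query$lognorm[present, , drop = FALSE])
  xs[, present] <- sweep(sweep(xq, 2, model$center[present], "-"),
                         2, model$scale[present], "/")
  xs %*% model$loadings
}

#' Classify projected cells
#'
#' Per-class one-vs-rest probabilities from the calibrated linear classifier;
#' a cell is labelled with the maximum-probability class when that
#' probability reaches the model's threshold, otherwise `unassigned`.
#'
#' @param model a `projection_model`.
#' @param pc_scores cell x PC matrix from [project_cells()].
#' @return List: `probabilities` (cell x class), `label` (character vector,
#'   classes plus `"unassigned"`).
#' @export
predict_celltype <- function(model, pc_scores) {
  stopifnot(inherits(model, "projection_model"))
  probs <- sapply(model$classes, function(cl) {
    sel <- model$selected_pcs[[cl]]
    if (max(sel) > ncol(pc_scores)) {
      stop("pc_scores does not cover the model's selected PCs", call. = FALSE)
    }
    par <- model$classifier_params[[cl]]
    eta <- par$intercept + pc_scores[, sel, drop = FALSE] %*% par$coef
    as.numeric(plogis(eta))
  })
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, model$classes))
  rownames(probs) <- rownames(pc_scores)
  best <- max.col(probs, ties.method = "first")
  best_p <- probs[cbind(seq_len(nrow(probs)), best)]
  label <- ifelse(best_p >= model$prob_threshold, model$classes[best],
                  "unassigned")
  names(label) <- rownames(probs)
  list(probabilities = probs, label = label)
}

#' Serialize a projection model to JSON
#'
#' Everything, including the loadings matrix, is written as (nested) JSON
#' arrays so the artifact is plain text.
#'
#' @param model a `projection_model`.
#' @param path output file.
#' @export
write_projection_model <- function(model, path) {
  out <- model
  out$loadings <- list(values = as.numeric(model$loadings),  # column-major
                       nrow = nrow(model$loadings),
                       rownames = rownames(model$loadings),
                       colnames = colnames(model$loadings))
  out$train_scores <- NULL
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection model from JSON
#'
#' @param path file written by [write_projection_model()].
#' @return A `projection_model` (without training scores).
#' @export
read_projection_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ld <- matrix(as.numeric(x$loadings$values), nrow = x$loadings$nrow,
               dimnames = list(x$loadings$rownames, x$loadings$colnames))
  x$loadings <- ld
  x$center <- stats::setNames(as.numeric(x$center), x$gene_list)
  x$scale <- stats::setNames(as.numeric(x$scale), x$gene_list)
  x$classifier_params <- lapply(x$classifier_params, function(p) {
    list(intercept = p$intercept, coef = as.numeric(p$coef))
  })
  structure(x, class = "projection_model")
}
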