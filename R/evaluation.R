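#' Binary classification metrics with ROC/AUC
#'
#' Confusion matrix (rows = truth, columns = predicted), accuracy, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1, and the ROC curve / AUC computed by
#' trapezoidal integration over thresholds at the unique scores (midrank tie
#' handling, so the AUC equals the Mann-Whitney U formulation). Glycolysis
#' is the conventional positive class.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param scores Numeric probabilities of the positive class (needed for
#'   ROC/AUC; optional).
#' @param positive Positive class label.
#' @return A `flim_metrics` object; see [tidy.flim_metrics()].
#' @export
binary_metrics <- function(truth, predicted, scores = NULL,
                           positive = "glycolysis") {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  lev <- union(positive, sort(unique(c(truth, predicted))))
  conf <- table(factor(truth, lev), factor(predicted, lev))
  tp <- conf[positive, positive]
  fp <- sum(conf[, positive]) - tp
  fn <- sum(conf[positive, ]) - tp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  auc <- NA_real_; roc <- NULL
  if (!is.null(scores)) {
    pos <- truth == positive
    if (length(unique(pos)) < 2) {
      warning("single-class truth: AUC undefined")
    } else {
      roc <- roc_points(pos, scores)
      auc <- auc_trapezoid(roc)
    }
  }
  structure(
    list(confusion = unclass(conf), accuracy = sum(diag(conf)) / sum(conf),
         per_class = tibble::tibble(class = positive, precision = prec,
                                    recall = rec, f1 = f1),
         macro = tibble::tibble(precision = prec, recall = rec, f1 = f1),
         auc = auc, roc = roc, positive_class = positive, n = sum(conf),
         type = "binary"),
    class = "flim_metrics")
}

# ROC points over thresholds at the unique scores (internal)
roc_points <- function(pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; sc <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(sc, fromLast = TRUE)  # one point per distinct score
  tibble::tibble(
    threshold = c(Inf, sc[last]),
    tpr = c(0, tp[last] / sum(pos)),
    fpr = c(0, fp[last] / sum(!pos)))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Multi-class classification metrics (macro-averaged)
#'
#' Per-class one-vs-rest precision, recall and F1
#' (`F1 = 2 * P * R / (P + R)`), plus their unweighted (macro) means and the
#' overall accuracy. Classes absent from the truth have undefined recall and
#' are excluded from the macro averages with a warning. Micro averages are
#' available behind `micro = TRUE`.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param micro Also report micro-averaged precision/recall/F1.
#' @return A `flim_metrics` object.
#' @export
multiclass_metrics <- function(truth, predicted, micro = FALSE) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  lev <- sort(unique(c(truth, predicted)))
  conf <- table(factor(truth, lev), factor(predicted, lev))
  per <- purrr::map_dfr(lev, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (cl %in% truth) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  absent <- per$class[is.na(per$recall)]
  if (length(absent))
    warning(sprintf("class(es) absent from truth excluded from macro averages: %s",
                    paste(absent, collapse = ", ")))
  keep <- !is.na(per$recall)
  macro <- tibble::tibble(
    precision = mean(per$precision[keep], na.rm = TRUE),
    recall = mean(per$recall[keep]),
    f1 = mean(per$f1[keep], na.rm = TRUE))
  out <- list(confusion = unclass(conf),
              accuracy = sum(diag(conf)) / sum(conf),
              per_class = per, macro = macro, auc = NA_real_, roc = NULL,
              positive_class = NA_character_, n = sum(conf),
              type = "multiclass")
  if (micro) {
    tp <- sum(diag(conf))
    out$micro <- tibble::tibble(precision = tp / sum(conf),
                                recall = tp / sum(conf),
                                f1 = tp / sum(conf))
  }
  structure(out, class = "flim_metrics")
}

#' @export
print.flim_metrics <- function(x, ...) {
  cat(sprintf("<flim_metrics> %s, n = %d, accuracy %.3f", x$type, x$n,
              x$accuracy))
  if (!is.na(x$auc)) cat(sprintf(", AUC %.3f", x$auc))
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Tidy per-class metrics table
#' @param x A `flim_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per class.
#' @export
tidy.flim_metrics <- function(x, ...) x$per_class

#' One-row metrics summary
#' @param x A `flim_metrics` object.
#' @param ... Unused.
#' @return One-row tibble: accuracy, macro precision/recall/F1, AUC, n.
#' @export
glance.flim_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 precision = x$macro$precision, recall = x$macro$recall,
                 f1 = x$macro$f1, auc = x$auc, n = x$n)
}

#' Phenotype fractions of a predicted population
#'
#' Counts and percentages per predicted class (summing to 100), the format
#' used to report the metabolic composition of an unlabelled cell
#' population.
#'
#' @param predicted Vector of predicted labels.
#' @param levels Optional class levels to report (zero counts included).
#' @return Tibble: phenotype, n, percent.
#' @export
phenotype_fractions <- function(predicted, levels = NULL) {
  if (!length(predicted)) stop("no predictions", call. = FALSE)
  predicted <- as.character(predicted)
  lev <- levels %||% sort(unique(predicted))
  n <- as.integer(table(factor(predicted, lev)))
  tibble::tibble(phenotype = lev, n = n, percent = 100 * n / sum(n))
}

#' Two-dimensional t-SNE embedding of a feature matrix
#'
#' Projects high-dimensional per-cell features (for example 256 temporal
#' features, or the 64 learned activations of a trained network) onto two
#' dimensions with t-distributed stochastic neighbour embedding: Gaussian
#' input affinities calibrated to the target perplexity by bisection, a
#' Student-t low-dimensional kernel, early exaggeration and momentum
#' gradient descent from a PCA initialisation. Exact (non-approximate)
#' gradients; intended for the modest n used here.
#'
#' @param features n x d numeric matrix (n >= 5).
#' @param seed Integer seed.
#' @param perplexity Target perplexity (default 30, capped at `(n-1)/3`).
#' @param n_iter Gradient-descent iterations.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(features, seed = 1L, perplexity = 30, n_iter = 400L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 5) stop("need at least 5 rows for a t-SNE embedding", call. = FALSE)
  set.seed(seed)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(features))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- p / s
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (hi == 1e20) beta * 2 else (lo + hi) / 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA initialisation, scaled small
  pc <- stats::prcomp(features, rank. = 2)$x
  Y <- pc / stats::sd(pc[, 1]) * 1e-4
  G <- matrix(0, n, 2); gain <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 100) 0.5 else 0.8
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gain <- ifelse(sign(grad) != sign(G), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    G <- mom * G - 200 * gain * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}
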