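# Post-evaluation of clustering against ground-truth labels.
#
# Clusters carry arbitrary indices, so they are first aligned to truth
# classes by the optimal one-to-one assignment on the contingency table
# (Hungarian algorithm, maximizing total matched count); the confusion
# matrix and balanced accuracy are computed on the aligned labels.
# Orientation convention: truth classes on rows (y-axis), aligned
# predicted clusters on columns (x-axis).

# Jonker-Volgenant style shortest augmenting path; square cost matrix,
# minimization. Returns assignment col index per row.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Align predicted clusters to truth classes
#'
#' Finds the one-to-one assignment of predicted clusters to truth classes
#' that maximizes the total matched count (optimal assignment on the
#' contingency table). When there are more clusters than classes, surplus
#' clusters map to \code{NA} ("unassigned").
#'
#' @param truth,predicted equal-length label vectors.
#' @return named integer vector: names are cluster labels, values the
#'   assigned truth class (\code{NA} for unassigned). Attribute
#'   \code{"matched"} carries the total matched count.
#' @export
alignClusters <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("length mismatch between truth and predicted labels")
  if (!length(truth)) stop("empty label vectors")
  classes <- sort(unique(truth))
  clusters <- sort(unique(predicted))
  tab <- table(factor(predicted, levels = clusters),
               factor(truth, levels = classes))
  n <- max(length(clusters), length(classes))
  cost <- matrix(0, n, n)
  cost[seq_along(clusters), seq_along(classes)] <- -tab
  assign <- solveAssignment(cost)
  map <- rep(NA_integer_, length(clusters))
  for (r in seq_along(clusters)) {
    j <- assign[r]
    if (j <= length(classes)) map[r] <- classes[j]
  }
  names(map) <- as.character(clusters)
  matched <- sum(vapply(seq_along(clusters), function(r) {
    if (is.na(map[r])) 0L else as.integer(tab[r, as.character(map[r])])
  }, 0L))
  attr(map, "matched") <- matched
  map
}

#' Confusion matrix of truth classes vs aligned clusters
#'
#' Entry \code{(r, c)} counts cells with truth class \code{r} whose
#' cluster was aligned to class \code{c}; truth classes on rows, aligned
#' predictions on columns. Cells from unassigned (surplus) clusters are
#' counted in an extra \code{"unassigned"} column.
#'
#' @param truth,predicted equal-length label vectors.
#' @param alignment map from \code{\link{alignClusters}} (computed from
#'   the same label sets).
#' @return integer matrix with dimnames; row sums equal truth class sizes.
#' @export
confusionMatrixFrom <- function(truth, predicted, alignment) {
  if (length(truth) != length(predicted))
    stop("length mismatch between truth and predicted labels")
  if (any(!as.character(predicted) %in% names(alignment)))
    stop("predicted labels outside alignment domain")
  classes <- sort(unique(truth))
  aligned <- alignment[as.character(predicted)]
  hasUn <- any(is.na(aligned))
  colLv <- c(as.character(classes), if (hasUn) "unassigned")
  alignedChr <- ifelse(is.na(aligned), "unassigned", as.character(aligned))
  cm <- table(factor(truth, levels = classes),
              factor(alignedChr, levels = colLv))
  m <- matrix(as.integer(cm), nrow = nrow(cm),
              dimnames = dimnames(cm))
  m
}

cmDiag <- function(cm) {
  if (is.null(rownames(cm)) || is.null(colnames(cm))) {
    stopifnot(nrow(cm) <= ncol(cm))
    return(as.numeric(diag(cm)))
  }
  vapply(rownames(cm), function(cl)
    if (cl %in% colnames(cm)) as.numeric(cm[cl, cl]) else 0, numeric(1))
}

#' Balanced accuracy from a confusion matrix
#'
#' The arithmetic mean of class-specific accuracies,
#' \deqn{\bar\mu = \frac{1}{C}\sum_{i=1}^{C} \mu_i, \quad
#'   \mu_i = cm_{ii} / \sum_j cm_{ij},}
#' robust to class imbalance; equals plain accuracy when all classes have
#' the same size.
#'
#' @param cm confusion matrix (truth on rows), e.g. from
#'   \code{\link{confusionMatrixFrom}}.
#' @return scalar in \code{[0, 1]}.
#' @export
balancedAccuracy <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("empty truth class in confusion matrix")
  mean(cmDiag(cm) / rs)
}

#' Precision, recall, F1 and balanced accuracy report
#'
#' Per-class precision \code{cm[i,i]/colsum(i)}, recall
#' \code{cm[i,i]/rowsum(i)}, F1 their harmonic mean; macro (unweighted)
#' averages are reported, consistent with the balanced-accuracy
#' convention. Classes with a zero denominator score 0 with a warning.
#'
#' @param cm confusion matrix, truth classes on rows.
#' @return list with \code{balancedAccuracy}, \code{perClassAccuracy},
#'   \code{precision}, \code{recall}, \code{f1} (macro),
#'   \code{perClassPrecision}, \code{perClassRecall}, \code{perClassF1},
#'   \code{accuracy}, \code{nClasses}.
#' @export
classificationReport <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("empty truth class in confusion matrix")
  classes <- if (is.null(rownames(cm))) as.character(seq_len(nrow(cm)))
             else rownames(cm)
  d <- cmDiag(cm)
  cs <- if (is.null(rownames(cm)) || is.null(colnames(cm)))
    colSums(cm)[seq_len(nrow(cm))]
  else vapply(rownames(cm), function(cl)
    if (cl %in% colnames(cm)) sum(cm[, cl]) else 0, numeric(1))
  if (any(cs == 0))
    warning("class absent from predictions; precision set to 0 for: ",
            paste(classes[cs == 0], collapse = ", "))
  prec <- ifelse(cs > 0, d / cs, 0)
  rec <- d / rs
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(balancedAccuracy = mean(rec),
       perClassAccuracy = as.numeric(rec),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       perClassPrecision = as.numeric(prec),
       perClassRecall = as.numeric(rec),
       perClassF1 = as.numeric(f1),
       accuracy = sum(d) / sum(cm),
       nClasses = length(classes))
}

#' Evaluate a clustering against truth labels
#'
#' Convenience wrapper: align, build the confusion matrix, and report.
#'
#' @param truth,predicted equal-length label vectors.
#' @return list with \code{alignment}, \code{confusion} and all
#'   \code{\link{classificationReport}} fields.
#' @export
evaluateClustering <- function(truth, predicted) {
  al <- alignClusters(truth, predicted)
  cm <- confusionMatrixFrom(truth, predicted, al)
  rep <- classificationReport(cm)
  c(list(alignment = al, confusion = cm), rep)
}

#' Project latent codes to 2D for visualization
#'
#' Deterministic principal-component projection of the latent codes onto
#' their first two axes of variation, with component signs fixed so the
#' output is byte-reproducible. Used only for plotting, never for
#' clustering.
#'
#' @param latent cells-by-n matrix.
#' @param seed kept for interface stability; the projection is
#'   deterministic regardless.
#' @return cells-by-2 coordinate matrix.
#' @export
embedLatent2D <- function(latent, seed = 1L) {
  Z <- as.matrix(latent)
  if (nrow(Z) < 3L) stop("too few cells to embed (need >= 3)")
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  xy <- pc$x[, 1:2, drop = FALSE]
  if (ncol(xy) < 2L) xy <- cbind(xy, 0)  # degenerate rank-1 case
  colnames(xy) <- c("dim1", "dim2")
  xy
}
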