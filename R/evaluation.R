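#' Normalized mutual information against a ground-truth labelling
#'
#' Plug-in estimate from the empirical contingency table, normalized by the
#' entropy of the ground truth only: `NMI = I(pred; truth) / H(truth)`.
#' The log base cancels. No bias correction is applied. Degenerate case:
#' if the truth has a single class, returns 1 when the prediction is also
#' constant and 0 otherwise, with a warning.
#'
#' @param pred,truth equal-length label vectors (any atomic type).
#' @return NMI in `[0, 1]`.
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
nmi <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  n <- length(pred)
  if (n == 0L) stop("empty label vectors")
  tab <- table(pred, truth)
  pj <- colSums(tab) / n
  H <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (H == 0) {
    warning("ground truth has a single class; NMI is degenerate")
    return(if (length(unique(pred)) == 1L) 1 else 0)
  }
  pij <- tab / n
  pi_ <- rowSums(tab) / n
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj)[nz]))
  I / H
}

#' Score a segmentation against ground truth
#'
#' Builds the contingency table between the fit's hard labels and the true
#' components and computes NMI. Points left unassigned by the membership
#' threshold are excluded by default (their count is reported); with
#' `unassigned_policy = "own_class"` they are scored as one extra class.
#'
#' @param fit a `hidalgo_fit`, or a plain label vector with unassigned
#'   points coded by `unassigned_value`.
#' @param truth ground-truth labels.
#' @param unassigned_policy `"exclude"` (default) or `"own_class"`.
#' @param unassigned_value label value marking unassigned points
#'   (default 0, the fit encoding).
#' @return list with `contingency` (pred x truth counts over scored
#'   points), `nmi` (NA with a warning when no points can be scored) and
#'   `n_unassigned`.
#' @export
compare_labels <- function(fit, truth,
                           unassigned_policy = c("exclude", "own_class"),
                           unassigned_value = 0L) {
  unassigned_policy <- match.arg(unassigned_policy)
  pred <- if (inherits(fit, "hidalgo_fit")) fit$labels else fit
  if (length(pred) != length(truth))
    stop("prediction and truth must have equal length")
  un <- pred == unassigned_value
  n_unassigned <- sum(un)
  if (unassigned_policy == "exclude") {
    pred <- pred[!un]
    truth <- truth[!un]
  }
  if (length(pred) == 0L) {
    warning("no assigned points to score; NMI undefined")
    return(list(contingency = table(integer(0), integer(0)),
                nmi = NA_real_, n_unassigned = n_unassigned))
  }
  value <- if (length(unique(truth)) == 1L) {
    warning("scored points cover a single true class; NMI degenerate")
    if (length(unique(pred)) == 1L) 1 else 0
  } else nmi(pred, truth)
  list(contingency = table(pred, truth), nmi = value,
       n_unassigned = n_unassigned)
}

#' Match fitted components to true components by majority overlap
#'
#' For each true component, returns the fitted component holding the most
#' of its (assigned) points — the bookkeeping needed to compare posterior
#' dimensions with per-component ground truth.
#'
#' @param fit a `hidalgo_fit` or label vector (0 = unassigned).
#' @param truth ground-truth labels.
#' @return named integer vector: for each true class, the matched fitted
#'   component index.
#' @export
match_components <- function(fit, truth) {
  pred <- if (inherits(fit, "hidalgo_fit")) fit$labels else fit
  keep <- pred != 0L
  tab <- table(truth[keep], pred[keep])
  out <- apply(tab, 1L, function(row) as.integer(colnames(tab)[which.max(row)]))
  stats::setNames(as.integer(out), rownames(tab))
}
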