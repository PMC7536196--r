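#' Choose the number of manifolds by scanning K
#'
#' Fits the model for each K in `k_min..k_max` with identical sampler
#' settings and seeds and compares the mean retained log-posterior `L`,
#' which includes all K-dependent normalizing constants so values are
#' comparable across models. The selected K is the argmax of `L` (ties go
#' to the smaller K). An optional early-stop threshold `delta` stops the
#' scan once `L(K+1) - L(K) < delta`; it is off by default so the full,
#' reproducible scan is the reference behaviour.
#'
#' @param x data accepted by [hidalgo()] (coordinates, distances or a
#'   `neighbor_stats` object).
#' @param k_min,k_max scan range.
#' @param ... arguments to [hidalgo_config()] shared by every K
#'   (`threshold` is interpreted on the `1/K` scale and must be valid for
#'   all scanned K).
#' @param delta optional early-stop improvement threshold.
#' @param engine passed to [hidalgo()].
#' @return an object of class `hidalgo_kscan`: `K_values`, `L_values`,
#'   `K_best` and the per-K fits.
#' @export
scan_k <- function(x, k_min = 1L, k_max, ..., delta = NULL,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(k_max >= k_min, k_min >= 1L)
  if (!inherits(x, "neighbor_stats")) {
    cfg0 <- hidalgo_config(K = max(k_min, 2L), ...)
    x <- neighbor_stats(as.matrix(x), q = cfg0$q)
  }
  K_values <- integer(0)
  L_values <- numeric(0)
  fits <- list()
  for (K in seq(k_min, k_max)) {
    cfg <- hidalgo_config(K = K, ...)
    fit <- hidalgo(x, config = cfg, engine = engine)
    K_values <- c(K_values, K)
    L_values <- c(L_values, fit$L)
    fits[[as.character(K)]] <- fit
    nK <- length(L_values)
    if (!is.null(delta) && nK >= 2L &&
        L_values[nK] - L_values[nK - 1L] < delta) break
  }
  structure(list(K_values = K_values, L_values = L_values,
                 K_best = K_values[which.max(L_values)], fits = fits),
            class = "hidalgo_kscan")
}

#' @export
print.hidalgo_kscan <- function(x, ...) {
  cat("Model scan over the number of manifolds:\n")
  print(data.frame(K = x$K_values, L = x$L_values))
  cat("selected K =", x$K_best, "(argmax of mean retained log-posterior)\n")
  invisible(x)
}
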