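#' Read a delimited numeric matrix (coordinates or distances)
#'
#' Reads comma- or tab-delimited text with optional header. The delimiter
#' and the header row are auto-detected unless given (a header is assumed
#' when the first row contains non-numeric cells). With
#' `distances = TRUE` the table is validated as a distance matrix
#' (square, symmetric within 1e-9, zero diagonal) via
#' [validate_distances()].
#'
#' @param path file path.
#' @param delimiter `","`, `"\t"`, or `NULL` to auto-detect.
#' @param header `TRUE`/`FALSE`, or `NULL` to auto-detect.
#' @param distances validate as a distance matrix.
#' @return numeric matrix.
#' @export
read_matrix <- function(path, delimiter = NULL, header = NULL,
                        distances = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
                 else ""
  if (is.null(header)) {
    cells <- strsplit(first, if (delimiter == "") "[[:space:]]+" else
                      delimiter, fixed = (delimiter != ""))[[1]]
    header <- anyNA(suppressWarnings(as.numeric(cells)))
  }
  df <- read.table(path, sep = delimiter, header = header,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric column(s): ", paste(names(df)[bad], collapse = ", "))
  }
  if (anyNA(m)) stop("missing or unparsable cells in ", path)
  dimnames(m) <- NULL
  if (distances) m <- validate_distances(m)
  m
}

#' Write fit results, traces and a reproducibility manifest
#'
#' Writes into `outdir`: `labels.csv` (point id, hard label with 0 =
#' unassigned, maximum membership probability), `pi.csv` (N x K
#' membership probabilities), `summary.json` (posterior summaries,
#' configuration and seeds, 17 significant digits so floats round-trip),
#' `trace.csv` (per-sweep log-posterior of the best chain) and
#' `manifest.json` (configuration echo, chain seeds, package version,
#' optional input checksum, timestamp) — enough to re-run the fit
#' bit-identically.
#'
#' @param fit a `hidalgo_fit`.
#' @param outdir output directory (created if needed).
#' @param input_checksum optional checksum string recorded in the manifest.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(fit, outdir, input_checksum = NULL) {
  stopifnot(inherits(fit, "hidalgo_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- fit$config
  paths <- file.path(outdir, c("labels.csv", "pi.csv", "summary.json",
                               "trace.csv", "manifest.json"))
  labels_df <- data.frame(point_id = seq_len(fit$n), label = fit$labels,
                          pi_max = apply(fit$pi, 1L, max))
  write.csv(labels_df, paths[1], row.names = FALSE)
  pi_df <- as.data.frame(fit$pi)
  names(pi_df) <- paste0("pi_", seq_len(cfg$K))
  write.csv(pi_df, paths[2], row.names = FALSE)
  summary <- list(d_mean = fit$d_mean, d_sd = fit$d_sd, p_mean = fit$p_mean,
                  L = fit$L, best_chain = fit$best_chain,
                  n_unassigned = sum(fit$labels == 0L),
                  config = unclass(cfg),
                  chain_seeds = cfg$seed + seq_len(cfg$n_chains) - 1L)
  jsonlite::write_json(summary, paths[3], auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(sweep = seq_along(fit$trace$log_post),
                       log_post = fit$trace$log_post),
            paths[4], row.names = FALSE)
  manifest <- list(package = "hidalgo",
                   version = as.character(utils::packageVersion("hidalgo")),
                   config = unclass(cfg),
                   chain_seeds = cfg$seed + seq_len(cfg$n_chains) - 1L,
                   best_chain = fit$best_chain,
                   mean_log_post = fit$diagnostics$mean_log_post,
                   max_log_post = fit$diagnostics$max_log_post,
                   input_checksum = input_checksum,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paths[5], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
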