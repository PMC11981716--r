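#' Multi-start fit with consensus summarisation
#'
#' The recommended end-to-end workflow: fit the mixture `M` times from
#' independent random initialisations, assemble the co-clustering matrix,
#' extract a consensus partition and — when variable selection is on — a
#' consensus selected-variable set. Defaults follow the package
#' recommendation of at least 25 runs summarised by minimum expected VoI
#' with complete linkage and a 0.95 selection threshold. Run m uses seed
#' `base_seed + m`, so results are independent of the number of workers.
#'
#' @param data a `catmix_data` object.
#' @param K_init number of mixture components to initialise with; set it
#'   above the number of clusters you expect.
#' @param M number of independently initialised runs (default 25).
#' @param method consensus method: `"voi_complete"` (default),
#'   `"voi_average"` or `"medvedovic"`.
#' @param tau selection-proportion threshold (default 0.95).
#' @param alpha0,a,variable_selection hyperparameters, see [catmix_hyper()].
#' @param base_seed integer; run m uses `base_seed + m`.
#' @param n_workers forked parallel workers (serial results are identical).
#' @param tol,max_iter convergence controls passed to [catmix_fit()].
#' @param output_dir optional directory; when given, writes the consensus
#'   partition CSV, selection CSV, co-clustering CSV and a reproducibility
#'   manifest JSON.
#' @param keep_fits keep the full per-run fit objects (default FALSE; the
#'   per-run partitions, selections and ELBOs are always kept).
#' @return Object of class `catmix_avg`: list with `consensus`
#'   (`catmix_consensus`), `selection` (`catmix_selection` or NULL), `ccm`,
#'   `runs` (per-run summary data.frame), `partitions`, `selection_runs`,
#'   `config`, and optionally `fits`.
#' @export
run_avg_pipeline <- function(data, K_init, M = 25L,
                             method = c("voi_complete", "voi_average", "medvedovic"),
                             tau = 0.95, alpha0 = 0.01, a = 2,
                             variable_selection = FALSE,
                             base_seed = 1L, n_workers = 1L,
                             tol = 5e-8, max_iter = 2000L,
                             output_dir = NULL, keep_fits = FALSE) {
  stopifnot(inherits(data, "catmix_data"), M >= 1L)
  method <- match.arg(method)
  hyper <- catmix_hyper(K_init, alpha0 = alpha0, a = a,
                        variable_selection = variable_selection)
  seeds <- as.integer(base_seed) + seq_len(M)
  fits <- .run_fits(data, hyper, seeds, n_workers, tol, max_iter)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all runs failed", call. = FALSE)
  if (!all(ok))
    warning(sprintf("%d of %d runs failed and were excluded", sum(!ok), M),
            call. = FALSE)
  fits <- fits[ok]; seeds <- seeds[ok]

  partitions <- lapply(fits, `[[`, "map_partition")
  ccm <- coclustering_matrix(partitions)
  consensus <- .consensus_by_name(ccm, method, max_k = K_init)
  selection <- NULL
  selection_runs <- NULL
  if (variable_selection) {
    selection_runs <- do.call(rbind, lapply(fits, `[[`, "selected"))
    colnames(selection_runs) <- data$column_ids
    selection <- summarize_selection(selection_runs, tau)
  }
  runs <- data.frame(
    run = seq_along(fits), seed = seeds,
    n_nonempty = vapply(fits, `[[`, integer(1), "n_nonempty"),
    final_elbo = vapply(fits, `[[`, numeric(1), "final_elbo"),
    n_iter = vapply(fits, `[[`, integer(1), "n_iter"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  config <- list(K_init = as.integer(K_init), M = as.integer(M),
                 method = method, tau = tau, alpha0 = alpha0, a = a,
                 variable_selection = variable_selection,
                 base_seed = as.integer(base_seed), seeds = seeds,
                 tol = tol, max_iter = as.integer(max_iter))
  res <- structure(
    list(consensus = consensus, selection = selection, ccm = ccm,
         runs = runs, partitions = partitions,
         selection_runs = selection_runs, config = config,
         row_ids = data$row_ids, column_ids = data$column_ids),
    class = "catmix_avg")
  if (keep_fits) res$fits <- fits
  if (!is.null(output_dir)) write_avg_result(res, output_dir)
  res
}

#' @export
print.catmix_avg <- function(x, ...) {
  cat(sprintf("Consensus over %d runs (%s): %d clusters\n",
              nrow(x$runs), x$consensus$method, x$consensus$n_clusters))
  cat(sprintf("  per-run non-empty clusters: median %g (range %d-%d)\n",
              stats::median(x$runs$n_nonempty),
              min(x$runs$n_nonempty), max(x$runs$n_nonempty)))
  if (!is.null(x$selection))
    cat(sprintf("  consensus selected variables: %d / %d (tau = %g)\n",
                sum(x$selection$selected), length(x$selection$selected),
                x$selection$tau))
  invisible(x)
}

#' Write a single fit to disk
#'
#' Serialises a fit as a partition CSV (`row_id, cluster`), a selection CSV
#' (`column_id, c, selected`) and a run-metadata JSON (seed,
#' hyperparameters, ELBO trace, iterations, convergence flag).
#'
#' @param fit a `catmix_fit` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default `"fit"`.
#' @return Invisibly, the paths written.
#' @export
write_fit_result <- function(fit, dir, prefix = "fit") {
  stopifnot(inherits(fit, "catmix_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    partition = file.path(dir, paste0(prefix, "_partition.csv")),
    selection = file.path(dir, paste0(prefix, "_selection.csv")),
    metadata  = file.path(dir, paste0(prefix, "_metadata.json")))
  utils::write.csv(
    data.frame(row_id = fit$row_ids, cluster = fit$map_partition),
    paths["partition"], row.names = FALSE)
  utils::write.csv(
    data.frame(column_id = fit$column_ids, c = fit$c, selected = fit$selected),
    paths["selection"], row.names = FALSE)
  meta <- list(seed = fit$seed,
               hyperparameters = list(K = fit$hyper$K, alpha0 = fit$hyper$alpha0,
                                      a = fit$hyper$a,
                                      variable_selection = fit$hyper$variable_selection),
               n_nonempty = fit$n_nonempty, final_elbo = fit$final_elbo,
               elbo_trace = fit$elbo_trace, n_iter = fit$n_iter,
               converged = fit$converged)
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a consensus (model-averaged) result to disk
#'
#' Writes the consensus partition CSV, the selection summary CSV (when
#' variable selection was on), the dense co-clustering matrix CSV, and a
#' reproducibility manifest JSON (configuration echo, per-run seeds,
#' package and R versions) from which the analysis can be regenerated.
#'
#' @param res a `catmix_avg` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_avg_result <- function(res, dir) {
  stopifnot(inherits(res, "catmix_avg"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(partition = file.path(dir, "consensus_partition.csv"),
             ccm = file.path(dir, "coclustering.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(
    data.frame(row_id = res$row_ids, cluster = res$consensus$partition),
    paths["partition"], row.names = FALSE)
  ccm <- as.data.frame(res$ccm$P)
  names(ccm) <- res$row_ids
  utils::write.csv(cbind(row_id = res$row_ids, ccm), paths["ccm"],
                   row.names = FALSE)
  if (!is.null(res$selection)) {
    paths["selection"] <- file.path(dir, "consensus_selection.csv")
    utils::write.csv(
      data.frame(column_id = res$column_ids,
                 proportion = res$selection$proportions,
                 selected = res$selection$selected),
      paths["selection"], row.names = FALSE)
  }
  manifest <- list(
    config = res$config,
    consensus = list(method = res$consensus$method,
                     n_clusters = res$consensus$n_clusters,
                     score = res$consensus$score),
    runs = res$runs,
    versions = list(package = as.character(utils::packageVersion("catmixvi")),
                    R = R.version.string))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
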