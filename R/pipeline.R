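# End-to-end pipeline: declarative run configuration, execution, series and
# partition I/O, and the small built-in fixtures.

#' Series and partition I/O
#'
#' Time series travel as plain CSV, one row per sample and one column per
#' coordinate (header optional). Partitions are saved as small JSON
#' sidecars (bounds and per-dimension counts) so a symbolization can be
#' reproduced exactly, e.g. across noise levels.
#'
#' @param series a `tm_series` (or numeric vector / matrix).
#' @param path file path.
#' @param header write / expect a header row.
#' @return Readers return the stored object; writers return `path`
#'   invisibly.
#' @export
write_series_csv <- function(series, path, header = TRUE) {
  v <- series_values(series)
  colnames(v) <- paste0("x", seq_len(ncol(v)))
  utils::write.table(v, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path, header = NA) {
  first <- readLines(path, n = 1L)
  if (is.na(header)) {
    header <- anyNA(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]])))
  }
  v <- as.matrix(utils::read.csv(path, header = header))
  if (!is.numeric(v)) stop("non-numeric values in series CSV")
  tm_series(v, meta = list(generator = "file", path = path))
}

#' @rdname write_series_csv
#' @param part a `tm_partition`.
#' @export
write_partition_json <- function(part, path) {
  jsonlite::write_json(list(lower = part$lower, upper = part$upper,
                            counts = part$counts),
                       path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_partition_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lower = as.numeric(p$lower), upper = as.numeric(p$upper),
                 counts = as.integer(p$counts), m = length(p$counts),
                 n_cells = prod(as.integer(p$counts))),
            class = "tm_partition")
}

#' Run configuration
#'
#' Collects everything needed to replay an analysis exactly: the signal
#' source (a named generator or an input CSV), its parameters, the
#' embedding, the partition, and the memory / betweenness options. The
#' `"ecg"` preset carries the settings intended for short physiological
#' recordings (m = 2, l = 15, N = 300) and requires an `input` file.
#'
#' @param system one of `"logistic"`, `"henon"`, `"ikeda"`, `"rossler"`,
#'   `"ar3"`, `"white"`, `"pink"`, `"file"`, or `"ecg"`.
#' @param n,n_transient samples kept / discarded (generators only).
#' @param seed master seed; stage seeds are derived from it.
#' @param m,l embedding dimension and delay (scalar sources; `m = 1` means
#'   symbolize the raw scalar series, the default for white / 1/f noise).
#' @param n_cells,per_dim partition size (total budget or per dimension).
#' @param tau_max,mode,h_floor,tau_fit_max,window memory-entropy options
#'   (see [fit_memory_exponent()]).
#' @param betweenness also compute the betweenness-preference distribution.
#' @param params extra generator parameters (e.g. `list(mu = 3.9)`).
#' @param input CSV path for `system = "file"` / `"ecg"`.
#' @return A list of class `tm_run_config`.
#' @export
run_config <- function(system, n = 2e4, n_transient = 4000, seed = 1,
                       m = NULL, l = NULL, n_cells = NULL, per_dim = NULL,
                       tau_max = 16, mode = "overlapping", h_floor = 1e-12,
                       tau_fit_max = 6, window = "scaling",
                       betweenness = FALSE, params = list(), input = NULL) {
  defaults <- list(
    logistic = list(m = 2, l = 1, n_cells = 900),
    henon    = list(m = 1, l = 1, n_cells = 2500),
    ikeda    = list(m = 1, l = 1, n_cells = 1600),
    rossler  = list(m = 1, l = 1, per_dim = c(5, 5, 4)),
    ar3      = list(m = 1, l = 1, n_cells = 100),
    white    = list(m = 1, l = 1, n_cells = 100),
    pink     = list(m = 1, l = 1, n_cells = 100),
    file     = list(m = 2, l = 1, n_cells = 900),
    ecg      = list(m = 2, l = 15, n_cells = 300)
  )
  if (!system %in% names(defaults)) {
    stop("unknown system: ", system)
  }
  d <- defaults[[system]]
  cfg <- list(system = system, n = n, n_transient = n_transient, seed = seed,
              m = if (is.null(m)) d$m else m,
              l = if (is.null(l)) d$l else l,
              n_cells = if (is.null(n_cells) && is.null(per_dim)) d$n_cells else n_cells,
              per_dim = if (is.null(per_dim)) d$per_dim else per_dim,
              tau_max = tau_max, mode = mode, h_floor = h_floor,
              tau_fit_max = tau_fit_max, window = window,
              betweenness = betweenness, params = params, input = input)
  if (system %in% c("file", "ecg") && is.null(input)) {
    stop(sprintf('system = "%s" requires an input CSV', system))
  }
  class(cfg) <- "tm_run_config"
  cfg
}

generate_from_config <- function(cfg) {
  p <- cfg$params
  seed <- derive_seed(cfg$seed, 0L)
  switch(cfg$system,
    logistic = do.call(gen_logistic, c(list(n = cfg$n, n_transient = cfg$n_transient,
                                            seed = seed), p)),
    henon = do.call(gen_henon, c(list(n = cfg$n, n_transient = cfg$n_transient,
                                      seed = seed), p)),
    ikeda = do.call(gen_ikeda, c(list(n = cfg$n, n_transient = cfg$n_transient,
                                      seed = seed), p)),
    rossler = do.call(gen_rossler, c(list(n_samples = cfg$n, seed = seed), p)),
    ar3 = do.call(gen_ar3, c(list(n = cfg$n, n_transient = cfg$n_transient,
                                  seed = seed), p)),
    white = gen_white_noise(cfg$n, seed = seed),
    pink = gen_pink_noise(cfg$n, seed = seed),
    file = ,
    ecg = read_series_csv(cfg$input),
    stop("unknown system: ", cfg$system)
  )
}

#' Run the full analysis pipeline
#'
#' Executes generate (or read) -> embed -> partition -> temporal network ->
#' entropy profile and memory-exponent fit, plus optionally the
#' betweenness-preference distribution and spatial map. With `out_dir` the
#' run writes its outputs as TSV (edges, profile, fit, betweenness), the
#' partition JSON sidecar, and the effective configuration JSON, so the run
#' can be replayed exactly.
#'
#' @param cfg a `tm_run_config`.
#' @param out_dir optional output directory (created if missing).
#' @return A list with `series`, `trajectory`, `partition`, `network`,
#'   `profile`, `fit`, and (when requested) `betweenness` and
#'   `spatial_map`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stage <- "generate"
  result <- tryCatch({
    series <- generate_from_config(cfg)
    stage <- "embed"
    v <- series_values(series)
    traj <- if (ncol(v) == 1L && cfg$m > 1) delay_embed(v[, 1L], cfg$m, cfg$l)
            else tm_trajectory(v, source = "raw")
    stage <- "partition"
    part <- fit_grid(traj, n_cells = cfg$n_cells, per_dim = cfg$per_dim)
    stage <- "network"
    gt <- temporal_network(symbolize(traj, part))
    stage <- "entropy"
    prof <- entropy_profile(gt, tau_max = cfg$tau_max, mode = cfg$mode)
    fit <- fit_memory_exponent(prof, h_floor = cfg$h_floor,
                               tau_fit_max = cfg$tau_fit_max,
                               window = cfg$window)
    out <- list(series = series, trajectory = traj, partition = part,
                network = gt, profile = prof, fit = fit)
    if (isTRUE(cfg$betweenness)) {
      stage <- "betweenness"
      out$betweenness <- bp_distribution(gt)
      out$spatial_map <- bp_spatial_map(out$betweenness, part)
    }
    out
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_temporal_edges(result$network, file.path(out_dir, "edges.tsv"))
    utils::write.table(result$profile, file.path(out_dir, "profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(rho = result$fit$rho, intercept = result$fit$intercept,
                 r_squared = result$fit$r_squared),
      file.path(out_dir, "fit.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_partition_json(result$partition, file.path(out_dir, "partition.json"))
    if (!is.null(result$betweenness)) {
      utils::write.table(cbind(result$spatial_map,
                               node = result$betweenness$node),
                         file.path(out_dir, "betweenness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cfg_out <- cfg
    class(cfg_out) <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' Built-in toy fixtures
#'
#' Writes the 8-cell schematic example (a symbol sequence hopping through
#' cells labelled a..h, with the transition c -> e at t = 1 followed by
#' e -> d at t = 2) together with its temporal network, aggregate network
#' and one-step memory network as TSV, plus tiny seeded samples of each
#' generator as CSV. Regeneration is deterministic, hence byte-identical.
#'
#' @param outdir writable directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  toy <- c("c", "e", "d", "a", "b", "f", "g", "h", "e")
  writeLines(c("symbol", toy), file.path(outdir, "toy_symbols.csv"))
  gt <- temporal_network(toy)
  write_temporal_edges(gt, file.path(outdir, "toy_temporal_edges.tsv"))
  g0 <- aggregate_network(gt)
  utils::write.table(g0$edges, file.path(outdir, "toy_aggregate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g1 <- memory_network(gt, tau = 1)
  e1 <- data.frame(
    from = apply(g1$paths[g1$edges$from, , drop = FALSE], 1L, paste, collapse = "-"),
    to = apply(g1$paths[g1$edges$to, , drop = FALSE], 1L, paste, collapse = "-"),
    weight = g1$edges$weight)
  utils::write.table(e1, file.path(outdir, "toy_memory1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_series_csv(gen_logistic(200, seed = 7), file.path(outdir, "sample_logistic.csv"))
  write_series_csv(gen_henon(200, seed = 7), file.path(outdir, "sample_henon.csv"))
  write_series_csv(gen_white_noise(200, seed = 7), file.path(outdir, "sample_white.csv"))
  invisible(list.files(outdir, full.names = TRUE))
}
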