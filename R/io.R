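# Plain-text formats and the pipeline driver. Signals are stored channels-as-
# rows (the EEG convention: P channels, long T), first column channel label,
# header row of sample indices; distances as labelled square CSV; diagrams as
# dimension/birth/death CSV with the literal "inf" for infinite deaths;
# landscapes as t + one column per layer with the ceiling recorded in a
# leading comment line.

#' Read a multichannel signal matrix
#'
#' Delimited text with channel labels in the first column and one row per
#' channel. CRLF and LF endings are both accepted. A shape heuristic warns
#' when there are fewer samples than channels, the signature of a transposed
#' file.
#'
#' @param path file path.
#' @return numeric matrix, channels in rows, with channel labels as rownames.
#' @export
read_signals <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels))
    stop(sprintf("duplicate channel label: '%s'",
                 labels[duplicated(labels)][1]))
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (any(is.na(num) & !is.na(as.matrix(body))) || any(is.na(num)))
    stop("non-numeric cells in signal body")
  m <- matrix(as.numeric(num), nrow = nrow(df))
  rownames(m) <- labels
  if (ncol(m) < nrow(m))
    warning("fewer samples than channels: is the file transposed?")
  m
}

#' Write a multichannel signal matrix
#'
#' Inverse of [read_signals()]; optionally records the sampling rate in a
#' JSON sidecar `<path>.json`.
#'
#' @param x channels-by-time matrix (rownames used as labels) or a
#'   `simulated_series`.
#' @param path output file path.
#' @param sampling_rate optional Hz, written to the sidecar.
#' @export
write_signals <- function(x, path, sampling_rate = NULL) {
  if (inherits(x, "simulated_series")) {
    if (is.null(sampling_rate)) sampling_rate <- x$sampling_rate
    x <- x$data
  }
  labels <- rownames(x) %||% sprintf("ch%d", seq_len(nrow(x)))
  df <- data.frame(channel = labels, x, check.names = FALSE)
  colnames(df) <- c("channel", seq_len(ncol(x)))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(sampling_rate))
    jsonlite::write_json(list(sampling_rate = sampling_rate),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write / read a persistence diagram as CSV
#'
#' Columns `dimension,birth,death`; infinite deaths are stored as the
#' literal `inf`.
#'
#' @param pd a `persistence_diagram`.
#' @param path file path.
#' @export
write_diagram <- function(pd, path) {
  out <- data.frame(dimension = pd$dimension, birth = pd$birth,
                    death = ifelse(is.finite(pd$death),
                                   as.character(pd$death), "inf"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$death <- ifelse(df$death == "inf", Inf,
                     suppressWarnings(as.numeric(df$death)))
  structure(data.frame(dimension = as.integer(df$dimension),
                       birth = as.numeric(df$birth), death = df$death),
            class = c("persistence_diagram", "data.frame"))
}

#' Write / read a persistence landscape as CSV
#'
#' First column is the scale grid `t`, then one column per layer; the
#' ceiling and homology dimension are kept in a leading `#` comment line.
#'
#' @param l a [landscape()].
#' @param path file path.
#' @export
write_landscape <- function(l, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ceiling=%.17g dimension=%d", l$ceiling, l$dimension),
             con)
  df <- data.frame(t = l$grid, l$values)
  colnames(df) <- c("t", sprintf("lambda%d", seq_len(ncol(l$values))))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("ceiling=([0-9.eE+-]+) dimension=([0-9]+)",
                             header))[[1]]
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(grid = df$t,
                 values = as.matrix(df[, -1, drop = FALSE]),
                 dimension = as.integer(meta[3]),
                 layers = ncol(df) - 1L,
                 ceiling = as.numeric(meta[2])),
            class = "persistence_landscape")
}

#' Validate a pipeline configuration
#'
#' Checks every numeric field of the configuration list against the
#' preconditions of the stage that consumes it and fills in defaults.
#'
#' @param config named list; recognised fields: `sampling_rate`, `band`
#'   (name or `c(low, high)`), `span`, `max_hom_dim`, `layers`, `grid_size`,
#'   `ceiling`, `B`, `alpha`, `seed`.
#' @return the completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(band = "alpha", span = 9, max_hom_dim = 1, layers = 5,
                   grid_size = 256, ceiling = 1, B = 999, alpha = 0.05,
                   seed = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$sampling_rate) || config$sampling_rate <= 0)
    stop("`sampling_rate` (Hz, > 0) is required")
  if (is.character(config$band)) config$band <- band_presets(config$band)
  if (length(config$band) != 2 || config$band[1] >= config$band[2])
    stop("`band` must name a preset or give c(low, high) with low < high")
  if (config$span %% 2 == 0 || config$span < 3)
    stop("`span` must be odd and >= 3")
  if (!config$max_hom_dim %in% 0:2) stop("`max_hom_dim` must be in 0..2")
  if (config$grid_size < 2) stop("`grid_size` must be >= 2")
  if (config$ceiling <= 0) stop("`ceiling` must be > 0")
  if (config$B < 100) stop("`B` must be >= 100")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  config$seed <- as.integer(config$seed)
  config
}

#' Run the full two-group topology pipeline
#'
#' Per subject: band coherence, dependence distance, Vietoris-Rips
#' persistence, landscapes for each homology dimension up to
#' `max_hom_dim`; per group and dimension: mean landscape; per dimension:
#' permutation test on the landscape discrepancy. When `out_dir` is given,
#' every artifact is written (distances, diagrams, landscapes as CSV;
#' results and a manifest with seeds and parameters as JSON), making runs
#' reproducible and the stages individually inspectable.
#'
#' @param config a [pipeline_config()] list (or raw list, validated here).
#' @param group1,group2 lists of subject signal matrices or
#'   `simulated_series`.
#' @param out_dir optional output directory.
#' @return invisibly, a list with per-subject `distances`, `diagrams`,
#'   `landscapes`, per-group `mean_landscapes`, and per-dimension `tests`.
#' @export
run_pipeline <- function(config, group1, group2, out_dir = NULL) {
  config <- pipeline_config(config)
  dims <- 0:config$max_hom_dim
  groups <- list(group1 = group1, group2 = group2)
  distances <- diagrams <- landscapes <- list()
  for (g in names(groups)) {
    distances[[g]] <- lapply(groups[[g]], function(x)
      coherence_distance(x, config$band, config$sampling_rate,
                         span = config$span))
    diagrams[[g]] <- lapply(distances[[g]], vr_diagram,
                            max_hom_dim = config$max_hom_dim)
    landscapes[[g]] <- lapply(diagrams[[g]], function(pd)
      lapply(stats::setNames(dims, paste0("dim", dims)), function(k)
        landscape(pd, dimension = k, layers = config$layers,
                  grid_size = config$grid_size, ceiling = config$ceiling)))
  }
  mean_landscapes <- lapply(landscapes, function(subj)
    lapply(stats::setNames(paste0("dim", dims), paste0("dim", dims)),
           function(kname) mean_landscape(lapply(subj, `[[`, kname))))
  tests <- lapply(stats::setNames(dims, paste0("dim", dims)), function(k) {
    kname <- paste0("dim", k)
    permutation_test(lapply(landscapes$group1, `[[`, kname),
                     lapply(landscapes$group2, `[[`, kname),
                     B = config$B, alpha = config$alpha,
                     seed = config$seed + k)
  })
  bundle <- list(config = config, distances = distances,
                 diagrams = diagrams, landscapes = landscapes,
                 mean_landscapes = mean_landscapes, tests = tests)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  invisible(bundle)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  manifest <- list(parameters = cfg, artifacts = list())
  add <- function(rel) manifest$artifacts[[length(manifest$artifacts) + 1]] <<- rel
  for (g in names(bundle$distances)) {
    for (i in seq_along(bundle$distances[[g]])) {
      fd <- sprintf("dist_%s_%02d.csv", g, i)
      utils::write.csv(as.data.frame(unclass(bundle$distances[[g]][[i]])),
                       file.path(out_dir, fd), row.names = FALSE)
      add(fd)
      fp <- sprintf("pd_%s_%02d.csv", g, i)
      write_diagram(bundle$diagrams[[g]][[i]], file.path(out_dir, fp))
      add(fp)
      for (kname in names(bundle$landscapes[[g]][[i]])) {
        fl <- sprintf("pl_%s_%02d_%s.csv", g, i, kname)
        write_landscape(bundle$landscapes[[g]][[i]][[kname]],
                        file.path(out_dir, fl))
        add(fl)
      }
    }
    for (kname in names(bundle$mean_landscapes[[g]])) {
      fm <- sprintf("pl_mean_%s_%s.csv", g, kname)
      write_landscape(bundle$mean_landscapes[[g]][[kname]],
                      file.path(out_dir, fm))
      add(fm)
    }
  }
  results <- lapply(bundle$tests, function(tt)
    list(observed = tt$observed, p_value = tt$p_value,
         threshold = tt$threshold, reject = tt$reject, B = tt$B,
         alpha = tt$alpha, n1 = tt$n1, n2 = tt$n2,
         enumerated = tt$enumerated,
         null_samples = tt$null_samples))
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("results.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
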