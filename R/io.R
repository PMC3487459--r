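#' Central run configuration
#'
#' One place holding every model parameter with its default, validated at
#' construction. The numeric defaults of the standard parameter set
#' (`L = 4`, `s = 0.05`, `eps = 1`, `mu = 1e-5`, `r = 0.05`, deterministic
#' fixation threshold 0.99, stochastic threshold 0.95, `n_reps = 50`) are
#' inferred defaults: midpoints of the published parameter sweeps.
#'
#' @param ... overrides of any default (unknown names are rejected).
#' @return list of class `run_config` with entries `L`, `s`, `eps`, `mu`,
#'   `r`, `fixation_threshold`, `stoch_fixation_threshold`, `B`, `N0`,
#'   `n_reps`, `tau_leap_threshold`, `tau_eps`, `t_max`, `rate_convention`,
#'   `seed`, `out_dir`.
#' @export
run_config <- function(...) {
  defaults <- list(
    L = 4L, s = 0.05, eps = 1.0, mu = 1e-5, r = 0.05,
    fixation_threshold = 0.99, stoch_fixation_threshold = 0.95,
    B = 1, N0 = 1e4, n_reps = 50L,
    tau_leap_threshold = 100, tau_eps = 0.03,
    t_max = 1e6, rate_convention = "total",
    seed = 1L, out_dir = "."
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides)[1])) overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$L < 2) stop("L must be >= 2", call. = FALSE)
  if (cfg$s <= 0) stop("s must be positive", call. = FALSE)
  if (cfg$eps <= 0) stop("eps must be positive", call. = FALSE)
  if (cfg$s * cfg$L^cfg$eps > 1)
    stop(sprintf("invalid landscape: s * L^eps = %.4g > 1 gives a negative fitness at k = L",
                 cfg$s * cfg$L^cfg$eps), call. = FALSE)
  if (cfg$mu < 0 || cfg$r < 0) stop("rates must be >= 0", call. = FALSE)
  for (nm in c("fixation_threshold", "stoch_fixation_threshold")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(nm, " must lie in (0, 1)", call. = FALSE)
  }
  if (!cfg$rate_convention %in% c("total", "per_locus"))
    stop("rate_convention must be 'total' or 'per_locus'", call. = FALSE)
  if (cfg$N0 < 2 || cfg$B <= 0 || cfg$n_reps < 1)
    stop("invalid stochastic parameters", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from a JSON/YAML-style file
#'
#' Reads a JSON file of `key: value` pairs and merges it over the defaults;
#' `overrides` (e.g. parsed command-line flags) win over the file. Unknown
#' keys are rejected.
#'
#' @param path path to a JSON config file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return a validated [run_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  vals <- utils::modifyList(vals, overrides)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a fitness topography as JSON
#'
#' File schema: `{"L": int, "lfgs": ["0101", ...]}` with genotypes as binary
#' strings (most significant locus first).
#'
#' @param topography a [fitness_topography()].
#' @param path output/input file path.
#' @return `read_topography()` returns a [fitness_topography()];
#'   `write_topography()` returns `path` invisibly.
#' @export
write_topography <- function(topography, path) {
  jsonlite::write_json(
    list(L = topography$L,
         lfgs = genotype_string(topography$lfgs, topography$L)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fitness_topography(obj$L, as.character(obj$lfgs %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a fitness landscape as TSV
#'
#' Columns: `genotype`, `k`, `is_lfg`, `m`.
#'
#' @param landscape a [build_landscape()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(as.data.frame(landscape), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table with a JSON manifest sidecar
#'
#' The table goes to `<path>` as TSV; the manifest (all parameters needed to
#' re-run the screen) to `<path>.manifest.json`.
#'
#' @param results data.frame of screen results.
#' @param path output TSV path.
#' @param manifest named list echoed verbatim into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, manifest = list()) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  manifest$n_rows <- nrow(results)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA)
}

#' Generate the packaged small test inputs
#'
#' Writes, under `dir`: the canonical two-locus quartet of topographies
#' (`l2_*.json`; its three locus-permutation classes are the complete
#' two-locus classification), a seeded sample of four-locus topographies with
#' 3, 5 and 7 LFGs (`l4_sample_<k>lfg_<i>.json`), and a tiny parameter grid
#' (`param_grid.tsv`). Byte-stable under a fixed seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the four-locus sample.
#' @param n_per_count sampled topographies per LFG count (default 5).
#' @return character vector of the written file paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, n_per_count = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  l2 <- enumerate_topographies(2, 2)
  for (i in seq_along(l2)) {
    p <- file.path(dir, sprintf("l2_topography_%d.json", i))
    write_topography(l2[[i]], p)
    paths <- c(paths, p)
  }
  counts <- c(3, 5, 7)
  seeds <- derive_seeds(seed, length(counts))
  for (ci in seq_along(counts)) {
    sampled <- sample_topographies(4, counts[ci], n_per_count, seed = seeds[ci])
    for (i in seq_along(sampled)) {
      p <- file.path(dir, sprintf("l4_sample_%dlfg_%d.json", counts[ci], i))
      write_topography(sampled[[i]], p)
      paths <- c(paths, p)
    }
  }
  grid <- standard_param_grid(r = c(0.01, 0.05, 0.1))
  gp <- file.path(dir, "param_grid.tsv")
  utils::write.table(grid, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, gp)
  invisible(paths)
}
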