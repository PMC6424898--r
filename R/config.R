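# Run configuration, defaults and hyperparameter grids.

#' Default run configuration
#'
#' The defaults every command starts from: Louvain resistance 0.1, MCL
#' inflation 2 (expansion 2), perturbation drop fraction 0.01 over 100
#' iterations, PPR teleport 0.85 at push tolerance 1e-5, module size
#' range 3-100, core size 60 with trigger 100, p-value cutoff 1e-4, 5%
#' FDR, consensus threshold 0.5, comorbidity top fraction 0.5.
#'
#' @return a named list of default parameter values.
#' @export
coremod_defaults <- function() {
  list(resistance = 0.1, inflation = 2, expansion = 2,
       drop_frac = 0.01, iterations = 100,
       alpha = 0.85, eps = 1e-5,
       max_size = 100, min_size = 3,
       core_size = 60, size_trigger = 100,
       pvalue_cutoff = 1e-4, fdr = 0.05,
       threshold = 0.5, top_frac = 0.5,
       seed = NULL)
}

#' Load / echo a YAML run configuration
#'
#' `load_config()` reads a YAML file, rejects unknown keys (listing the
#' valid ones) and fills unset keys with [coremod_defaults()]; an empty or
#' missing-key file yields the defaults. `echo_config()` writes the fully
#' resolved configuration plus the package version next to a run's
#' outputs, for provenance; `load_config()` silently drops the `version`
#' field so `load_config(echo_config(cfg))` round-trips.
#'
#' @param path a YAML file path.
#' @param cfg a configuration list.
#' @return `load_config()`: the resolved configuration list;
#'   `echo_config()`: `path`, invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw$version <- NULL
  defaults <- coremod_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, raw)
}

#' @rdname load_config
#' @export
echo_config <- function(cfg, path) {
  cfg$version <- as.character(utils::packageVersion("coremod"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Cartesian hyperparameter grid
#'
#' Expands named parameter ranges into a list of configurations, one per
#' combination.
#'
#' @param ranges a named list of non-empty vectors.
#' @return a list of named lists.
#' @export
config_grid <- function(ranges) {
  if (length(ranges) == 0 || any(lengths(ranges) == 0)) {
    stop("every range must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(ranges, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
}

#' Default baseline hyperparameter grids
#'
#' `mcl_grid()` is inflation 2..9 at intervals of 1 (8 configurations);
#' `louvain_grid()` is resistance 0.1..1 at intervals of 0.1 (10
#' configurations); CEIL has no hyperparameter. `baseline_runs()` is the
#' full set of base runs the ensemble uses by default: every baseline
#' method at every grid point (10 + 8 + 1 = 19 runs).
#'
#' @return `mcl_grid()`, `louvain_grid()`: lists of configs;
#'   `baseline_runs()`: a list of base-run configs, each with a `method`
#'   field.
#' @export
mcl_grid <- function() config_grid(list(inflation = 2:9))

#' @rdname mcl_grid
#' @export
louvain_grid <- function() config_grid(list(resistance = seq(0.1, 1, by = 0.1)))

#' @rdname mcl_grid
#' @export
baseline_runs <- function() {
  c(lapply(louvain_grid(), function(x) c(list(method = "louvain"), x)),
    lapply(mcl_grid(), function(x) c(list(method = "mcl"), x)),
    list(list(method = "ceil")))
}
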