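# Serialization: JSON containers for meshes, chains and models, CSV for
# metric tables, YAML/JSON walker configs, and the run manifest.

schema_version <- "1"

json_write <- function(x, path) {
  # I(17) = 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
}

json_read <- function(path, what) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("cannot read %s from '%s': %s", what, path,
                                 conditionMessage(e)), call. = FALSE))
  if (!identical(as.character(obj$schema), schema_version))
    stop(sprintf(
      "schema version mismatch in '%s': found %s, this package reads %s",
      path, deparse(obj$schema), schema_version), call. = FALSE)
  obj
}

#' Read or write a walker configuration file
#'
#' Configs round-trip through YAML or JSON (by file extension).
#'
#' @param config A [walker_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_walker_config` returns `path` invisibly;
#'   `read_walker_config` returns a `walker_config`.
#' @export
write_walker_config <- function(config, path) {
  stopifnot(inherits(config, "walker_config"))
  keep <- c("state_dim", "fixed_point", "fail_bound", "grid_half_n",
            "noise_sd", "timing", "g", "nominal_step_length",
            "nominal_step_duration", "sens_state", "sens_pert", "family",
            "seed")
  obj <- config[keep]
  obj$a <- as.numeric(config$a)
  obj$b <- config$b
  obj$pert_min <- min(config$pert_grid)
  obj$pert_max <- max(config$pert_grid)
  obj$pert_spacing <- config$pert_grid[2] - config$pert_grid[1]
  obj$pert_grid <- config$pert_grid  # verbatim, for exact reconstruction
  obj$spatio_gain <- as.list(config$spatio_gain)
  if (grepl("\\.ya?ml$", path))
    writeLines(yaml::as.yaml(obj, precision = 17L), path)
  else json_write(c(list(schema = schema_version), obj), path)
  invisible(path)
}

#' @rdname write_walker_config
#' @export
read_walker_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else json_read(path, "walker config")
  cfg <- walker_config(
    state_dim = obj$state_dim, a = unlist(obj$a), b = unlist(obj$b),
    fixed_point = unlist(obj$fixed_point),
    fail_bound = unlist(obj$fail_bound),
    grid_half_n = obj$grid_half_n, pert_min = obj$pert_min,
    pert_max = obj$pert_max, pert_spacing = obj$pert_spacing,
    noise_sd = obj$noise_sd, timing = obj$timing, g = obj$g,
    nominal_step_length = obj$nominal_step_length,
    nominal_step_duration = obj$nominal_step_duration,
    sens_state = obj$sens_state, sens_pert = obj$sens_pert,
    spatio_gain = unlist(obj$spatio_gain), family = obj$family,
    seed = obj$seed)
  if (!is.null(obj$pert_grid))
    cfg$pert_grid <- as.numeric(unlist(obj$pert_grid))
  cfg
}

#' Save or load a deterministic mesh
#'
#' JSON container holding the state grid, the transition table, the
#' representative perturbations and the generating config; values at full
#' precision.
#'
#' @param mesh A `deterministic_mesh`.
#' @param path File path (`.json`).
#' @return `save_mesh` returns `path` invisibly; `load_mesh` the mesh.
#' @export
save_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "deterministic_mesh"))
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path))
  write_walker_config(mesh$config, cfg_path)
  json_write(list(schema = schema_version,
                  states = mesh$states,
                  transitions = mesh$transitions,
                  rep_pert = mesh$rep_pert,
                  config = jsonlite::read_json(cfg_path,
                                               simplifyVector = TRUE)),
             path)
  invisible(path)
}

#' @rdname save_mesh
#' @export
load_mesh <- function(path) {
  obj <- json_read(path, "mesh")
  cfg_path <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_path))
  json_write(obj$config, cfg_path)
  config <- read_walker_config(cfg_path)
  states <- matrix(as.numeric(obj$states), ncol = config$state_dim)
  trans <- matrix(as.integer(obj$transitions), nrow = nrow(states))
  rp <- matrix(as.numeric(obj$rep_pert), nrow = nrow(states))
  structure(list(states = states, transitions = trans, rep_pert = rp,
                 config = config),
            class = "deterministic_mesh")
}

#' Save or load an absorbing chain
#'
#' @param chain An `absorbing_chain`.
#' @param path File path (`.json`).
#' @return `save_chain` returns `path` invisibly; `load_chain` the chain.
#' @export
save_chain <- function(chain, path) {
  stopifnot(inherits(chain, "absorbing_chain"))
  json_write(list(schema = schema_version, Q = chain$Q, R = chain$R,
                  cell_masses = chain$cell_masses,
                  state_labels = chain$state_labels,
                  mesh_ref = chain$mesh_ref),
             path)
  invisible(path)
}

#' @rdname save_chain
#' @export
load_chain <- function(path) {
  obj <- json_read(path, "chain")
  t_n <- length(obj$R)
  structure(list(Q = matrix(as.numeric(obj$Q), t_n, t_n),
                 R = as.numeric(obj$R),
                 cell_masses = as.numeric(obj$cell_masses),
                 state_labels = obj$state_labels,
                 mesh_ref = matrix(as.numeric(obj$mesh_ref), nrow = t_n)),
            class = "absorbing_chain")
}

#' Write or read a metric table as CSV
#'
#' One row per condition, the 49 named metric columns plus `condition`,
#' `provenance` and `n_steps`; numbers at 17 significant digits so the
#' round-trip is lossless.
#'
#' @param vectors Named list of `metric_vector`s (names = condition labels)
#'   or a metric matrix with rownames.
#' @param path CSV path.
#' @return `write_metric_csv` returns `path` invisibly; `read_metric_csv` a
#'   matrix with `provenance`/`n_steps` attributes per row in attributes
#'   `provenance` and `n_steps`.
#' @export
write_metric_csv <- function(vectors, path) {
  M <- metric_matrix(vectors)
  prov <- if (is.list(vectors))
    vapply(vectors, function(v) as.character(attr(v, "provenance") %||% NA),
           character(1))
  else rep(NA_character_, nrow(M))
  nst <- if (is.list(vectors))
    vapply(vectors, function(v) as.integer(attr(v, "n_steps") %||% NA),
           integer(1))
  else rep(NA_integer_, nrow(M))
  df <- data.frame(condition = rownames(M) %||% seq_len(nrow(M)),
                   provenance = prov, n_steps = nst,
                   stringsAsFactors = FALSE)
  for (cn in colnames(M)) df[[cn]] <- format(M[, cn], digits = 17)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_csv
#' @export
read_metric_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("condition", "provenance", "n_steps")
  M <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  rownames(M) <- df$condition
  attr(M, "provenance") <- df$provenance
  attr(M, "n_steps") <- df$n_steps
  M
}

#' Save or load a combined fall-risk model
#'
#' JSON serialization of everything needed to predict: variant,
#' normalization record, PCA centre and loadings, selected terms,
#' coefficients, tolerance and seed.
#'
#' @param model A [fallrisk()] model.
#' @param path File path (`.json`).
#' @return `save_fallrisk` returns `path` invisibly; `load_fallrisk` a
#'   `fallrisk` model (prediction-capable; the training `lm` is not
#'   serialized).
#' @export
save_fallrisk <- function(model, path) {
  stopifnot(inherits(model, "fallrisk"))
  json_write(list(
    schema = schema_version, variant = model$variant,
    center = as.list(model$normalization$center),
    scale = as.list(model$normalization$scale),
    pca_center = as.list(model$pca$center),
    pca_rotation = model$pca$rotation,
    n_scores = model$pca$n_scores,
    terms = model$terms,
    coefficients = as.list(model$coefficients),
    tolerance = model$tolerance, seed = model$seed), path)
  invisible(path)
}

#' @rdname save_fallrisk
#' @export
load_fallrisk <- function(path) {
  obj <- json_read(path, "fall-risk model")
  record <- structure(list(center = unlist(obj$center),
                           scale = unlist(obj$scale)),
                      class = "normalization_record")
  rot <- matrix(as.numeric(obj$pca_rotation),
                nrow = length(obj$pca_center),
                dimnames = list(names(obj$pca_center),
                                paste0("PC", seq_len(obj$n_scores))))
  pca <- structure(list(rotation = rot, center = unlist(obj$pca_center),
                        n_scores = obj$n_scores, sdev = NULL, scores = NULL),
                   class = "metric_pca")
  structure(list(variant = obj$variant, normalization = record, pca = pca,
                 terms = as.character(unlist(obj$terms)),
                 coefficients = unlist(obj$coefficients),
                 fit = NULL, votes = NULL, seed = obj$seed,
                 tolerance = obj$tolerance,
                 training = NULL),
            class = "fallrisk")
}

#' Run manifest
#'
#' Records what produced a run's outputs: an MD5 hash of the canonical
#' config JSON, the seeds, the package version, the registered files and
#' timing, so a run can be reproduced bit for bit.
#'
#' @param config A [walker_config()] (or a list of them).
#' @param seeds Named or plain integer vector of the seeds used.
#' @param files Character vector of output files produced.
#' @param path Optional path: when given, the manifest is also written
#'   there as JSON.
#' @return The manifest list, invisibly when `path` is given.
#' @export
run_manifest <- function(config, seeds, files = character(0), path = NULL) {
  cfgs <- if (inherits(config, "walker_config")) list(config) else config
  hashes <- vapply(cfgs, function(cf) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    write_walker_config(cf, tmp)
    unname(tools::md5sum(tmp))
  }, character(1))
  man <- list(schema = schema_version,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("fallrisk")),
              config_hash = hashes, seeds = as.list(seeds),
              files = as.list(files))
  if (!is.null(path)) {
    json_write(man, path)
    return(invisible(man))
  }
  man
}

`%||%` <- function(a, b) if (is.null(a)) b else a
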