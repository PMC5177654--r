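# Model and bundle serialisation: JSON metadata plus full-precision TSV
# coefficient tables, so archives remain text and round-trip exactly.

num17 <- function(x) sprintf("%.17g", as.numeric(x))

write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  df <- as.data.frame(m)
  names(df) <- colnames(m) %||% paste0("c", seq_len(ncol(m)))
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  as.matrix(read.delim(path, sep = "\t", check.names = FALSE))
}

#' Serialise an encoding model to a directory
#'
#' @param model An `encoding_model`.
#' @param dir Output directory.
#' @export
write_encoding_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format = "ukfbmi-encoding-model", version = 1L,
    spec = if (!is.null(model$spec)) {
      list(groups = model$spec$groups, tap_offsets = model$spec$tap_offsets,
           magnitudes = as.list(model$spec$magnitudes),
           history_scope = model$spec$history_scope, label = model$spec$label)
    },
    lambda = num17(model$lambda), lambda_grid = num17(model$lambda_grid),
    unit_ids = model$unit_ids, n_rows = model$n_rows,
    kept = model$kept)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_matrix_tsv(model$coef, file.path(dir, "coefficients.tsv"))
  write_tsv(data.frame(feature = model$features$name, group = model$features$group,
                       var = model$features$var, tap = model$features$tap,
                       type = model$features$type, unit = model$features$unit,
                       center = model$centers, scale = model$scales),
            file.path(dir, "features.tsv"))
  write_tsv(data.frame(unit_id = model$unit_ids, unit_mean = model$unit_means),
            file.path(dir, "units.tsv"))
  if (!is.null(model$R)) write_matrix_tsv(model$R, file.path(dir, "residual_cov.tsv"))
  invisible(dir)
}

#' Read an encoding model from a directory
#'
#' @param dir Directory written by [write_encoding_model()].
#' @export
read_encoding_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "ukfbmi-encoding-model")) {
    stop(dir, ": not an encoding-model archive")
  }
  featfile <- read.delim(file.path(dir, "features.tsv"), sep = "\t")
  units <- read.delim(file.path(dir, "units.tsv"), sep = "\t")
  coef <- read_matrix_tsv(file.path(dir, "coefficients.tsv"))
  rpath <- file.path(dir, "residual_cov.tsv")
  spec <- if (!is.null(meta$spec)) {
    feature_spec(meta$spec$groups, meta$spec$tap_offsets,
                 magnitudes = unlist(meta$spec$magnitudes),
                 history_scope = meta$spec$history_scope,
                 label = meta$spec$label)
  }
  structure(
    list(spec = spec,
         features = data.frame(name = featfile$feature, group = featfile$group,
                               var = featfile$var, tap = featfile$tap,
                               type = featfile$type, unit = featfile$unit,
                               stringsAsFactors = FALSE),
         coef = structure(coef, dimnames = list(meta$unit_ids, featfile$feature)),
         centers = featfile$center, scales = featfile$scale,
         kept = meta$kept, unit_means = units$unit_mean,
         lambda = as.numeric(meta$lambda),
         lambda_grid = as.numeric(meta$lambda_grid),
         R = if (file.exists(rpath)) unname(read_matrix_tsv(rpath)),
         unit_ids = meta$unit_ids, n_rows = meta$n_rows),
    class = "encoding_model"
  )
}

#' Serialise a ground-truth population model
#'
#' @param model A [sample_population()] model.
#' @param dir Output directory.
#' @export
write_population_model <- function(model, dir) {
  write_encoding_model(model, dir)
  jsonlite::write_json(
    list(channel_of_unit = model$channel_of_unit,
         untuned_units = model$untuned_units,
         config = unclass(model$config)),
    file.path(dir, "population.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Read a ground-truth population model
#'
#' @param dir Directory written by [write_population_model()].
#' @export
read_population_model <- function(dir) {
  model <- read_encoding_model(dir)
  pop <- jsonlite::read_json(file.path(dir, "population.json"),
                             simplifyVector = TRUE)
  model$channel_of_unit <- pop$channel_of_unit
  model$untuned_units <- pop$untuned_units
  cfg <- as.list(pop$config)
  cfg$scales <- unlist(cfg$scales)
  model$config <- do.call(population_config, cfg)
  class(model) <- c("population_model", "encoding_model")
  model
}

#' Serialise a decoder bundle to a directory
#'
#' Writes the encoding model, the transition model and the bundle
#' configuration (layout, control settings, initial belief) as a
#' version-stamped text archive.
#'
#' @param bundle A `decoder_bundle`.
#' @param dir Output directory.
#' @export
write_decoder_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_encoding_model(bundle$encoding, file.path(dir, "encoding"))
  tr <- bundle$transition
  write_matrix_tsv(tr$F, file.path(dir, "transition_F.tsv"))
  write_matrix_tsv(tr$Q, file.path(dir, "transition_Q.tsv"))
  write_matrix_tsv(bundle$init_belief$cov, file.path(dir, "init_cov.tsv"))
  meta <- list(
    format = "ukfbmi-decoder-bundle", version = 1L,
    variant = bundle$variant, mode = bundle$mode, dt = bundle$dt,
    smooth_accel_window = bundle$smooth_accel_window,
    control = unclass(bundle$control),
    transition = list(kind = tr$kind, params = tr$params,
                      position_feedback = tr$position_feedback,
                      b = num17(tr$b)),
    init_mean = num17(bundle$init_belief$mean),
    last_train_counts = bundle$last_train_counts)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a decoder bundle from a directory
#'
#' @param dir Directory written by [write_decoder_bundle()].
#' @export
read_decoder_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "ukfbmi-decoder-bundle")) {
    stop(dir, ": not a decoder-bundle archive")
  }
  layout <- make_layout(meta$variant)
  F <- unname(read_matrix_tsv(file.path(dir, "transition_F.tsv")))
  Q <- unname(read_matrix_tsv(file.path(dir, "transition_Q.tsv")))
  dimnames(F) <- dimnames(Q) <- list(layout$names, layout$names)
  trans <- new_transition(F, as.numeric(meta$transition$b), Q, layout,
                          as.list(meta$transition$params),
                          meta$transition$position_feedback,
                          meta$transition$kind)
  ctrl <- do.call(control_config, meta$control)
  init <- gaussian_belief(as.numeric(meta$init_mean),
                          unname(read_matrix_tsv(file.path(dir, "init_cov.tsv"))))
  structure(
    list(variant = meta$variant, mode = meta$mode, layout = layout,
         encoding = read_encoding_model(file.path(dir, "encoding")),
         transition = trans, control = ctrl, init_belief = init,
         last_train_counts = meta$last_train_counts,
         smooth_accel_window = meta$smooth_accel_window, dt = meta$dt),
    class = "decoder_bundle"
  )
}
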