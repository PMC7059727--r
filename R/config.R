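#' Read a pipeline configuration from YAML
#'
#' Builds the run configuration from a YAML file with optional blocks
#' \code{preprocessing:} (thresholds \code{patient_threshold},
#' \code{predictor_threshold}, \code{statistic_threshold},
#' \code{impute_scope}), \code{ga:} (any \code{\link{ga_config}}
#' argument) and \code{model:} (any \code{\link{model_spec}} argument,
#' with \code{task} required).  Omitted fields fall back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return List with elements \code{preprocessing} (named list of
#'   thresholds), \code{ga} (a \code{ga_config}) and \code{model} (a
#'   \code{model_spec}).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path) %||% list()
  pp_defaults <- list(patient_threshold = 0.30, predictor_threshold = 0.40,
                      statistic_threshold = 0.20, impute_scope = "train_only")
  pp <- utils::modifyList(pp_defaults, y$preprocessing %||% list())
  unknown <- setdiff(names(pp), names(pp_defaults))
  assert_that(length(unknown) == 0,
              sprintf("unknown preprocessing option(s): %s",
                      paste(unknown, collapse = ", ")),
              "icustatsel_config_error")
  ga <- do.call(ga_config, y$ga %||% list())
  model <- do.call(model_spec, y$model %||% list())
  list(preprocessing = pp, ga = ga, model = model)
}
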