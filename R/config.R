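# Pipeline configuration: a validated flat key -> value mapping that
# serializes losslessly to YAML/JSON. Defaults are the package's tested
# operating point; every key is documented in ?pipelineConfig.

.config_defaults <- function() list(
  # Harris corner detector
  harris_sigma        = 2,      # Gaussian window scale, px
  harris_k            = 0.04,   # trace weight in R = det - k tr^2
  harris_rel_threshold = 0.01,  # keep R > rel * max(R)
  anms_n              = 100,    # corners retained after ANMS
  anms_c_robust       = 0.9,    # ANMS robustness ratio
  # vesselness / junction detection
  vessel_sigma        = 2,      # Hessian scale, px
  junction_merge_radius = 8,    # junction barycenter merge radius, px
  # relaxation matching
  relax_window        = 21,     # gradient-descriptor window side, px (odd)
  relax_search_radius = 30,     # target search radius, px
  relax_ratio_max     = 1,      # best/second-peak SAD cap; 1 = off
  # shape-context strict matching
  sc_radius           = 100,    # shape-context outer radius R, px
  sc_n_angle          = 12,     # angular bins
  sc_n_rad            = 5,      # radial bins
  # matching-vector revision / merge
  vector_tol          = 10,     # matching-vector tolerance, px
  pair_anms_n         = 40,     # control pairs retained after ANMS
  # TPS
  tps_lambda          = 300,    # regularization; 0 = pure interpolation
  # SOM refinement
  som_grid_size       = 5,      # units per lattice side (odd)
  som_grid_spacing    = 2,      # lattice spacing, px
  som_eta0            = 0.5,    # initial learning rate
  som_sig0            = 10,     # initial neighborhood parameter, px
  som_i_max           = 30,     # iteration budget
  som_mi_tol          = 0.02,   # winner-vs-center MI noise margin, nats
  som_mi_stride       = 2,      # pixel stride of candidate MI scoring
  som_trust_radius    = 6,      # max travel from the matched position, px
  mi_bins             = 32,     # MI joint-histogram bins
  # preprocessing (off by default; the upstream method does not fix one)
  enhance_contrast    = FALSE,  # stretch intensities to full [0,1] range
  seed                = 1       # seed for any stochastic tie-breaking
)

#' PipelineConfig: all tunables of the registration pipeline
#'
#' A flat, validated key-value mapping holding every stage's parameters.
#' Construct with \code{\link{pipelineConfig}}; read/write with
#' \code{\link{readPipelineConfig}} / \code{\link{writePipelineConfig}}.
#'
#' @slot values named list of parameter values.
#' @export
setClass("PipelineConfig", representation(values = "list"))

setValidity("PipelineConfig", function(object) {
  v <- object@values
  def <- .config_defaults()
  unknown <- setdiff(names(v), names(def))
  if (length(unknown))
    return(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (!setequal(names(v), names(def)))
    return("config must contain every documented key")
  dimensionful <- c("harris_sigma", "anms_n", "vessel_sigma",
                    "junction_merge_radius", "relax_window",
                    "relax_search_radius", "sc_radius", "sc_n_angle",
                    "sc_n_rad", "vector_tol", "pair_anms_n",
                    "som_grid_size", "som_grid_spacing", "som_sig0",
                    "som_i_max", "som_mi_stride", "mi_bins")
  for (k in dimensionful)
    if (!is.numeric(v[[k]]) || v[[k]] <= 0)
      return(sprintf("config key '%s' must be positive", k))
  if (v$harris_k < 0.04 - 1e-12 || v$harris_k > 0.06 + 1e-12)
    return("harris_k must lie in [0.04, 0.06]")
  if (v$harris_rel_threshold <= 0 || v$harris_rel_threshold >= 1)
    return("harris_rel_threshold must lie in (0, 1)")
  if (v$anms_c_robust <= 0 || v$anms_c_robust > 1)
    return("anms_c_robust must lie in (0, 1]")
  if (v$relax_window %% 2 != 1)
    return("relax_window must be odd")
  if (v$som_grid_size %% 2 != 1)
    return("som_grid_size must be odd")
  if (v$tps_lambda < 0) return("tps_lambda must be >= 0")
  if (v$som_eta0 <= 0 || v$som_eta0 > 1)
    return("som_eta0 must lie in (0, 1]")
  TRUE
})

#' Build a pipeline configuration
#'
#' Returns the default configuration with any named overrides applied.
#' See the source of \code{thermoreg:::.config_defaults} (or the methods
#' vignette) for the meaning, unit and default of every key.
#'
#' @param ... named overrides of default keys, e.g.
#'   \code{pipelineConfig(relax_search_radius = 20)}.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(som_i_max = 10)
#' cfg[["som_i_max"]]
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  def <- .config_defaults()
  bad <- setdiff(names(over), names(def))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  def[names(over)] <- over
  new("PipelineConfig", values = def)
}

#' @export
setMethod("[[", "PipelineConfig", function(x, i) {
  if (!i %in% names(x@values)) stop("unknown config key: ", i)
  x@values[[i]]
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig with", length(object@values), "keys\n")
  v <- object@values
  for (k in names(v)) cat(sprintf("  %-22s %s\n", k, format(v[[k]])))
})

#' Read a pipeline configuration from YAML or JSON
#'
#' The file must be a flat mapping; missing keys take their defaults,
#' unknown keys are an error.
#'
#' @param path file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipelineConfig, as.list(vals))
}

#' Write a pipeline configuration to YAML or JSON
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path destination path; format chosen by extension.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config@values, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config@values, path)
  invisible(path)
}
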