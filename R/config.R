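#' Coefficient configuration for molecular-weight estimators
#'
#' Loads the editable YAML table of method coefficients: the
#' volume-of-correlation power-law constants per molecule class, the
#' apparent-Porod-volume truncation correction, and the per-residue
#' average masses and partial specific volumes used by
#' [sequence_stats()]. Users may point to their own file to override any
#' value; the packaged defaults document their provenance inline.
#'
#' @param path optional path to a YAML file with the same structure as the
#'   packaged `extdata/coefficients.yaml`.
#' @return Nested named list of coefficients.
#' @export
sas_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0(".sas_coeff_cache", envir = .saskit_env)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "coefficients.yaml", package = "saskit")
    if (!nzchar(path)) {
      # during development (package not installed)
      path <- file.path("inst", "extdata", "coefficients.yaml")
    }
    out <- yaml::read_yaml(path)
    assign(".sas_coeff_cache", out, envir = .saskit_env)
    return(out)
  }
  yaml::read_yaml(path)
}

.saskit_env <- new.env(parent = emptyenv())
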