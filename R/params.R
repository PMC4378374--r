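#' Model parameterization
#'
#' The whole model is driven by a single nested parameter list: allometric
#' rules per trait, the four functional types, the zooplankton size spectrum,
#' food-web rate constants, seasonal forcing, grid and numerical settings.
#' `plankton_params()` returns the default set shipped with the package
#' (see `inst/extdata/default_params.yaml`), optionally modified; the defaults
#' follow the published size-scaling literature and are fully overridable.
#'
#' @param ... named overrides, merged recursively into the defaults, e.g.
#'   `plankton_params(ecology = list(mortality = 0.1))`.
#' @param file optional path to a YAML parameter file to use instead of the
#'   packaged defaults (overrides in `...` still apply on top).
#' @return A nested list of class `evo_params`.
#' @examples
#' p <- plankton_params()
#' p$ecology$mortality
#' p2 <- plankton_params(ecology = list(mortality = 0.1))
#' @export
plankton_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_params.yaml", package = "evoplankton")
  }
  p <- read_params(file)
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(nzchar(names(dots))))
    p <- utils::modifyList(p, dots)
  }
  structure(p, class = c("evo_params", "list"))
}

#' Read a parameter file
#'
#' Parameter files are plain YAML with the same nesting as
#' [plankton_params()]. Reading and writing round-trip losslessly (up to
#' numeric formatting, which is preserved at full double precision).
#'
#' @param file path to a YAML file.
#' @return A nested list of class `evo_params`.
#' @seealso [write_params()]
#' @export
read_params <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  p <- yaml::read_yaml(file)
  structure(p, class = c("evo_params", "list"))
}

#' Write a parameter file
#'
#' @param params an `evo_params` list.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_params <- function(params, file) {
  yaml::write_yaml(unclass(params), file, precision = 17)
  invisible(file)
}

#' @export
print.evo_params <- function(x, ...) {
  cat("<evo_params>\n")
  cat("  functional types:", paste(names(x$functional_types), collapse = ", "), "\n")
  cat("  zooplankton spectrum:", x$zooplankton$n_species, "species,",
      format(x$zooplankton$volume_min), "-", format(x$zooplankton$volume_max), "um^3\n")
  cat("  grid:", x$grid$n_levels, "levels over", x$grid$depth, "m\n")
  cat("  dt:", x$numerics$dt_bio, "d\n")
  invisible(x)
}
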