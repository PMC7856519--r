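#' The Iris variable-aperture collimator model
#'
#' The Iris collimator offers 12 discrete field diameters — 5, 7.5, 10, 12.5,
#' 15, 20, 25, 30, 35, 40, 50 and 60 mm — defined at 800 mm from the focal
#' spot. The engine models the field as a ball of the nominal diameter
#' centred on the predicted target position (beam divergence and the
#' nonisocentric beam geometry are not modelled).
#'
#' @param diameters Strictly increasing positive field diameters in mm.
#'   Defaults to the 12 Iris diameters.
#' @param reference_distance Distance (mm) at which the diameters are
#'   defined; informational only.
#' @return An `iris_collimator` object.
#' @examples
#' iris_collimator()$diameters
#' @export
iris_collimator <- function(diameters = c(5, 7.5, 10, 12.5, 15, 20, 25, 30,
                                          35, 40, 50, 60),
                            reference_distance = 800) {
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0 || any(!is.finite(diameters)) ||
      any(diameters <= 0) || is.unsorted(diameters, strictly = TRUE)) {
    stop("`diameters` must be strictly increasing and positive",
      call. = FALSE
    )
  }
  structure(
    list(diameters = diameters, reference_distance = reference_distance),
    class = "iris_collimator"
  )
}

#' @export
print.iris_collimator <- function(x, ...) {
  cat(
    "<iris_collimator> ", length(x$diameters), " field diameters (mm): ",
    paste(x$diameters, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
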