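# Anatomical orientation metadata. A disarticulated facet has no intrinsic
# dorsal/volar or radial/ulnar direction; either a landmark-derived axis
# file supplies one, or PCA of the patch is used as a declared default.

#' Construct an orientation specification
#'
#' @param dorsal_volar Unit 3-vector pointing dorsally (optional).
#' @param radial_ulnar Unit 3-vector pointing ulnarly (optional).
#' @param source `"landmarks"` or `"pca-default"`.
#' @return An `orientation_spec` object with re-orthogonalised axes.
#' @export
orientation_spec <- function(dorsal_volar = NULL, radial_ulnar = NULL,
                             source = c("pca-default", "landmarks")) {
  source <- match.arg(source)
  if (source == "landmarks") {
    u1 <- normalize(as_point3(dorsal_volar, "dorsal_volar"))
    v <- as_point3(radial_ulnar, "radial_ulnar")
    ang <- angle_between(u1, v)
    if (abs(ang - 90) > 10) {
      fm_abort(
        sprintf("orientation axes are %.1f degrees apart; more than 10 degrees from orthogonal", ang),
        "fm_validation_error"
      )
    }
    u2 <- normalize(v - sum(v * u1) * u1)
    u3 <- cross3(u1, u2)
    out <- list(dorsal_volar_axis = u1, radial_ulnar_axis = u2,
                proximal_distal_axis = u3, source = source)
  } else {
    out <- list(dorsal_volar_axis = NULL, radial_ulnar_axis = NULL,
                proximal_distal_axis = NULL, source = source)
  }
  structure(out, class = "orientation_spec")
}

#' Read an orientation JSON file
#'
#' Expects `{"dorsal_volar": [x,y,z], "radial_ulnar": [x,y,z]}`. Axes are
#' re-orthogonalised by Gram-Schmidt (dorsal-volar first) and the third
#' axis derived by right-handed completion. A missing file falls back to
#' the PCA default with a warning; axes more than 10 degrees from
#' orthogonal raise a validation error.
#'
#' @param path Path to the JSON file.
#' @return An [orientation_spec()].
#' @export
read_orientation <- function(path) {
  if (!file.exists(path)) {
    rlang::warn(sprintf("orientation file '%s' not found; falling back to PCA axes", path))
    return(orientation_spec(source = "pca-default"))
  }
  js <- jsonlite::fromJSON(path)
  if (is.null(js$dorsal_volar) || is.null(js$radial_ulnar)) {
    fm_abort("orientation JSON must name 'dorsal_volar' and 'radial_ulnar' axes", "fm_validation_error")
  }
  orientation_spec(js$dorsal_volar, js$radial_ulnar, source = "landmarks")
}
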