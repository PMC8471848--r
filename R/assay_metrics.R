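#' Caliper tumor volume
#'
#' Ellipsoid approximation from caliper length and width:
#' volume = 0.52 * L * W^2 (mm^3). By caliper convention the length is the
#' larger dimension; pairs supplied with W > L are swapped, with a warning.
#'
#' @param L tumor length, mm (vectorized).
#' @param W tumor width, mm.
#' @return volume(s), mm^3.
#' @export
tumor_volume <- function(L, W) {
  stopifnot(length(L) == length(W))
  if (any(L <= 0 | W <= 0)) stop("L and W must be positive")
  swap <- W > L
  if (any(swap)) {
    warning("W > L for ", sum(swap), " measurement(s); swapped to the ",
            "caliper convention L >= W")
    tmp <- L[swap]; L[swap] <- W[swap]; W[swap] <- tmp
  }
  0.52 * L * W^2
}

#' Soluble collagen per tumor mass
#'
#' @param collagen_ug total soluble collagen, micrograms.
#' @param mass_mg tumor mass, milligrams (> 0).
#' @return micrograms of collagen per milligram of tumor.
#' @export
collagen_density <- function(collagen_ug, mass_mg) {
  if (any(mass_mg <= 0)) stop("tumor mass must be positive")
  if (any(collagen_ug < 0)) stop("collagen amount must be non-negative")
  collagen_ug / mass_mg
}

#' Fibroblast density as marker-positive area per high-power field
#'
#' @param marker_area_px2 total marker-positive area across fields, px^2
#'   (or a vector of per-field areas, summed).
#' @param n_fields number of high-power fields (>= 1).
#' @param pixel_size pixel edge length, micrometres.
#' @return mean marker-positive area per HPF, square micrometres.
#' @export
fibroblast_density <- function(marker_area_px2, n_fields, pixel_size = 1) {
  if (n_fields < 1) stop("need at least one high-power field")
  if (any(marker_area_px2 < 0)) stop("areas must be non-negative")
  sum(marker_area_px2) * pixel_size^2 / n_fields
}
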