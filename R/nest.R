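## Initial-chamber geometry of incipient nests.

#' Initial-chamber volume from radius and height
#'
#' Volume of the first excavated nest chamber, modelled as a cylinder with a
#' rounded cap: `V = pi * r^2 * (ch + 0.67 * r)` with cylinder height
#' `ch = h - r`. The 0.67 factor is an empirical correction for the rounded
#' roof; at `h = r` (no cylindrical section) it reproduces a hemispherical
#' cap to within 0.5% (0.67 vs 2/3).
#'
#' @param r chamber base radius, cm (>= 0).
#' @param h maximum chamber height, cm; must satisfy `h >= r`.
#' @return Volume in cm3.
#' @examples
#' chamber_volume(1, 2) # pi * 1.67
#' @export
chamber_volume <- function(r, h) {
  if (any(r < 0)) stop("`r` must be non-negative")
  if (any(h < r)) stop("`h` must be at least `r` (cylinder height ch = h - r)")
  pi * r^2 * ((h - r) + 0.67 * r)
}

#' Chamber base radius from measured horizontal dimensions
#'
#' Field measurements record chamber width and length; the volume formula
#' needs a single base radius. The default rule takes the mean horizontal
#' semi-axis, `r = (width + length) / 4`; alternative reductions of the
#' elliptical base are selectable and the choice is recorded by callers.
#'
#' @param width,length measured horizontal chamber dimensions, cm (> 0).
#' @param rule how to reduce the two semi-axes to one radius: `"mean"`
#'   (default), `"min"`, `"max"` or `"geometric"` mean.
#' @return Radius in cm.
#' @export
chamber_radius <- function(width, length,
                           rule = c("mean", "min", "max", "geometric")) {
  rule <- match.arg(rule)
  if (any(width <= 0) || any(length <= 0)) {
    stop("`width` and `length` must be strictly positive")
  }
  switch(rule,
    mean = (width + length) / 4,
    min = pmin(width, length) / 2,
    max = pmax(width, length) / 2,
    geometric = sqrt(width * length) / 2
  )
}

#' Append derived chamber volumes to a nest table
#'
#' Computes the base radius from `width_cm`/`length_cm` via [chamber_radius()]
#' and the volume from the radius and `height_cm` via [chamber_volume()].
#' Reported mean volumes should be means of these per-nest volumes, never the
#' volume of mean dimensions (the volume formula is nonlinear).
#'
#' @param nests data frame with columns `width_cm`, `length_cm`, `height_cm`.
#' @param rule radius rule, passed to [chamber_radius()].
#' @return `nests` with `radius_cm` and `volume_cm3` appended; the radius rule
#'   is recorded in the `"radius_rule"` attribute.
#' @export
nest_volumes <- function(nests, rule = "mean") {
  needed <- c("width_cm", "length_cm", "height_cm")
  missing_cols <- setdiff(needed, names(nests))
  if (length(missing_cols)) {
    stop("nest table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  r <- chamber_radius(nests$width_cm, nests$length_cm, rule = rule)
  h <- pmax(nests$height_cm, r) # a cap shallower than its radius is all cap
  nests$radius_cm <- r
  nests$volume_cm3 <- chamber_volume(r, h)
  attr(nests, "radius_rule") <- rule
  nests
}
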