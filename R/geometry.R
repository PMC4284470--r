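#' Container geometry of a spherical, turgid protocell
#'
#' The protocell is modelled as a spherical vesicle with a membrane of constant
#' thickness `delta` and constant lipid number density `rho`. The container
#' size is measured by `C`, the total number of lipid molecules in the
#' membrane (proportional to membrane mass). Inverting the spherical-shell
#' relation `C = rho * (4/3) * pi * ((r + delta)^3 - r^3)` for the inner radius
#' `r` gives the internal (aqueous) volume as a closed form,
#'
#' \deqn{V_r(C) = \frac{\pi\delta^3}{6}\left(\sqrt{\frac{C}{\pi\rho\delta^3} -
#'   \frac13} - 1\right)^3}
#'
#' which scales as \eqn{O(C^{3/2})} when \eqn{\delta^3\rho/C \to 0} (thin
#' membrane). The domain requires `C >= (4/3) * pi * rho * delta^3` (the
#' membrane at most fills the whole sphere, inner radius 0).
#'
#' @param C lipid count (may be a vector).
#' @param delta membrane thickness, length units.
#' @param rho lipid number density in the membrane (lipids per unit membrane
#'   volume).
#' @return `internal_volume()`: internal volume `V_r >= 0`;
#'   `surface_area()`: inner membrane surface area `A = 4 pi r^2`;
#'   `inner_radius()`: the inner radius `r`.
#' @examples
#' internal_volume(1e6, delta = 0.02, rho = 1000)
#' surface_area(1e6, delta = 0.02, rho = 1000)
#' @export
internal_volume <- function(C, delta, rho) {
  r <- inner_radius(C, delta, rho)
  (4 / 3) * pi * r^3
}

#' @rdname internal_volume
#' @export
inner_radius <- function(C, delta, rho) {
  stopifnot(delta > 0, rho > 0)
  u <- C / (pi * rho * delta^3) - 1 / 3
  if (any(u < 1)) {
    stop("C below the geometric bound (4/3)*pi*rho*delta^3: no inner volume")
  }
  (delta / 2) * (sqrt(u) - 1)
}

#' @rdname internal_volume
#' @export
surface_area <- function(C, delta, rho) {
  r <- inner_radius(C, delta, rho)
  4 * pi * r^2
}

#' Lipid count of a spherical shell of inner radius r
#'
#' Forward relation `C = rho * (4/3) * pi * ((r + delta)^3 - r^3)`; the exact
#' inverse of [internal_volume()] composed with the radius of a sphere.
#'
#' @param r inner radius (vectorized).
#' @inheritParams internal_volume
#' @return lipid count C.
#' @export
shell_mass <- function(r, delta, rho) {
  rho * (4 / 3) * pi * ((r + delta)^3 - r^3)
}

#' Daughter-to-mother volume ratio and material loss at division
#'
#' A protocell divides when its lipid count reaches the threshold `theta`;
#' each daughter receives `theta / 2` lipids. Because volume scales faster
#' than linearly in membrane mass, the two daughters together hold less volume
#' than the mother: the ratio `V_r(theta/2) / V_r(theta)` tends to
#' `(1/2)^(3/2) = 0.3535...` as `delta^3 * rho / theta -> 0`, so a fraction
#' `1 - 2 * ratio` (about 29.3%, "around 30%") of the internal material is
#' lost to the environment at each division if internal concentrations are
#' conserved.
#'
#' @param theta division threshold, lipid count.
#' @inheritParams internal_volume
#' @return `daughter_volume_ratio()`: a number in (0, 1/2);
#'   `lost_fraction()`: `1 - 2 * daughter_volume_ratio()`.
#' @examples
#' daughter_volume_ratio(1e6, delta = 0.01, rho = 1) # close to 2^(-3/2)
#' lost_fraction(1e6, delta = 0.01, rho = 1)         # close to 0.293
#' @export
daughter_volume_ratio <- function(theta, delta, rho) {
  internal_volume(theta / 2, delta, rho) / internal_volume(theta, delta, rho)
}

#' @rdname daughter_volume_ratio
#' @export
lost_fraction <- function(theta, delta, rho) {
  1 - 2 * daughter_volume_ratio(theta, delta, rho)
}

#' Define the container geometry of a protocell
#'
#' Bundles the geometric parameters used by the simulator: membrane thickness,
#' lipid density, the division threshold, the current lipid count and the
#' lipid-increment granularity `g` of the stochastic growth channel (each
#' firing of the growth channel adds `g` lipids; `g = 1` is the exact SSA
#' channel, larger `g` batches lipid additions without changing the mean
#' dynamics).
#'
#' @inheritParams internal_volume
#' @param theta division threshold (lipid count); both `theta` and `theta / 2`
#'   must satisfy the positivity bound so daughters are well formed.
#' @param C0 initial lipid count; defaults to `theta / 2` (a newborn).
#' @param g lipid increment per growth event (positive integer).
#' @return an object of class `container_geometry`.
#' @examples
#' geom <- container_geometry(delta = 0.01, rho = 1000, theta = 2000)
#' geom
#' @export
container_geometry <- function(delta, rho, theta, C0 = theta / 2, g = 1L) {
  stopifnot(delta > 0, rho > 0, theta > 0, g >= 1)
  bound <- (4 / 3) * pi * rho * delta^3
  if (theta / 2 <= bound) {
    stop("theta/2 must exceed (4/3)*pi*rho*delta^3 so daughters have volume")
  }
  if (C0 <= bound) stop("C0 below the geometric positivity bound")
  structure(
    list(delta = delta, rho = rho, theta = theta, C0 = C0, g = as.integer(g)),
    class = "container_geometry"
  )
}

#' @export
print.container_geometry <- function(x, ...) {
  cat("<container_geometry>\n")
  cat(sprintf("  delta = %g, rho = %g, theta = %g, C0 = %g, g = %d\n",
              x$delta, x$rho, x$theta, x$C0, x$g))
  cat(sprintf("  V_r(C0) = %.4g, V_r(theta) = %.4g, daughter/mother ratio = %.4f, lost = %.1f%%\n",
              internal_volume(x$C0, x$delta, x$rho),
              internal_volume(x$theta, x$delta, x$rho),
              daughter_volume_ratio(x$theta, x$delta, x$rho),
              100 * lost_fraction(x$theta, x$delta, x$rho)))
  invisible(x)
}

#' Geometry summary table
#'
#' One-row tibble of derived geometric quantities, convenient for reports and
#' the command-line `geom` subcommand.
#'
#' @param geometry a [container_geometry()].
#' @return a tibble with columns `C`, `V_r`, `area`, `daughter_ratio`,
#'   `lost_fraction`.
#' @export
geometry_summary <- function(geometry) {
  stopifnot(inherits(geometry, "container_geometry"))
  tibble(
    C = geometry$C0,
    theta = geometry$theta,
    V_r = internal_volume(geometry$C0, geometry$delta, geometry$rho),
    area = surface_area(geometry$C0, geometry$delta, geometry$rho),
    daughter_ratio = daughter_volume_ratio(geometry$theta, geometry$delta, geometry$rho),
    lost_fraction = lost_fraction(geometry$theta, geometry$delta, geometry$rho)
  )
}
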