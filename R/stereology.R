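#' Stereology parameters
#'
#' Coefficients for model-based 3D extrapolation of 2D profile
#' measurements. The tuft volume uses the Weibel-Gomez estimator
#' `V = (beta / k) * A^(3/2)` with the sphere shape coefficient
#' `beta = 1.38` and size-distribution coefficient `k = 1`; podocyte
#' nuclei are modeled as spheres.
#'
#' @param beta shape coefficient (>= 1).
#' @param k size-distribution coefficient (>= 1).
#' @param nucleus_shape currently only `"sphere"`.
#' @return list of class `stereology_params`.
#' @export
stereology_params <- function(beta = 1.38, k = 1.0,
                              nucleus_shape = c("sphere")) {
  assert_scalar(beta, "beta", lo = 1)
  assert_scalar(k, "k", lo = 1)
  nucleus_shape <- match.arg(nucleus_shape)
  structure(list(beta = beta, k = k, nucleus_shape = nucleus_shape),
            class = "stereology_params")
}

#' Glomerular tuft volume from its profile area
#'
#' Weibel-Gomez estimator `V = (beta / k) * A^(3/2)`.
#'
#' @param tuft_area_um2 profile area A (um^2, >= 0); vectorised.
#' @param params a [stereology_params()].
#' @return volume in um^3.
#' @export
tuft_volume <- function(tuft_area_um2, params = stereology_params()) {
  assert_that(all(is.finite(tuft_area_um2)) && all(tuft_area_um2 >= 0),
              "tuft area must be nonnegative")
  (params$beta / params$k) * tuft_area_um2^1.5
}

#' Mean caliper diameter of spherical nuclei from mean profile area
#'
#' For spheres cut by uniformly random planes the mean profile area is
#' `(2/3) pi R^2`; inverting gives `R = sqrt(3 a / (2 pi))` and the mean
#' caliper diameter `D = 2 R` (for a sphere the caliper diameter is its
#' diameter).
#'
#' @param mean_nuclear_profile_area_um2 mean section area a (um^2, > 0);
#'   vectorised.
#' @param params a [stereology_params()].
#' @return D in um.
#' @export
caliper_diameter <- function(mean_nuclear_profile_area_um2,
                             params = stereology_params()) {
  assert_that(all(is.finite(mean_nuclear_profile_area_um2)) &&
                all(mean_nuclear_profile_area_um2 > 0),
              "mean nuclear profile area must be positive")
  2 * sqrt(3 * mean_nuclear_profile_area_um2 / (2 * pi))
}

#' Numerical density, volume density and total podocyte count
#'
#' `N_V = N_A / D` (profile count per area over mean caliper diameter),
#' `V_V = A_A` (Delesse principle: areal fraction equals volume
#' fraction), and `N = N_V * V`.
#'
#' @param profile_density_per_um2 N_A, nucleus profiles per um^2 of tuft.
#' @param D mean caliper diameter (um, > 0).
#' @param V tuft volume (um^3, >= 0).
#' @param nuclear_area_fraction A_A in `[0, 1]`.
#' @return data.frame: `numerical_density_per_um3`, `volume_density`,
#'   `total_podocytes`.
#' @export
density_and_count <- function(profile_density_per_um2, D, V,
                              nuclear_area_fraction) {
  assert_that(all(D > 0), "caliper diameter must be positive")
  assert_that(all(V >= 0), "volume must be nonnegative")
  assert_that(all(nuclear_area_fraction >= 0 & nuclear_area_fraction <= 1),
              "nuclear area fraction must be in [0, 1]")
  nv <- profile_density_per_um2 / D
  data.frame(numerical_density_per_um3 = nv,
             volume_density = nuclear_area_fraction,
             total_podocytes = nv * V)
}

#' Stereological extrapolation of a morphometry table
#'
#' Consumes the per-glomerulus output of [compute_morphometrics()] and
#' returns the 3D record per glomerulus.
#'
#' @param morpho data.frame from [compute_morphometrics()].
#' @param params a [stereology_params()].
#' @return data.frame: `glomerulus_id`, `tuft_volume_um3`,
#'   `mean_caliper_diameter_um`, `numerical_density_per_um3`,
#'   `volume_density`, `total_podocytes`. Glomeruli without nuclei get
#'   `NA` diameter and zero density/count.
#' @export
stereology_records <- function(morpho, params = stereology_params()) {
  stopifnot(is.data.frame(morpho))
  V <- tuft_volume(morpho$tuft_area_um2, params)
  D <- ifelse(is.na(morpho$mean_nuclear_area_um2) |
                morpho$mean_nuclear_area_um2 <= 0, NA_real_,
              2 * sqrt(3 * pmax(morpho$mean_nuclear_area_um2, 0) / (2 * pi)))
  na <- morpho$podocyte_count / morpho$tuft_area_um2
  nv <- ifelse(is.na(D), 0, na / D)
  data.frame(glomerulus_id = morpho$glomerulus_id,
             tuft_volume_um3 = V,
             mean_caliper_diameter_um = D,
             numerical_density_per_um3 = nv,
             volume_density = ifelse(is.na(morpho$nuclear_tuft_ratio), 0,
                                     morpho$nuclear_tuft_ratio),
             total_podocytes = nv * V)
}

#' Simulate sectioning of a known sphere population
#'
#' Places `n_spheres` of radius `radius` uniformly in an `L^3` box and
#' cuts the box with `n_sections` horizontal planes at uniform heights
#' within `[radius, L - radius]` (so every section lies fully inside the
#' population). Returns the measured profile density and mean profile
#' area together with the generating truth -- the end-to-end oracle for
#' the stereological estimators.
#'
#' @param radius sphere radius (um).
#' @param n_spheres number of spheres in the box.
#' @param box_um box side L (um); must exceed `2 * radius`.
#' @param n_sections number of random sections.
#' @param seed integer seed.
#' @return list: `profile_density_per_um2` (N_A over all sections),
#'   `mean_profile_area_um2`, `true_count`, `box_volume_um3`,
#'   `true_radius`.
#' @export
simulate_sphere_sections <- function(radius, n_spheres, box_um,
                                     n_sections = 100L, seed = 1L) {
  assert_that(box_um > 2 * radius, "box must exceed the sphere diameter")
  with_rng(seed, {
    cz <- runif(n_spheres, 0, box_um)
    areas <- numeric(0)
    hits <- 0L
    for (s in seq_len(n_sections)) {
      z0 <- runif(1, radius, box_um - radius)
      d <- abs(cz - z0)
      cut <- d < radius
      hits <- hits + sum(cut)
      areas <- c(areas, pi * (radius^2 - d[cut]^2))
    }
    list(profile_density_per_um2 = hits / (n_sections * box_um^2),
         mean_profile_area_um2 = mean(areas),
         true_count = n_spheres,
         box_volume_um3 = box_um^3,
         true_radius = radius)
  })
}
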