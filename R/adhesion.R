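#' Self-locking load angle of a claw tip
#'
#' For a claw tip pressed against a surface asperity at pressure angle
#' `alpha` with friction coefficient `mu`, force balance gives the load
#' angle \deqn{\theta = \arctan\mu - \alpha.} A positive `theta` means the
#' grasp is sustainable (friction self-locks the contact); at
#' `alpha = arctan(mu)` the load angle vanishes and the claw disengages.
#' This closed form is equivalent to the tangent-quotient expression of
#' the force balance wherever the latter is defined, and has no
#' singularity.
#'
#' @param alpha pressure angle (radians, in `[0, pi/2)`).
#' @param mu friction coefficient (>= 0).
#' @return load angle `theta` (radians); vectorised.
#' @export
#' @examples
#' degrees(load_angle(radians(10), 0.5))
load_angle <- function(alpha, mu) {
  stopifnot(all(mu >= 0), all(alpha >= 0), all(alpha < pi / 2))
  atan(mu) - alpha
}

#' Pressure angle for a single-particle contact
#'
#' Geometry of a claw tip (radius `r`) hooked on an isolated particle
#' (radius `R`) embedded to depth `h` in the surface:
#' \deqn{\sin\alpha = (r + h) / (r + R).} At the limit `h = R` the angle is
#' 90 degrees and adhesion is impossible.
#'
#' @param r claw tip radius (length units, > 0).
#' @param R particle radius (same units, > 0).
#' @param h embedding depth in `[0, R]`.
#' @return pressure angle `alpha` (radians); vectorised.
#' @export
#' @examples
#' degrees(pressure_angle_single(1, 1, 0)) # 30
pressure_angle_single <- function(r, R, h) {
  stopifnot(all(r > 0), all(R > 0), all(h >= 0))
  if (any(h > R)) stop_claw("embedding depth h cannot exceed R")
  ratio <- (r + h) / (r + R)
  if (any(ratio > 1)) stop_claw("impossible geometry: (r+h)/(r+R) > 1")
  asin(ratio)
}

#' Pressure angle for contact between two surface particles
#'
#' When neighbouring particles sit closer than `2(R + r)` the tip wedges
#' between two of them; the law of cosines on the contact triangle gives
#' \deqn{\alpha = \arccos\big(d / (2(R + r))\big).}
#'
#' @inheritParams pressure_angle_single
#' @param d centre-to-centre particle spacing, `0 < d <= 2(R + r)`.
#' @return pressure angle `alpha` (radians); vectorised.
#' @export
#' @examples
#' degrees(pressure_angle_double(1, 1, 2)) # 60
pressure_angle_double <- function(r, R, d) {
  stopifnot(all(r > 0), all(R > 0), all(d > 0))
  if (any(d > 2 * (R + r))) {
    stop_claw("d > 2(R+r): particles too far apart, ",
              "use the single-contact model")
  }
  acos(d / (2 * (R + r)))
}

#' Claw-particle adhesion geometry
#'
#' Bundles the geometric and frictional parameters of a grasp and resolves
#' the regime: single-particle contact when `d > 2(R + r)` (pressure angle
#' from the embedding depth), double contact otherwise (pressure angle
#' from the spacing).
#'
#' @inheritParams pressure_angle_single
#' @param d particle spacing; `Inf` (default) forces the single-contact
#'   regime.
#' @param mu friction coefficient (>= 0).
#' @return an `adhesion_geometry` list with fields `r`, `R`, `d`, `h`,
#'   `mu`, `regime`, `alpha`.
#' @export
#' @examples
#' g <- adhesion_geometry(r = 0.1, R = 1, h = 0.2, mu = 0.5)
#' can_attach(g)
adhesion_geometry <- function(r, R, h = 0, d = Inf, mu = 0.5) {
  check_number(mu, "mu", lower = 0)
  regime <- if (d > 2 * (R + r)) "single" else "double"
  alpha <- if (regime == "single") {
    pressure_angle_single(r, R, h)
  } else {
    pressure_angle_double(r, R, d)
  }
  structure(
    list(r = r, R = R, d = d, h = h, mu = mu, regime = regime,
         alpha = alpha),
    class = "adhesion_geometry"
  )
}

#' Can the claw attach?
#'
#' Attachment requires self-locking: `alpha < arctan(mu)` strictly, i.e. a
#' positive load angle. At the boundary the claw cannot self-lock and
#' disengages.
#'
#' @param geometry an [adhesion_geometry()], or a pressure angle in
#'   radians if `mu` is supplied.
#' @param mu friction coefficient (only when `geometry` is an angle).
#' @return logical.
#' @export
can_attach <- function(geometry, mu = NULL) {
  if (inherits(geometry, "adhesion_geometry")) {
    alpha <- geometry$alpha
    mu <- geometry$mu
  } else {
    alpha <- geometry
    if (is.null(mu)) stop_claw("mu is required with a bare angle")
  }
  load_angle(alpha, mu) > 0
}

#' Two-contact force distribution
#'
#' Static equilibrium of a claw tip wedged between two particles under a
#' driving force `F` applied at load angle `theta` from the vertical.
#' With horizontal/vertical components `Fp = F sin(theta)`,
#' `Fv = F cos(theta)` and friction fully mobilised (`Ff = mu N` at each
#' contact), the contact normals follow from the linear system
#' \deqn{F_p = (N_1 - N_2)(\mu\cos\alpha - \sin\alpha), \quad
#'       F_v = (N_1 + N_2)(\mu\sin\alpha + \cos\alpha).}
#' The chained closed form in terms of `k = N1/N2` is algebraically
#' equivalent and retained as a cross-check in the test-suite; the linear
#' solve avoids its sign ambiguity around `k = 0`. Past the limit load
#' angle `N1` goes negative: it is reported with its reversed sign and
#' `regime = "upper_contact"` (the upper particle carries the grasp), not
#' clamped.
#'
#' @param F driving force (N, >= 0).
#' @param theta load angle (radians).
#' @param alpha pressure angle (radians, in `[0, pi/2)`).
#' @param mu friction coefficient (>= 0), with `tan(alpha) != mu` (the
#'   friction-cone boundary is singular).
#' @return one-row tibble of class `force_balance` with columns `F`,
#'   `theta`, `alpha`, `mu`, `Fp`, `Fv`, `N1`, `N2`, `Ff1`, `Ff2`, `Fp1`,
#'   `Fv1`, `Fp2`, `Fv2`, `k`, `m`, `regime`.
#' @export
#' @examples
#' force_distribution(3, radians(10), radians(45), 0.5)
force_distribution <- function(F, theta, alpha, mu) {
  check_number(F, "F", lower = 0)
  check_number(theta, "theta")
  check_number(alpha, "alpha", 0, pi / 2)
  check_number(mu, "mu", lower = 0)
  cpa <- mu * cos(alpha) - sin(alpha)
  cva <- mu * sin(alpha) + cos(alpha)
  if (abs(cpa) < 1e-12) {
    stop_claw("singular geometry: mu*cos(alpha) = sin(alpha) ",
              "(friction-cone boundary)")
  }
  Fp <- F * sin(theta)
  Fv <- F * cos(theta)
  A <- Fp / cpa           # N1 - N2
  B <- Fv / cva           # N1 + N2
  N1 <- (A + B) / 2
  N2 <- (B - A) / 2
  k <- N1 / N2
  tibble::new_tibble(
    tibble::tibble(
      F = F, theta = theta, alpha = alpha, mu = mu,
      Fp = Fp, Fv = Fv, N1 = N1, N2 = N2,
      Ff1 = mu * N1, Ff2 = mu * N2,
      Fp1 = N1 * cpa, Fv1 = N1 * cva,
      Fp2 = -N2 * cpa, Fv2 = N2 * cva,
      k = k, m = 1 / k,
      regime = dplyr::case_when(
        N1 < 0 ~ "upper_contact",
        N1 == 0 ~ "limit",
        TRUE ~ "two_contact"
      )
    ),
    class = "force_balance"
  )
}

#' Limit load angle at which the lower contact unloads
#'
#' The load angle where `N1 = 0` (the numerator root of the force-ratio
#' expression): \deqn{\theta_{lim} = \arctan\frac{\tan\alpha - \mu}
#' {1 + \mu\tan\alpha}.} Beyond it the upper particle is the sole support.
#' Requires `tan(alpha) > mu`; otherwise `N1` stays positive for all
#' upward load angles and no limit exists.
#'
#' @inheritParams force_distribution
#' @return limit angle (radians).
#' @export
#' @examples
#' degrees(limit_load_angle(radians(45), 0.5)) # 18.43
limit_load_angle <- function(alpha, mu) {
  check_number(alpha, "alpha", 0, pi / 2)
  check_number(mu, "mu", lower = 0)
  if (tan(alpha) <= mu) {
    stop_claw("no positive root: requires tan(alpha) > mu")
  }
  atan((tan(alpha) - mu) / (1 + mu * tan(alpha)))
}

#' Parameter sweeps over the adhesion models
#'
#' Tabulates the characteristic relationships of the grasp models:
#' \describe{
#'   \item{`theta_vs_alpha_mu`}{load angle over a (pressure angle,
#'     friction) grid.}
#'   \item{`alpha_vs_R_over_r`}{single-contact pressure angle over
#'     (R/r, h/R).}
#'   \item{`alpha_vs_d_R_r`}{double-contact pressure angle over
#'     (d/R, R/r).}
#'   \item{`forces_vs_theta`}{two-contact force distribution over the load
#'     angle at fixed `alpha`, `mu`, `F`.}
#' }
#' Rows whose parameters hit a singularity (friction-cone boundary,
#' impossible geometry) are flagged in the `singular` column rather than
#' aborting the sweep. Angles in the returned tables are degrees.
#'
#' @param relationship which table to build.
#' @param alpha_deg,mu,theta_deg,R_over_r,h_over_R,d_over_R grids; sensible
#'   defaults cover the worked-example ranges.
#' @param F driving force (N) for `forces_vs_theta`.
#' @return tibble of class `adhesion_sweep` with attribute `relationship`.
#' @export
#' @examples
#' sw <- adhesion_sweep("forces_vs_theta", alpha_deg = 45, mu = 0.5, F = 3)
#' sw[which.min(abs(sw$N1)), "theta_deg"]
adhesion_sweep <- function(relationship = c("theta_vs_alpha_mu",
                                            "alpha_vs_R_over_r",
                                            "alpha_vs_d_R_r",
                                            "forces_vs_theta"),
                           alpha_deg = seq(0, 85, by = 5),
                           mu = c(0.25, 0.5, 0.75, 1),
                           theta_deg = seq(0, 90, by = 1),
                           R_over_r = seq(1, 20, by = 0.5),
                           h_over_R = c(0.1, 0.3, 0.5, 0.8),
                           d_over_R = seq(0.2, 2, by = 0.1),
                           F = 3) {
  relationship <- match.arg(relationship)
  tab <- switch(relationship,
    theta_vs_alpha_mu = tidyr::expand_grid(alpha_deg = alpha_deg, mu = mu) |>
      dplyr::mutate(
        theta_deg = degrees(load_angle(radians(.data$alpha_deg), .data$mu)),
        singular = FALSE
      ),
    alpha_vs_R_over_r = tidyr::expand_grid(
      R_over_r = R_over_r, h_over_R = h_over_R
    ) |>
      dplyr::mutate(
        alpha_deg = degrees(pressure_angle_single(
          r = 1, R = .data$R_over_r, h = .data$h_over_R * .data$R_over_r
        )),
        singular = FALSE
      ),
    alpha_vs_d_R_r = tidyr::expand_grid(
      d_over_R = d_over_R, R_over_r = R_over_r
    ) |>
      dplyr::mutate(
        alpha_deg = degrees(pressure_angle_double(
          r = 1, R = .data$R_over_r, d = .data$d_over_R * .data$R_over_r
        )),
        singular = FALSE
      ),
    forces_vs_theta = {
      stopifnot(length(alpha_deg) == 1, length(mu) == 1)
      purrr::map_dfr(theta_deg, function(th) {
        row <- tryCatch(
          force_distribution(F, radians(th), radians(alpha_deg), mu),
          clawmech_error = function(e) NULL
        )
        if (is.null(row)) {
          tibble::tibble(theta_deg = th, singular = TRUE)
        } else {
          dplyr::mutate(
            dplyr::select(row, -"theta", -"alpha"),
            theta_deg = th, alpha_deg = alpha_deg, singular = FALSE,
            .before = 1
          )
        }
      })
    }
  )
  structure(tab,
    relationship = relationship,
    class = c("adhesion_sweep", class(tab))
  )
}
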