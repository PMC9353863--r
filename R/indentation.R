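#' Oliver-Pharr analysis configuration
#'
#' Geometry and material constants of the indenter system. `beta` is the
#' indenter geometry constant (1.034 for a Berkovich tip), `epsilon` the
#' contact-depth intercept factor (0.75 for power-law unloading), and
#' `area_coefficient` the ideal projected-area coefficient
#' (`A_c = 24.56 h_c^2` for a perfect Berkovich). An optional first-order
#' tip-rounding correction adds a spherical-cap term
#' `2 pi tip_radius h_c` to the area.
#'
#' @param beta geometry constant (> 0).
#' @param epsilon contact-depth intercept factor (> 0).
#' @param area_coefficient ideal area coefficient (dimensionless).
#' @param tip_radius indenter tip radius (m).
#' @param tip_correction logical; apply the first-order rounding term.
#' @param E_i indenter Young's modulus (Pa); diamond, 1140 GPa.
#' @param nu_i indenter Poisson ratio; diamond, 0.07.
#' @param nu specimen Poisson ratio.
#' @param unload_fit_fraction top fraction of the unloading branch used in
#'   the power-law fit.
#' @return an `indentation_config` list.
#' @export
indentation_config <- function(beta = 1.034, epsilon = 0.75,
                               area_coefficient = 24.56,
                               tip_radius = 200e-9, tip_correction = FALSE,
                               E_i = 1140e9, nu_i = 0.07, nu = 0.3,
                               unload_fit_fraction = 0.5) {
  check_number(beta, "beta", 0, strict_lower = TRUE)
  check_number(epsilon, "epsilon", 0, strict_lower = TRUE)
  check_number(area_coefficient, "area_coefficient", 0, strict_lower = TRUE)
  check_number(nu, "nu", 0, 0.5)
  check_number(nu_i, "nu_i", 0, 0.5)
  check_number(unload_fit_fraction, "unload_fit_fraction", 0.05, 1)
  structure(
    list(beta = beta, epsilon = epsilon,
         area_coefficient = area_coefficient, tip_radius = tip_radius,
         tip_correction = tip_correction, E_i = E_i, nu_i = nu_i, nu = nu,
         unload_fit_fraction = unload_fit_fraction),
    class = "indentation_config"
  )
}

# split a record without a segment column at the peak-load plateau
split_indentation_segments <- function(curve, tol_frac = 1e-3) {
  P <- curve$load_mN
  peak <- max(P)
  at_peak <- P >= peak * (1 - tol_frac)
  first_peak <- which(at_peak)[1]
  last_peak <- rev(which(at_peak))[1]
  seg <- rep("unloading", length(P))
  seg[seq_len(first_peak)] <- "loading"
  if (last_peak > first_peak) seg[(first_peak + 1):last_peak] <- "hold"
  dplyr::mutate(curve, segment = seg)
}

#' Fit the unloading branch of an indentation curve
#'
#' Levenberg-Marquardt fit of the power law \eqn{P = B (h_d - h_f)^m} to
#' the top `unload_fit_fraction` of the unloading data (by load). The
#' contact stiffness is the analytic slope at the maximum displacement,
#' \eqn{S = m B (h_{max} - h_f)^{m-1}}. An exponent outside `[1, 3]` or a
#' non-convergent fit is reported as failure.
#'
#' @param curve tibble with `load_mN`, `displacement_nm` and optionally a
#'   `segment` column (otherwise segments are split at the peak-load
#'   plateau).
#' @param config an [indentation_config()].
#' @return list with `S` (N/m), `h_f` (m), `m`, `B`, `h_max` (m),
#'   `P_max` (N), `converged`.
#' @export
fit_unloading <- function(curve, config = indentation_config()) {
  stopifnot(is.data.frame(curve))
  if (!"segment" %in% names(curve)) {
    curve <- split_indentation_segments(curve)
  }
  un <- dplyr::filter(curve, .data$segment == "unloading")
  if (nrow(un) < 10) stop_claw("unloading segment has fewer than 10 samples")
  P <- un$load_mN * 1e-3
  h <- un$displacement_nm * 1e-9
  # reject branches that rise rather than unload; small upward jitter from
  # load-cell noise is tolerated
  if (P[length(P)] > P[1] || any(diff(P) > 0.1 * max(P))) {
    stop_claw("unloading load is not monotone non-increasing")
  }
  # peak load from the hold-plateau average when one exists: the maximum
  # of a noisy channel is upward-biased
  P_max <- if (any(curve$segment == "hold")) {
    mean(curve$load_mN[curve$segment == "hold"]) * 1e-3
  } else {
    max(curve$load_mN) * 1e-3
  }
  h_max <- max(curve$displacement_nm) * 1e-9 # peak depth sits on the hold

  keep <- P >= (1 - config$unload_fit_fraction) * P_max
  # fit in instrument units (mN, nm) so the optimizer sees O(1) scales
  P_fit <- P[keep] * 1e3
  h_fit <- h[keep] * 1e9

  # profile h_f: for a trial residual depth the model is linear in
  # log-space, so a 1-D search gives a near-exact start for the LM polish
  span <- max(h_fit) - min(h_fit)
  loglog_sse <- function(h_f) {
    lx <- log(h_fit - h_f)
    ly <- log(pmax(P_fit, 1e-12))
    sum(stats::lm.fit(cbind(1, lx), ly)$residuals^2)
  }
  opt <- stats::optimize(loglog_sse,
                         lower = min(h_fit) - 10 * span,
                         upper = min(h_fit) - 1e-6 * span)
  h_f0 <- opt$minimum
  cf0 <- stats::lm.fit(cbind(1, log(h_fit - h_f0)),
                       log(pmax(P_fit, 1e-12)))$coefficients
  m0 <- min(max(cf0[[2]], 0.6), 3.9)
  B0 <- exp(cf0[[1]])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P_fit ~ B * (h_fit - h_f)^m,
      start = list(B = B0, h_f = h_f0, m = m0),
      lower = c(0, -Inf, 0.5), upper = c(Inf, min(h_fit) - 1e-9, 4),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(S = NA_real_, h_f = NA_real_, m = NA_real_, B = NA_real_,
                h_max = h_max, P_max = P_max, converged = FALSE))
  }
  cf <- stats::coef(fit)
  conv <- cf[["m"]] >= 1 && cf[["m"]] <= 3
  m_hat <- cf[["m"]]
  h_f <- cf[["h_f"]] * 1e-9                      # back to SI
  B <- cf[["B"]] * 1e-3 * (1e9)^m_hat            # mN/nm^m -> N/m^m
  S <- m_hat * B * (h_max - h_f)^(m_hat - 1)
  list(S = S, h_f = h_f, m = m_hat, B = B,
       h_max = h_max, P_max = P_max, converged = conv)
}

#' Projected contact area
#'
#' Contact depth \eqn{h_c = h_{max} - \varepsilon P_{max}/S}, then the
#' ideal Berkovich area \eqn{A_c = 24.56 h_c^2} (plus the optional
#' first-order tip-rounding term).
#'
#' @param h_max maximum indentation depth (m).
#' @param P_max peak load (N).
#' @param S unloading stiffness (N/m, > 0).
#' @param config an [indentation_config()].
#' @return projected contact area (m^2).
#' @export
contact_area <- function(h_max, P_max, S, config = indentation_config()) {
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S <= 0) {
    stop_claw("S must be a single positive stiffness")
  }
  h_c <- h_max - config$epsilon * P_max / S
  if (h_c <= 0) {
    stop_claw("contact depth is not positive: ",
              "incompatible stiffness/depth combination")
  }
  A <- config$area_coefficient * h_c^2
  if (config$tip_correction) A <- A + 2 * pi * config$tip_radius * h_c
  A
}

#' Indentation hardness
#'
#' `H = P_max / A_c`.
#'
#' @param P_max peak load (N).
#' @param A_c projected contact area (m^2, > 0).
#' @return hardness (Pa).
#' @export
hardness <- function(P_max, A_c) {
  stopifnot(all(A_c > 0))
  P_max / A_c
}

#' Reduced modulus from stiffness and contact area
#'
#' \deqn{E_r = \frac{\sqrt{\pi}\,S}{2\beta\sqrt{A_c}}.}
#'
#' @param S unloading stiffness (N/m).
#' @param A_c projected contact area (m^2).
#' @param beta indenter geometry constant.
#' @return reduced modulus (Pa).
#' @export
reduced_modulus <- function(S, A_c, beta = 1.034) {
  stopifnot(all(S > 0), all(A_c > 0))
  sqrt(pi) * S / (2 * beta * sqrt(A_c))
}

#' Specimen modulus from the reduced modulus
#'
#' Inverts the series-compliance relation
#' \deqn{1/E_r = (1-\nu^2)/E + (1-\nu_i^2)/E_i} for the specimen Young's
#' modulus `E`. Requires the specimen compliance to be positive, i.e.
#' `E_r < E_i / (1 - nu_i^2)`.
#'
#' @param E_r reduced modulus (Pa).
#' @param nu specimen Poisson ratio.
#' @param nu_i indenter Poisson ratio.
#' @param E_i indenter modulus (Pa).
#' @return specimen modulus (Pa).
#' @export
#' @examples
#' specimen_modulus(1e9) / 1e9
specimen_modulus <- function(E_r, nu = 0.3, nu_i = 0.07, E_i = 1140e9) {
  stopifnot(all(E_r > 0))
  comp <- 1 / E_r - (1 - nu_i^2) / E_i
  if (any(comp <= 0)) {
    stop_claw("E_r too high: specimen compliance would be non-positive")
  }
  (1 - nu^2) / comp
}

#' Oliver-Pharr analysis of one load-displacement record
#'
#' Runs the full chain: unloading power-law fit, contact depth and area,
#' hardness, reduced modulus, and specimen modulus. Both the reduced and
#' the specimen modulus are reported, since summary conventions differ on
#' which one "modulus" means.
#'
#' @param curve tibble with `time_s`, `load_mN`, `displacement_nm`,
#'   optional `segment` and `condition` columns.
#' @param config an [indentation_config()].
#' @return one-row tibble of class `indentation_result`: `P_max_mN`,
#'   `h_max_nm`, `h_c_nm`, `S_N_per_m`, `A_c_um2`, `H_GPa`, `Er_GPa`,
#'   `E_GPa`, `m`, `h_f_nm`, `condition`, `converged`.
#' @export
#' @examples
#' res <- analyze_indentation(generate_indentation_curve(0.2, 1.2))
#' res$H_GPa
analyze_indentation <- function(curve, config = indentation_config()) {
  fit <- fit_unloading(curve, config)
  if (!isTRUE(fit$converged)) {
    stop_claw("unloading fit failed or exponent out of range")
  }
  A_c <- contact_area(fit$h_max, fit$P_max, fit$S, config)
  h_c <- fit$h_max - config$epsilon * fit$P_max / fit$S
  H <- hardness(fit$P_max, A_c)
  E_r <- reduced_modulus(fit$S, A_c, config$beta)
  E <- specimen_modulus(E_r, config$nu, config$nu_i, config$E_i)
  cond <- if ("condition" %in% names(curve)) curve$condition[1] else NA
  tibble::new_tibble(
    tibble::tibble(
      P_max_mN = fit$P_max * 1e3, h_max_nm = fit$h_max * 1e9,
      h_c_nm = h_c * 1e9, S_N_per_m = fit$S, A_c_um2 = A_c * 1e12,
      H_GPa = H / 1e9, Er_GPa = E_r / 1e9, E_GPa = E / 1e9,
      m = fit$m, h_f_nm = fit$h_f * 1e9,
      condition = cond, converged = fit$converged
    ),
    class = "indentation_result"
  )
}

#' @export
tidy.indentation_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), dplyr::where(is.numeric)),
    dplyr::everything(), names_to = "term", values_to = "estimate"
  )
}

#' @export
glance.indentation_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("H_GPa", "Er_GPa", "E_GPa", "converged")]
}

#' Summarise indentation results by hydration condition
#'
#' Mean and SD of hardness and modulus per condition, plus dry/wet ratios
#' of the means rounded to two decimals (the convention used when
#' comparing hydrated and desiccated cuticle).
#'
#' @param results tibble of [analyze_indentation()] rows (bindable), with
#'   a `condition` column; at least two rows per condition.
#' @param modulus which modulus column the summary ratio uses.
#' @return list with `by_condition` (tibble of means and SDs) and
#'   `ratios` (tibble `hardness_ratio`, `modulus_ratio`), or only the
#'   per-condition table when fewer than two conditions are present.
#' @export
#' @examples
#' res <- dplyr::bind_rows(
#'   analyze_indentation(generate_indentation_curve(0.197, 1.105)),
#'   analyze_indentation(generate_indentation_curve(0.197, 1.105)),
#'   analyze_indentation(generate_indentation_curve(0.071, 0.693,
#'                                                  condition = "wet")),
#'   analyze_indentation(generate_indentation_curve(0.071, 0.693,
#'                                                  condition = "wet"))
#' )
#' summarize_indentation(res)$ratios
summarize_indentation <- function(results,
                                  modulus = c("Er_GPa", "E_GPa")) {
  modulus <- match.arg(modulus)
  stopifnot(is.data.frame(results), "condition" %in% names(results))
  counts <- dplyr::count(results, .data$condition)
  if (any(counts$n < 2)) {
    stop_claw("need at least 2 results per condition for a SD")
  }
  by_cond <- results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      H_mean_GPa = mean(.data$H_GPa), H_sd_GPa = stats::sd(.data$H_GPa),
      Er_mean_GPa = mean(.data$Er_GPa), Er_sd_GPa = stats::sd(.data$Er_GPa),
      E_mean_GPa = mean(.data$E_GPa), E_sd_GPa = stats::sd(.data$E_GPa),
      .groups = "drop"
    )
  out <- list(by_condition = by_cond)
  if (all(c("dry", "wet") %in% by_cond$condition)) {
    dry <- by_cond[by_cond$condition == "dry", ]
    wet <- by_cond[by_cond$condition == "wet", ]
    mcol <- if (modulus == "Er_GPa") "Er_mean_GPa" else "E_mean_GPa"
    mod_dry <- dry[[mcol]]
    mod_wet <- wet[[mcol]]
    out$ratios <- tibble::tibble(
      hardness_ratio = round(dry$H_mean_GPa / wet$H_mean_GPa, 2),
      modulus_ratio = round(mod_dry / mod_wet, 2)
    )
  }
  out
}
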