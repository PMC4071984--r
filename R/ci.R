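#' F-distribution threshold for profile (grid-search) confidence regions
#'
#' A perturbed flux value is inside the `alpha` confidence interval while
#' the reoptimized SSD stays below
#' `phi_res * (1 + F_alpha(1, n - p) / (n - p))`, where `n` is the number
#' of independent data points and `p` the number of free fluxes.
#'
#' @param phi_res minimized SSD of the unconstrained fit.
#' @param n independent data points: each fitted MDV contributes its
#'   length minus one (the unit-sum constraint removes one).
#' @param p number of free fluxes.
#' @param alpha confidence level (default 0.95).
#' @return the SSD threshold.
#' @export
ci_threshold <- function(phi_res, n, p, alpha = 0.95) {
  stopifnot(phi_res >= 0, alpha > 0, alpha < 1)
  if (n <= p)
    stop("model not identifiable for an F-based interval: n <= p", call. = FALSE)
  phi_res * (1 + qf(alpha, 1, n - p) / (n - p))
}

#' Grid-search confidence interval for one flux
#'
#' Profiles the fitting objective along one reaction: the flux is fixed at
#' `v_opt + d`, all remaining free fluxes are reoptimized (warm-started
#' from the neighboring solution), and `|d|` is grown geometrically in
#' each direction until the reoptimized SSD crosses the
#' [ci_threshold()]; the crossing is then located by bisection.  The
#' range of fixed values whose SSD stays below the threshold is the
#' confidence interval.
#'
#' @param fit an [fit_fluxes()] result (must not have failed to converge).
#' @param flux_id the reaction to profile; must not be a predetermined
#'   flux.
#' @param alpha confidence level.
#' @param d0_frac,d0_min initial perturbation: `max(d0_frac * |v_opt|,
#'   d0_min)`.
#' @param growth geometric growth factor of the perturbation.
#' @param tol relative bisection tolerance on the interval endpoints.
#' @param flux_cap search limit; a side whose SSD never crosses the
#'   threshold before the cap is flagged unbounded.  Defaults to
#'   `5 * max(v_opt)` above and 0 below (irreversible reactions).
#' @param max_iter_refit Levenberg-Marquardt iteration cap per
#'   reoptimization.
#' @return object of class `mfa_ci`: `lower`, `upper`, `threshold`,
#'   per-side `unbounded` flags, and the `profile` table of
#'   (value, reoptimized SSD) pairs.
#' @export
grid_search_ci <- function(fit, flux_id, alpha = 0.95,
                           d0_frac = 0.01, d0_min = 1e-4, growth = 2,
                           tol = 1e-4, flux_cap = NULL,
                           max_iter_refit = 100L) {
  stopifnot(inherits(fit, "mfa_fit"))
  if (!flux_id %in% names(fit$v_opt))
    stop("unknown flux id ", flux_id, call. = FALSE)
  if (flux_id %in% names(fit$model$fixed_fluxes))
    stop(flux_id, " is a predetermined flux: no interval to profile",
         call. = FALSE)
  threshold <- ci_threshold(fit$phi, fit$n, fit$p, alpha)
  v0 <- unname(fit$v_opt[flux_id])
  cap <- if (is.null(flux_cap)) max(5 * max(fit$v_opt), v0 + 1) else flux_cap

  profile <- data.frame(value = v0, phi = fit$phi)
  refit_at <- function(value, warm_v) {
    basis2 <- tryCatch(flux_basis(fit$model, fix_extra = setNames(value, flux_id)),
                       error = function(e) NULL)
    if (is.null(basis2)) return(list(phi = Inf, v = warm_v))
    u0 <- as.numeric(crossprod(basis2$K, warm_v - basis2$vp))
    if (min(basis2$vp + as.numeric(basis2$K %*% u0)) < -1e-9) {
      v_alt <- tryCatch(generate_initial_flux(fit$model, basis = basis2),
                        error = function(e) NULL)
      if (is.null(v_alt)) return(list(phi = Inf, v = warm_v))
      u0 <- as.numeric(crossprod(basis2$K, v_alt - basis2$vp))
    }
    res <- lm_minimize(fit$objective, basis2, u0,
                       max_iter = max_iter_refit,
                       lambda0 = fit$controls$lambda0,
                       ftol = fit$controls$ftol, gtol = fit$controls$gtol)
    profile <<- rbind(profile, data.frame(value = value, phi = res$phi))
    res
  }

  one_side <- function(sgn) {
    d <- max(d0_frac * abs(v0), d0_min)
    inside <- v0; inside_v <- fit$v_opt
    outside <- NA_real_; unbounded <- FALSE
    repeat {
      val <- v0 + sgn * d
      clamped <- FALSE
      if (sgn < 0 && val < 0) { val <- 0; clamped <- TRUE }
      if (sgn > 0 && val > cap) { val <- cap; clamped <- TRUE }
      r <- refit_at(val, inside_v)
      if (r$phi > threshold) { outside <- val; break }
      inside <- val; inside_v <- r$v
      if (clamped) { unbounded <- sgn > 0; break }  # hit 0 (hard bound) or cap
      d <- d * growth
    }
    if (is.na(outside)) return(list(bound = inside, unbounded = unbounded))
    while (abs(outside - inside) > tol * max(abs(v0), 1)) {
      mid <- (outside + inside) / 2
      r <- refit_at(mid, inside_v)
      if (r$phi > threshold) outside <- mid
      else { inside <- mid; inside_v <- r$v }
    }
    list(bound = (inside + outside) / 2, unbounded = FALSE)
  }

  up <- one_side(+1)
  lo <- one_side(-1)
  structure(list(flux_id = flux_id, alpha = alpha,
                 lower = lo$bound, upper = up$bound,
                 threshold = threshold,
                 unbounded = c(lower = lo$unbounded, upper = up$unbounded),
                 v_opt = v0,
                 profile = profile[order(profile$value), ]),
            class = "mfa_ci")
}

#' @export
print.mfa_ci <- function(x, ...) {
  cat("<mfa_ci> ", x$flux_id, ": ", format(100 * x$alpha), "% CI [",
      format(x$lower, digits = 6), ", ", format(x$upper, digits = 6),
      "] around ", format(x$v_opt, digits = 6),
      " (SSD threshold ", format(x$threshold, digits = 6), ")\n", sep = "")
  if (any(x$unbounded))
    cat("  note: ", paste(names(x$unbounded)[x$unbounded], collapse = " and "),
        " side hit the search cap before crossing the threshold\n", sep = "")
  invisible(x)
}
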