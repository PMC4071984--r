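#' Free-flux parameterization of the steady-state constraints
#'
#' Expresses every feasible flux vector as `v = v_p + K u`, where `v_p` is
#' a particular solution of the equality constraints (`S v = 0` plus the
#' predetermined fluxes) and the orthonormal columns of `K` span their
#' null space.  The fit then searches the unconstrained coordinates `u`,
#' so stoichiometric feasibility is exact by construction.
#'
#' @param model an `mfa_model` with `fixed_fluxes` set.
#' @param fix_extra optional named numeric vector of additional flux
#'   equality constraints (used by the grid-search profiler to pin one
#'   flux).
#' @return list with `vp` (particular solution, named), `K` (nullspace
#'   basis, fluxes x p), `p` (number of free fluxes), `Aeq`, `beq`.
#' @export
flux_basis <- function(model, fix_extra = NULL) {
  fixed <- model$fixed_fluxes
  if (length(fix_extra)) fixed <- c(fixed[setdiff(names(fixed), names(fix_extra))],
                                    fix_extra)
  nrx <- length(model$reactions)
  ids <- names(model$reactions)
  E <- matrix(0, length(fixed), nrx,
              dimnames = list(paste0("fix:", names(fixed)), ids))
  for (k in seq_along(fixed)) E[k, match(names(fixed)[k], ids)] <- 1
  Aeq <- rbind(model$S, E)
  rownames(Aeq) <- c(paste0("balance:", rownames(model$S)), rownames(E))
  beq <- c(rep(0, nrow(model$S)), as.numeric(fixed))
  sv <- svd(Aeq, nu = nrow(Aeq), nv = ncol(Aeq))
  tol <- max(dim(Aeq)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  vp <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((t(sv$u[, seq_len(r), drop = FALSE]) %*% beq) / sv$d[seq_len(r)])
  resid <- Aeq %*% vp - beq
  if (max(abs(resid)) > 1e-7 * max(1, max(abs(beq)))) {
    worst <- rownames(Aeq)[which.max(abs(resid))]
    stop("predetermined fluxes are inconsistent with the mass balances ",
         "(largest violation at ", worst, ")", call. = FALSE)
  }
  K <- if (r < ncol(Aeq)) sv$v[, (r + 1L):ncol(Aeq), drop = FALSE]
       else matrix(0, ncol(Aeq), 0)
  vp <- setNames(as.numeric(vp), ids)
  rownames(K) <- ids
  list(vp = vp, K = K, p = ncol(K), Aeq = Aeq, beq = beq)
}

#' Draw a random feasible starting flux distribution
#'
#' Samples the free coordinates uniformly and keeps the first draw whose
#' full flux vector is nonnegative (all reactions are written as
#' irreversible forward/backward pairs), with the predetermined fluxes
#' held exactly.
#'
#' @param model an `mfa_model` with `fixed_fluxes` set.
#' @param seed optional integer seed.
#' @param basis optionally a precomputed [flux_basis()].
#' @param max_tries bounded number of rejection-sampling draws.
#' @return named feasible flux vector with `S v = 0`.
#' @export
generate_initial_flux <- function(model, seed = NULL, basis = NULL,
                                  max_tries = 5000L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(basis)) basis <- flux_basis(model)
  if (basis$p == 0L) {
    v <- basis$vp
    if (min(v) < -1e-9)
      stop("the predetermined fluxes force a negative irreversible flux",
           call. = FALSE)
    return(pmax(v, 0))
  }
  a <- 2 * max(abs(basis$vp), abs(basis$beq), 1)
  for (try in seq_len(max_tries)) {
    u <- runif(basis$p, -a, a)
    v <- basis$vp + as.numeric(basis$K %*% u)
    if (min(v) >= 0) return(setNames(v, names(basis$vp)))
    if (try %% 500L == 0L) a <- a * 0.7  # shrink towards vp if the cone is narrow
  }
  stop("could not draw a nonnegative feasible flux vector; the ",
       "predetermined fluxes may force a negative irreversible flux",
       call. = FALSE)
}

# objective closure: whitened residual vector over all measurement entries
make_objective <- function(net, measurements, labeling,
                           mode = c("stationary", "inst"),
                           pools = NULL, h = 0.01) {
  mode <- match.arg(mode)
  entries <- measurements$entries
  ids <- vapply(entries, function(e) emu_id(emu(e$metabolite, e$atoms)), "")
  if (mode == "inst") {
    times <- sort(unique(vapply(entries, `[[`, 0, "time")))
    if (any(is.na(times))) stop("INST mode requires timed measurements", call. = FALSE)
    tix <- match(vapply(entries, `[[`, 0, "time"), times)
  }
  function(v, detail = FALSE) {
    if (mode == "stationary") {
      sim <- simulate_stationary(net, v, labeling)
      simv <- lapply(ids, function(id) sim[[id]])
    } else {
      traj <- simulate_inst(net, v, labeling, pools, times, h)
      simv <- lapply(seq_along(entries), function(k) traj$states[[tix[k]]][[ids[k]]])
    }
    res <- unlist(lapply(seq_along(entries), function(k) {
      if (is.null(simv[[k]]))
        stop("measured EMU ", ids[k], " is not simulated by this network",
             call. = FALSE)
      (entries[[k]]$mdv - simv[[k]]) / entries[[k]]$sd
    }))
    if (!detail) return(res)
    do.call(rbind, lapply(seq_along(entries), function(k)
      data.frame(fragment = entries[[k]]$fragment,
                 time = entries[[k]]$time,
                 replicate = entries[[k]]$replicate,
                 channel = seq_along(entries[[k]]$mdv) - 1L,
                 observed = entries[[k]]$mdv,
                 simulated = simv[[k]],
                 residual = entries[[k]]$mdv - simv[[k]])))
  }
}

#' Covariance-weighted sum of squared differences
#'
#' Simulates the labeling under the requested mode and evaluates the
#' fitting objective: the sum over sampling points and fragments of
#' squared residuals weighted by the inverse measurement covariance
#' (diagonal of squared measurement SDs).
#'
#' @param net an `emu_network` covering the measured fragments.
#' @param v named flux vector (`S v = 0`).
#' @param measurements an `mfa_measurements` object.
#' @param labeling a [substrate_labeling()].
#' @param mode `"stationary"` or `"inst"`.
#' @param pools,h pool sizes and Euler step (INST mode only).
#' @return list with `phi` (the SSD) and `residuals` (per-channel table).
#' @export
compute_ssd <- function(net, v, measurements, labeling,
                        mode = c("stationary", "inst"), pools = NULL, h = 0.01) {
  obj <- make_objective(net, measurements, labeling, mode, pools, h)
  r <- obj(v)
  list(phi = sum(r^2), residuals = obj(v, detail = TRUE))
}

# Levenberg-Marquardt over the free coordinates u, with trial steps
# clipped to keep every flux nonnegative.
lm_minimize <- function(obj, basis, u0, max_iter = 200L, lambda0 = 1e-3,
                        ftol = 1e-8, gtol = 1e-6) {
  vp <- basis$vp; K <- basis$K; p <- basis$p
  v_of <- function(u) setNames(vp + as.numeric(K %*% u), names(vp))
  phi_of <- function(u) {
    r <- tryCatch(obj(pmax(v_of(u), 0)), error = function(e) NULL)
    if (is.null(r)) return(list(phi = Inf, r = NULL))
    list(phi = sum(r^2), r = r)
  }
  u <- u0
  cur <- phi_of(u)
  if (!is.finite(cur$phi)) return(list(u = u, phi = Inf, converged = FALSE, iter = 0L))
  if (p == 0L)  # fully determined system: nothing to optimize
    return(list(u = u, v = pmax(v_of(u), 0), phi = cur$phi, r = cur$r,
                J = matrix(0, length(cur$r), 0L), converged = TRUE, iter = 0L))
  lambda <- lambda0
  iter <- 0L; converged <- FALSE
  J <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    # forward-difference Jacobian of the whitened residuals
    J <- matrix(0, length(cur$r), p)
    for (i in seq_len(p)) {
      du <- max(1e-6 * abs(u[i]), 1e-8)
      up <- u; up[i] <- up[i] + du
      if (min(v_of(up)) < 0) { up[i] <- u[i] - du; du <- -du }
      rp <- tryCatch(obj(pmax(v_of(up), 0)), error = function(e) NULL)
      if (is.null(rp)) { up[i] <- u[i] + abs(du); du <- abs(du)
                         rp <- obj(pmax(v_of(up), 0)) }
      J[, i] <- (rp - cur$r) / du
    }
    g <- crossprod(J, cur$r)
    if (any(!is.finite(g))) break
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (lambda <= 1e10) {
      M <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), p)
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        # clip the step so that v stays nonnegative
        dv <- as.numeric(K %*% delta)
        vcur <- v_of(u)
        neg <- dv < 0
        alpha <- if (any(neg)) min(1, 0.995 * min(vcur[neg] / -dv[neg])) else 1
        if (alpha > 1e-12) {
          utry <- u + alpha * as.numeric(delta)
          trial <- phi_of(utry)
          if (trial$phi < cur$phi) {
            improvement <- cur$phi - trial$phi
            u <- utry; cur <- trial
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            if (improvement <= ftol * max(cur$phi, 1e-30)) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted || converged) break
  }
  list(u = u, v = pmax(v_of(u), 0), phi = cur$phi, r = cur$r, J = J,
       converged = converged, iter = iter)
}

#' Estimate metabolic fluxes from labeling measurements
#'
#' Minimizes the covariance-weighted SSD between measured and simulated
#' MDVs over the free-flux coordinates by the Levenberg-Marquardt method,
#' keeping `S v = 0` and the predetermined fluxes exact through the
#' null-space parameterization and all fluxes nonnegative by clipping
#' trial steps.  The best of `restarts` random starts is returned.
#'
#' @param model an `mfa_model` with `fixed_fluxes` set.
#' @param measurements an `mfa_measurements` object.
#' @param labeling a [substrate_labeling()].
#' @param mode `"stationary"` or `"inst"`.
#' @param pools named pool-size vector (INST mode).
#' @param h Euler step size in seconds (INST mode).
#' @param restarts number of random starting points.
#' @param seed optional integer seed for the random starts.
#' @param init optional named flux vector used as the first start.
#' @param max_iter,lambda0,ftol,gtol Levenberg-Marquardt controls:
#'   iteration cap, initial damping, relative-SSD and gradient-norm
#'   stopping tolerances.
#' @param net optionally a prebuilt `emu_network`; by default the minimal
#'   network for the measured fragments is constructed.
#' @return object of class `mfa_fit`: optimized fluxes `v_opt`, SSD
#'   `phi`, per-flux standard errors `se`, residual table, convergence
#'   log, free-flux basis, and the data/context needed by
#'   [grid_search_ci()].
#' @export
fit_fluxes <- function(model, measurements, labeling,
                       mode = c("stationary", "inst"),
                       pools = NULL, h = 0.01,
                       restarts = 10L, seed = NULL, init = NULL,
                       max_iter = 200L, lambda0 = 1e-3,
                       ftol = 1e-8, gtol = 1e-6, net = NULL) {
  mode <- match.arg(mode)
  if (!length(model$fixed_fluxes))
    warning("no predetermined fluxes: the fit is scaled only by the data",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(net)) {
    targets <- unique(lapply(measurements$entries,
                             function(e) emu(e$metabolite, e$atoms)))
    net <- build_emu_network(model, targets)
  }
  basis <- flux_basis(model)
  obj <- make_objective(net, measurements, labeling, mode, pools, h)
  n_points <- sum(vapply(measurements$entries,
                         function(e) length(e$mdv) - 1L, 0L))
  if (n_points < basis$p)
    warning("fewer independent data points (", n_points, ") than free fluxes (",
            basis$p, "): the fit is underdetermined", call. = FALSE)

  best <- NULL
  log <- data.frame(restart = integer(0), phi = numeric(0),
                    iter = integer(0), converged = logical(0))
  for (rs in seq_len(restarts)) {
    v0 <- if (rs == 1L && !is.null(init)) flux_vec(names(basis$vp), init)
          else generate_initial_flux(model, basis = basis)
    u0 <- as.numeric(crossprod(basis$K, v0 - basis$vp))
    res <- lm_minimize(obj, basis, u0, max_iter = max_iter,
                       lambda0 = lambda0, ftol = ftol, gtol = gtol)
    log <- rbind(log, data.frame(restart = rs, phi = res$phi,
                                 iter = res$iter, converged = res$converged))
    if (is.null(best) || res$phi < best$phi) best <- res
  }
  if (is.null(best$J)) stop("all restarts failed to evaluate the objective",
                            call. = FALSE)
  # linearized covariance of the free coordinates (residuals are whitened)
  JtJ <- crossprod(best$J)
  cov_u <- tryCatch(chol2inv(chol(JtJ + 1e-12 * diag(basis$p))),
                    error = function(e) matrix(NA_real_, basis$p, basis$p))
  cov_v <- basis$K %*% cov_u %*% t(basis$K)
  se <- setNames(sqrt(pmax(diag(cov_v), 0)), names(basis$vp))

  structure(list(
    v_opt = best$v, u_opt = best$u, phi = best$phi,
    converged = best$converged, iterations = best$iter, restart_log = log,
    se = se, vcov = cov_v, n = n_points, p = basis$p,
    residuals = obj(best$v, detail = TRUE),
    basis = basis, objective = obj,
    model = model, net = net, measurements = measurements,
    labeling = labeling, mode = mode, pools = pools, h = h,
    controls = list(max_iter = max_iter, lambda0 = lambda0,
                    ftol = ftol, gtol = gtol)),
    class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat("<mfa_fit> mode ", x$mode, "; SSD = ", format(x$phi, digits = 6),
      "; converged: ", x$converged, "\n", sep = "")
  cat("  free fluxes p = ", x$p, ", data points n = ", x$n, "\n", sep = "")
  fixed <- names(x$model$fixed_fluxes)
  tab <- data.frame(flux = names(x$v_opt),
                    value = round(x$v_opt, 6),
                    se = round(x$se, 6),
                    fixed = names(x$v_opt) %in% fixed)
  print(tab, row.names = FALSE)
  invisible(x)
}
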