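#' Substrate labeling composition
#'
#' Describes the positional 13C labeling of the carbon sources as a
#' mixture of isotopomer patterns, e.g. 50% \[1-13C\] + 50% \[U-13C\]
#' pyruvate.  Patterns may be bit strings (`"100"`) or the named forms
#' `"1-13C"`, `"1,2-13C"`, `"U-13C"`, `"unlabeled"`.
#'
#' @param spec `data.frame` (or CSV path) with columns `Metabolite`,
#'   `Pattern`, `Fraction`.
#' @param model an `mfa_model`, used to resolve carbon counts for named
#'   patterns and to check pattern lengths.
#' @return an object of class `substrate_labeling`.
#' @export
substrate_labeling <- function(spec, model) {
  if (is.character(spec)) spec <- read.csv(spec, stringsAsFactors = FALSE)
  stopifnot(all(c("Metabolite", "Pattern", "Fraction") %in% names(spec)))
  mix <- list()
  for (met in unique(spec$Metabolite)) {
    rows <- spec[spec$Metabolite == met, , drop = FALSE]
    carb <- model$metabolites$carbons[match(met, model$metabolites$name)]
    if (is.na(carb))
      stop("labeled metabolite ", met, " is not in the model", call. = FALSE)
    pats <- vapply(as.character(rows$Pattern), function(p)
      paste(pattern_bits(p, carb), collapse = ""), "")
    if (any(nchar(pats) != carb))
      stop("labeling pattern length does not match the ", carb,
           " carbons of ", met, call. = FALSE)
    fr <- as.numeric(rows$Fraction)
    if (abs(sum(fr) - 1) > 1e-8)
      stop("labeling fractions of ", met, " must sum to 1", call. = FALSE)
    mix[[met]] <- data.frame(pattern = unname(pats), fraction = fr)
  }
  structure(list(mix = mix), class = "substrate_labeling")
}

# MDV of a source EMU under the given labeling.  Unbalanced (Ind_) carbon
# donors default to the unlabeled distribution unless labeled explicitly.
source_mdv <- function(labeling, met, atoms) {
  mix <- labeling$mix[[met]]
  if (!is.null(mix)) return(mixture_mdv(mix, atoms))
  if (startsWith(met, "Ind_")) return(c(1, rep(0, length(atoms))))
  stop("no labeling defined for source metabolite ", met, call. = FALSE)
}

# numeric A and B for one size level at flux vector v
build_AB <- function(lv, v) {
  n <- length(lv$unknown); m <- length(lv$known)
  A <- matrix(0, n, n)
  B <- matrix(0, n, max(m, 1L))
  dsum <- rowsum(v[lv$diag$f] * lv$diag$w, lv$diag$i)
  ii <- as.integer(rownames(dsum))
  A[cbind(ii, ii)] <- -dsum[, 1]
  if (nrow(lv$A_trip))
    for (r in seq_len(nrow(lv$A_trip)))
      A[lv$A_trip$i[r], lv$A_trip$j[r]] <-
        A[lv$A_trip$i[r], lv$A_trip$j[r]] + lv$A_trip$w[r] * v[lv$A_trip$f[r]]
  if (nrow(lv$B_trip))
    for (r in seq_len(nrow(lv$B_trip)))
      B[lv$B_trip$i[r], lv$B_trip$j[r]] <-
        B[lv$B_trip$i[r], lv$B_trip$j[r]] - lv$B_trip$w[r] * v[lv$B_trip$f[r]]
  list(A = A, B = B)
}

#' Simulate isotopically stationary labeling
#'
#' Solves the EMU cascade size by size: within each size the unknown MDVs
#' satisfy a linear balance whose right-hand side collects carbon-source
#' EMUs and convolutions of smaller, already-solved EMUs.  The result is
#' the steady-state mass distribution of every unknown EMU.
#'
#' @param net an [build_emu_network()] result.
#' @param v named flux vector satisfying `S v = 0`.
#' @param labeling a [substrate_labeling()].
#' @return named list (EMU id -> MDV), class `mdv_set`.
#' @export
simulate_stationary <- function(net, v, labeling) {
  v <- flux_vec(net$flux_ids, v)
  solved <- list()
  for (s in net$sizes) {
    lv <- net$levels[[as.character(s)]]
    asm <- assemble_balance_matrices(net, s, v, labeling, solved)
    Z <- tryCatch(solve(asm$A, asm$B %*% asm$Y),
                  error = function(e)
                    stop("singular EMU balance at size ", s, " (metabolites ",
                         paste(unique(lv$met), collapse = ", "), "): ",
                         conditionMessage(e), call. = FALSE))
    for (i in seq_along(lv$unknown))
      solved[[lv$unknown[i]]] <- as_mdv(Z[i, ])
  }
  structure(solved, class = "mdv_set")
}

#' Extract one MDV from a simulation result
#'
#' @param x an `mdv_set` from [simulate_stationary()] or a
#'   `labeling_trajectory` from [simulate_inst()].
#' @param metabolite metabolite name.
#' @param atoms atom positions of the EMU (default: all carbons present in
#'   the stored ids is not guessed — pass them explicitly).
#' @param time for trajectories, the sampling time to extract.
#' @return numeric MDV.
#' @export
get_mdv <- function(x, metabolite, atoms, time = NULL) {
  id <- emu_id(emu(metabolite, atoms))
  if (inherits(x, "labeling_trajectory")) {
    k <- match(TRUE, abs(x$times - time) < 1e-9)
    if (is.na(k)) stop("time ", time, " not recorded", call. = FALSE)
    md <- x$states[[k]][[id]]
  } else md <- x[[id]]
  if (is.null(md)) stop("EMU ", id, " not present in this result", call. = FALSE)
  md
}

# Build the per-size numeric system consumed by the Euler integrator.
compile_inst_system <- function(net, v, labeling, pools) {
  v <- flux_vec(net$flux_ids, v)
  sizes <- net$sizes
  size_index <- setNames(seq_along(sizes), as.character(sizes))
  spec <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    lv <- net$levels[[as.character(s)]]
    ab <- build_AB(lv, v)
    if (any(diag(ab$A) == 0))
      stop("zero total consumption flux for ",
           paste(unique(lv$met[diag(ab$A) == 0]), collapse = ", "), call. = FALSE)
    m <- length(lv$known)
    Yfix <- matrix(0, max(m, 1L), s + 1L)
    conv <- list()
    for (j in seq_len(m)) {
      sp <- lv$known[[j]]
      if (sp$type == "source") {
        Yfix[j, ] <- source_mdv(labeling, sp$met, sp$atoms)
      } else {
        enc <- lapply(sp$parts, function(p) {
          if (p$type == "source")
            list(kind = 1L, size = 0L, row = 0L,
                 fix = source_mdv(labeling, p$met, p$atoms))
          else {
            lv2 <- net$levels[[as.character(p$size)]]
            list(kind = 0L, size = size_index[[as.character(p$size)]],
                 row = match(p$id, lv2$unknown), fix = numeric(0))
          }
        })
        if (all(vapply(enc, `[[`, 0L, "kind") == 1L)) {
          Yfix[j, ] <- convolve_mdv(enc[[1]]$fix, enc[[2]]$fix)
        } else {
          conv[[length(conv) + 1L]] <- list(
            row = j,
            a_kind = enc[[1]]$kind, a_size = enc[[1]]$size,
            a_row = enc[[1]]$row, a_fix = enc[[1]]$fix,
            b_kind = enc[[2]]$kind, b_size = enc[[2]]$size,
            b_row = enc[[2]]$row, b_fix = enc[[2]]$fix)
        }
      }
    }
    X <- pools[lv$met]
    if (any(is.na(X)) || any(X <= 0))
      stop("missing or non-positive pool size for: ",
           paste(unique(lv$met[is.na(X) | X <= 0]), collapse = ", "),
           call. = FALSE)
    n <- length(lv$unknown)
    Z0 <- matrix(0, n, s + 1L); Z0[, 1] <- 1
    spec[[si]] <- list(A = ab$A, B = ab$B, Yfix = Yfix, conv = conv,
                       invX = 1 / as.numeric(X), Z0 = Z0,
                       unknown = lv$unknown)
  }
  spec
}

#' Simulate an isotopic labeling time course
#'
#' Integrates the pool-size-weighted labeling ODE
#' `dMDV_j/dt = (1/X_j) (sum of inflow fluxes times precursor MDVs -
#' total outflow flux times MDV_j)` for every unknown EMU, starting from
#' the fully unlabeled state at the tracer switch (t = 0).  The solver is
#' fixed-step explicit Euler without adaptive step-size control; after
#' every step each MDV is renormalized to sum 1 to prevent drift.
#' Condensation inflows are convolved from the current state at each step.
#' Sampled states are the Euler grid point landing on (or latest before)
#' each requested time.
#'
#' @param net an [build_emu_network()] result.
#' @param v named flux vector satisfying `S v = 0`.
#' @param labeling a [substrate_labeling()].
#' @param pools named numeric vector of metabolite pool sizes
#'   (amount per biomass, e.g. umol/gDCW), strictly positive for every
#'   metabolite in the network.
#' @param times numeric vector of sampling times (seconds), ascending.
#' @param h Euler step size in the same time unit; must not exceed the
#'   smallest spacing of `times`.  Stiff systems need a smaller `h`.
#' @return object of class `labeling_trajectory`: `times`, `states` (per
#'   time: named list EMU id -> MDV), `h`.
#' @export
simulate_inst <- function(net, v, labeling, pools, times, h) {
  stopifnot(h > 0, length(times) >= 1)
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (length(times) > 1 && h > min(diff(times)) + 1e-12)
    stop("step size h exceeds the smallest sampling interval", call. = FALSE)
  spec <- compile_inst_system(net, v, labeling, pools)
  record <- as.integer(floor(times / h + 1e-9))
  nsteps <- max(record)
  res <- tryCatch(
    euler_inst_cpp(spec, nsteps, h, record),
    error = function(e)
      stop("Euler integration failed (", conditionMessage(e),
           "); the system may be stiff - reduce the step size h",
           call. = FALSE))
  states <- vector("list", length(times))
  for (k in seq_along(times)) {
    st <- list()
    for (si in seq_along(spec)) {
      Z <- res[[k]][[si]]
      for (i in seq_along(spec[[si]]$unknown))
        st[[spec[[si]]$unknown[i]]] <- as.numeric(Z[i, ])
    }
    states[[k]] <- st
  }
  structure(list(times = times, states = states, h = h),
            class = "labeling_trajectory")
}

#' Characteristic times of the labeling dynamics
#'
#' The per-size labeling ODEs are linear with system matrix
#' `diag(1/X) A_s`; because network cycles recycle label, the slowest
#' relaxation mode of these matrices — not the turnover time `X/flux` of
#' any single pool — governs how long the system takes to reach isotopic
#' stationarity.
#'
#' @inheritParams simulate_inst
#' @return list with `turnover` (per unknown EMU, pool size over total
#'   consumption flux) and `relaxation` (slowest mode, the largest
#'   `1 / |Re(lambda)|` over all sizes).
#' @export
labeling_timescales <- function(net, v, pools) {
  v <- flux_vec(net$flux_ids, v)
  turn <- c(); relax <- 0
  for (s in net$sizes) {
    lv <- net$levels[[as.character(s)]]
    ab <- build_AB(lv, v)
    X <- as.numeric(pools[lv$met])
    turn <- c(turn, setNames(-X / diag(ab$A), lv$unknown))
    ev <- eigen(ab$A / X, only.values = TRUE)$values
    relax <- max(relax, 1 / min(abs(Re(ev))))
  }
  list(turnover = turn, relaxation = relax)
}

#' @export
print.labeling_trajectory <- function(x, ...) {
  cat("<labeling_trajectory> ", length(x$states[[1]]), " EMUs at ",
      length(x$times), " times in [", min(x$times), ", ", max(x$times),
      "], h = ", x$h, "\n", sep = "")
  invisible(x)
}
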