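#' Configuration table of the benchmark TCA-cycle model
#'
#' A 16-reaction simplified TCA cycle fed by pyruvate and glutamate, with
#' six biomass drains, an unbalanced CO2 pool, a symmetric succinate, and
#' two reversible steps written as forward/backward pairs (tags 1 and 2 in
#' the `Net flux` column).  This is the standard small benchmark network
#' for carbon-labeling software.
#'
#' @return `data.frame` in [parse_config()] layout.
#' @export
tca_config <- function() {
  data.frame(
    FluxID = paste0("R", 1:16),
    Rxns = c(
      "Subs_PYR_EX -> PYR",
      "PYR -> ACCOA + Ind_CO2",
      "ACCOA + OAA -> IsoCit",
      "IsoCit -> AKG + Ind_CO2",
      "AKG -> Sym_SUC + Ind_CO2",
      "Sym_SUC -> OAA",
      "PYR + Ind_CO2 -> OAA",
      "AKG -> [AKG_B]",
      "OAA -> [OAA_B]",
      "OAA -> [LYS_B]",
      "PYR -> [PYR_B]",
      "PYR -> [LYS_B]",
      "PYR -> [VAL_B]",
      "Subs_GLU_EX -> AKG",
      "OAA -> Sym_SUC",
      "OAA -> PYR + Ind_CO2"),
    `Net flux` = c(0, 0, 0, 0, 0, 1, 2, 0, 0, 0, 0, 0, 0, 0, 1, 2),
    Carbon_transitions = c(
      "abc -> abc",
      "abc -> bc + a",
      "ab + cdef -> fedbac",
      "abcdef -> abcde + f",
      "abcde -> abcd + e",
      "abcd -> abcd",
      "abc + d -> abcd",
      "", "", "", "", "", "",
      "abcde -> abcde",
      "abcd -> abcd",
      "abcd -> abc + d"),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Ground-truth flux distribution of the benchmark experiment
#'
#' A documented feasible flux vector on the TCA model (satisfies
#' `S v = 0`, all fluxes nonnegative): the pyruvate influx R1 and the six
#' drains R8-R13 are the predetermined rates; the glutamate influx R14,
#' the anaplerotic carboxylation R7 and the back-flux R15 of the
#' reversible succinate/oxaloacetate step are the three free fluxes.
#'
#' @return named numeric vector of 16 fluxes (umol/gDCW/s).
#' @export
tca_fluxes <- function() {
  c(R1 = 1, R2 = 1.05, R3 = 1.05, R4 = 1.05, R5 = 1.5, R6 = 1.8,
    R7 = 0.4, R8 = 0.05, R9 = 0.05, R10 = 0.05, R11 = 0.1, R12 = 0.05,
    R13 = 0.15, R14 = 0.5, R15 = 0.3, R16 = 0.75)
}

#' Assemble the complete benchmark experiment
#'
#' Bundles the TCA model, predetermined fluxes, ground-truth flux vector,
#' metabolite pool sizes, substrate labeling (50% \[1-13C\] + 50%
#' \[U-13C\] pyruvate, 100% \[1-13C\] glutamate), measured fragments and
#' the nonstationary sampling schedule (17 samples at 5-second
#' intervals).  Pool sizes are chosen so that the labeling transient
#' spans the sampling window.
#'
#' @param noise_sd Gaussian noise SD added per mass channel (absolute, on
#'   the fractional abundances).
#' @return object of class `mfa_experiment`: `model`, `truth`, `pools`,
#'   `labeling`, `msreac` (stationary fragments), `msreac_inst`
#'   (nonstationary fragments), `components`, `times`, `h`, `noise_sd`.
#' @export
tca_experiment <- function(noise_sd = 0.01) {
  truth <- tca_fluxes()
  fixed <- truth[c("R1", paste0("R", 8:13))]
  model <- parse_config(tca_config(), fixed = fixed)
  labeling <- substrate_labeling(data.frame(
    Metabolite = c("Subs_PYR_EX", "Subs_PYR_EX", "Subs_GLU_EX"),
    Pattern = c("1-13C", "U-13C", "1-13C"),
    Fraction = c(0.5, 0.5, 1)), model)
  pools <- c(PYR = 5, ACCOA = 2.5, IsoCit = 2.5, AKG = 10,
             Sym_SUC = 5, OAA = 5)
  # stationary fragments: precursor skeletons of the measured amino acids
  # (valine <- pyruvate, glutamate/lysine pathway <- AKG/OAA, aspartate <-
  # OAA) plus succinate
  msreac <- data.frame(
    Fragment = c("PYR", "AKG", "SUC", "OAA"),
    Metabolite = c("PYR", "AKG", "Sym_SUC", "OAA"),
    First_atom = 1L, Last_atom = c(3L, 5L, 4L, 4L),
    stringsAsFactors = FALSE)
  msreac_inst <- msreac[msreac$Fragment %in% c("SUC", "OAA"), ]
  components <- data.frame(
    Fragment = msreac$Fragment,
    C = msreac$Last_atom, H = 0L, N = 0L, O = 0L, S = 0L, Si = 0L,
    Skeleton_C = msreac$Last_atom,
    stringsAsFactors = FALSE)
  structure(list(model = model, truth = truth, pools = pools,
                 labeling = labeling, msreac = msreac,
                 msreac_inst = msreac_inst, components = components,
                 times = seq(5, 85, by = 5), h = 0.01,
                 noise_sd = noise_sd,
                 free_fluxes = c("R7", "R14", "R15")),
            class = "mfa_experiment")
}

#' Write the benchmark model bundle to a directory
#'
#' Emits the full plain-text model directory: the configuration worksheet
#' and the auxiliary CSVs (measured fragments, substrate labeling, mass
#' balance, predetermined fluxes, pool sizes, sampling times, fragment
#' compositions, measurement SDs).
#'
#' @param outdir output directory (created if missing).
#' @param noise_sd see [tca_experiment()].
#' @return the `mfa_experiment`, invisibly, with `dir` set.
#' @export
make_tca_bundle <- function(outdir, noise_sd = 0.01) {
  exp <- tca_experiment(noise_sd = noise_sd)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) write.csv(x, file.path(outdir, f), row.names = FALSE)
  w(tca_config(), "Metabolic_network.csv")
  w(exp$msreac, "MSReac.csv")
  w(data.frame(Metabolite = c("Subs_PYR_EX", "Subs_PYR_EX", "Subs_GLU_EX"),
               Pattern = c("1-13C", "U-13C", "1-13C"),
               Fraction = c(0.5, 0.5, 1)), "Substrate.csv")
  w(data.frame(Metabolite = rownames(exp$model$S), Balanced = 1L),
    "Mass_balance.csv")
  fixed <- exp$model$fixed_fluxes
  w(data.frame(FluxID = names(fixed), Value = as.numeric(fixed)), "efflux.csv")
  w(data.frame(Metabolite = names(exp$pools),
               Pool_size = as.numeric(exp$pools)), "Initial_pool.csv")
  w(data.frame(Time = exp$times), "Time_course.csv")
  w(exp$components, "Components.csv")
  w(data.frame(Fragment = exp$msreac$Fragment, SD = noise_sd),
    "Measurement_SD.csv")
  exp$dir <- outdir
  invisible(exp)
}

#' Simulate a measurement dataset from the benchmark experiment
#'
#' Generates mass spectra from the ground-truth fluxes: in stationary
#' mode, `replicates` independent noisy copies of the steady-state MDVs
#' of all stationary fragments; in nonstationary mode, one noisy spectrum
#' of oxaloacetate and succinate per sampling time.  Gaussian noise of
#' the configured SD is added per mass channel (absolute, on the
#' fractions), negative channels are clipped to zero, and each spectrum
#' is renormalized.
#'
#' @param exp an [tca_experiment()] (or [make_tca_bundle()]) object.
#' @param mode `"stationary"` or `"inst"`.
#' @param seed integer seed; the same seed regenerates the identical
#'   dataset (and identical files).
#' @param replicates stationary replicate count (default 17, matching the
#'   nonstationary sampling-point count for like-for-like comparisons).
#' @param noise_sd override the experiment's noise SD (0 gives noiseless
#'   data).
#' @param outdir optional directory; when set, one
#'   `Abundance_list_<k>.csv` per replicate/time point is written.
#' @return an `mfa_measurements` object.
#' @export
simulate_dataset <- function(exp, mode = c("stationary", "inst"),
                             seed = NULL, replicates = 17L,
                             noise_sd = exp$noise_sd, outdir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  msreac <- if (mode == "inst") exp$msreac_inst else exp$msreac
  targets <- msreac_targets(msreac)
  net <- build_emu_network(exp$model, targets)
  ids <- vapply(targets, emu_id, "")

  n_clipped <- 0L
  noisy <- function(md) {
    if (noise_sd > 0) {
      md <- md + rnorm(length(md), 0, noise_sd)
      if (any(md < 0)) {
        n_clipped <<- n_clipped + sum(md < 0)
        md <- pmax(md, 0)
      }
    }
    md / sum(md)
  }
  spectra <- list()   # one data.frame per sampling point / replicate
  if (mode == "stationary") {
    sim <- simulate_stationary(net, exp$truth, exp$labeling)
    for (r in seq_len(replicates))
      spectra[[r]] <- lapply(ids, function(id) noisy(sim[[id]]))
    times <- NULL
  } else {
    traj <- simulate_inst(net, exp$truth, exp$labeling, exp$pools,
                          exp$times, exp$h)
    for (k in seq_along(exp$times))
      spectra[[k]] <- lapply(ids, function(id) noisy(traj$states[[k]][[id]]))
    times <- exp$times
  }
  tabs <- lapply(spectra, function(sp) {
    wmax <- max(vapply(sp, length, 0L))
    tab <- data.frame(Fragment = msreac$Fragment)
    for (c in seq_len(wmax))
      tab[[paste0("M", c - 1L)]] <- vapply(sp, function(x)
        if (c <= length(x)) x[c] else NA_real_, 0)
    tab
  })
  if (n_clipped > 0L)
    message("clipped ", n_clipped, " negative post-noise channel(s) to 0")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(tabs))
      write.csv(tabs[[k]], file.path(outdir,
                sprintf("Abundance_list_%03d.csv", k)), row.names = FALSE)
  }
  load_measurements(tabs, msreac, time_course = times,
                    sd = if (noise_sd > 0) noise_sd else 0.01)
}
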