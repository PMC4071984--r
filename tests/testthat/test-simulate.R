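test_that("MDV convolution matches the exhaustive double sum", {
  expect_equal(convolve_mdv(c(1, 0), c(1, 0)), c(1, 0, 0))
  expect_equal(convolve_mdv(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  set.seed(101)
  for (rep in 1:20) {
    a <- as_mdv(runif(sample(2:6, 1)))
    b <- as_mdv(runif(sample(2:6, 1)))
    brute <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) for (j in seq_along(b))
      brute[i + j - 1L] <- brute[i + j - 1L] + a[i] * b[j]
    expect_equal(convolve_mdv(a, b), brute, tolerance = 1e-12)
  }
})

test_that("labeling passes unchanged through an identity chain", {
  m <- parse_config(chain_config(), fixed = c(R1 = 1))
  lab <- substrate_labeling(
    data.frame(Metabolite = "Subs_S", Pattern = "1", Fraction = 1), m)
  net <- build_emu_network(m, list(emu("B", 1)))
  sim <- simulate_stationary(net, c(R1 = 1, R2 = 1, R3 = 1), lab)
  expect_equal(sim[["A:1"]], c(0, 1))
  expect_equal(sim[["B:1"]], c(0, 1))
})

test_that("every simulated MDV is normalized", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac))
  sim <- simulate_stationary(net, exp$truth, exp$labeling)
  expect_true(all(abs(vapply(sim, sum, 0) - 1) < 1e-9))
  traj <- simulate_inst(net, exp$truth, exp$labeling, exp$pools,
                        times = c(1, 10), h = 0.01)
  for (st in traj$states)
    expect_true(all(abs(vapply(st, sum, 0) - 1) < 1e-12))
})

test_that("EMU cascade equals the exhaustive isotopomer solver on a tiny model", {
  cfg <- data.frame(
    FluxID = c("R1", "R2", "R3", "R4"),
    Rxns = c("Subs_S -> A", "A -> B + Ind_CO2", "A + B -> C", "C -> [C_B]"),
    Carbon_transitions = c("abc -> abc", "abc -> ab + c", "abc + de -> edcba",
                           ""),
    stringsAsFactors = FALSE)
  m <- parse_config(cfg, fixed = c(R1 = 2))
  v <- c(R1 = 2, R2 = 1, R3 = 1, R4 = 1)
  expect_lt(max(abs(m$S %*% v[colnames(m$S)])), 1e-12)
  lab <- substrate_labeling(
    data.frame(Metabolite = "Subs_S", Pattern = c("100", "111"),
               Fraction = c(0.5, 0.5)), m)
  net <- build_emu_network(m, list(emu("C", 1:5)))
  sim <- simulate_stationary(net, v, lab)
  or <- iso_oracle(cfg, v,
                   list(Subs_S = data.frame(pattern = c("100", "111"),
                                            fraction = c(0.5, 0.5))))
  expect_equal(sim[["C:1,2,3,4,5"]], or$mdvs$C, tolerance = 1e-10)
  expect_equal(sim[["B:1,2"]], or$mdvs$B, tolerance = 1e-10)
})

test_that("single-pool relaxation follows the closed-form exponential", {
  m <- parse_config(single_pool_config(), fixed = c(R1 = 1))
  lab <- substrate_labeling(
    data.frame(Metabolite = "Subs_S", Pattern = "1", Fraction = 1), m)
  net <- build_emu_network(m, list(emu("A", 1)))
  v <- c(R1 = 1, R2 = 1); X <- c(A = 2)
  times <- c(1, 2, 5)
  closed <- function(t) {
    md_in <- c(0, 1); md0 <- c(1, 0)
    md_in + (md0 - md_in) * exp(-v[["R1"]] * t / X[["A"]])
  }
  errs <- vapply(c(0.01, 0.005), function(h) {
    traj <- simulate_inst(net, v, lab, X, times, h)
    max(vapply(seq_along(times), function(k)
      max(abs(traj$states[[k]][["A:1"]] - closed(times[k]))), 0))
  }, 0)
  expect_lt(errs[1], 0.01)                  # O(h) accurate
  expect_gt(errs[1] / errs[2], 1.5)         # first-order halving
  expect_lt(errs[1] / errs[2], 3)
})

test_that("an input matching the current state is a fixed point", {
  m <- parse_config(single_pool_config(), fixed = c(R1 = 1))
  lab <- substrate_labeling(   # unlabeled source = initial state
    data.frame(Metabolite = "Subs_S", Pattern = "0", Fraction = 1), m)
  net <- build_emu_network(m, list(emu("A", 1)))
  traj <- simulate_inst(net, c(R1 = 1, R2 = 1), lab, c(A = 1),
                        times = c(5, 20), h = 0.01)
  expect_equal(traj$states[[2]][["A:1"]], c(1, 0))
})

test_that("step halving converges linearly on the TCA network", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac_inst))
  tr <- lapply(c(0.2, 0.1, 0.05), function(h)
    simulate_inst(net, exp$truth, exp$labeling, exp$pools, times = 20, h = h))
  d1 <- max(abs(unlist(tr[[1]]$states[[1]]) - unlist(tr[[3]]$states[[1]])))
  d2 <- max(abs(unlist(tr[[2]]$states[[1]]) - unlist(tr[[3]]$states[[1]])))
  expect_gt(d1 / d2, 2)   # error ~ h: (h - h/4) vs (h/2 - h/4) ratio ~ 3
  expect_lt(d1 / d2, 4.5)
})

test_that("scaling fluxes and pools together rescales time", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac_inst))
  c_scale <- 2
  t1 <- simulate_inst(net, exp$truth, exp$labeling, exp$pools,
                      times = c(10, 30), h = 0.01)
  # v*c with the same pools runs c times faster: state at t/c matches
  t2 <- simulate_inst(net, c_scale * exp$truth, exp$labeling, exp$pools,
                      times = c(10, 30) / c_scale, h = 0.01 / c_scale)
  expect_equal(unlist(t1$states), unlist(t2$states), tolerance = 1e-9)
  # v*c and X*c leave the trajectory unchanged at the same times
  t3 <- simulate_inst(net, c_scale * exp$truth, exp$labeling,
                      c_scale * exp$pools, times = c(10, 30), h = 0.01)
  expect_equal(unlist(t1$states), unlist(t3$states), tolerance = 1e-12)
})

test_that("the compiled Euler core agrees with a plain R reference loop", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac_inst))
  h <- 0.05; nsteps <- 100L
  traj <- simulate_inst(net, exp$truth, exp$labeling, exp$pools,
                        times = nsteps * h, h = h)
  # reference: assemble matrices per size once, step in R
  v <- exp$truth
  state <- list()
  for (s in net$sizes) {
    lv <- net$levels[[as.character(s)]]
    Z <- matrix(0, length(lv$unknown), s + 1L); Z[, 1] <- 1
    rownames(Z) <- lv$unknown
    state[[as.character(s)]] <- Z
  }
  solved_of <- function(state) {
    out <- list()
    for (s in names(state))
      for (id in rownames(state[[s]])) out[[id]] <- state[[s]][id, ]
    out
  }
  for (step in seq_len(nsteps)) {
    solved <- solved_of(state)
    newstate <- state
    for (s in net$sizes) {
      lv <- net$levels[[as.character(s)]]
      asm <- assemble_balance_matrices(net, s, v, exp$labeling, solved)
      dZ <- (asm$A %*% state[[as.character(s)]] - asm$B %*% asm$Y) /
        exp$pools[lv$met]
      Znew <- state[[as.character(s)]] + h * dZ
      newstate[[as.character(s)]] <- Znew / rowSums(Znew)
    }
    state <- newstate
  }
  ref <- solved_of(state)
  got <- traj$states[[1]]
  expect_equal(got[names(ref)], ref, tolerance = 1e-10)
})

test_that("a divergent step size is reported with advice", {
  m <- parse_config(single_pool_config(), fixed = c(R1 = 1))
  lab <- substrate_labeling(
    data.frame(Metabolite = "Subs_S", Pattern = "1", Fraction = 1), m)
  net <- build_emu_network(m, list(emu("A", 1)))
  # h far above the stability limit 2X/v
  expect_error(
    simulate_inst(net, c(R1 = 1, R2 = 1), lab, c(A = 0.001),
                  times = c(50, 100), h = 10),
    "step size")
})

test_that("timescales report pool turnover and the slower network relaxation", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac_inst))
  ts <- labeling_timescales(net, exp$truth, exp$pools)
  # OAA turnover: X / total consumption (R3+R9+R10+R15+R16 = 2.2)
  expect_equal(unname(ts$turnover["OAA:1,2,3,4"]), 5 / 2.2, tolerance = 1e-9)
  expect_gt(ts$relaxation, max(ts$turnover))
})
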