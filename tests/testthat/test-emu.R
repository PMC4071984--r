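# independent recursive EMU enumerator used as a counting oracle: works on
# the raw configuration strings, not through the package's network builder
emu_closure_oracle <- function(config, targets, sym = character(0)) {
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rxns <- list()
  for (i in seq_len(nrow(config))) {
    map <- trimws(config$Carbon_transitions[i])
    if (!nzchar(map)) next
    eq <- strsplit(config$Rxns[i], "->", fixed = TRUE)[[1]]
    sides <- strsplit(map, "->", fixed = TRUE)[[1]]
    rxns[[length(rxns) + 1L]] <- list(
      subs = trimws(strsplit(eq[1], "+", fixed = TRUE)[[1]]),
      prods = trimws(strsplit(eq[2], "+", fixed = TRUE)[[1]]),
      sstr = trimws(strsplit(sides[1], "+", fixed = TRUE)[[1]]),
      pstr = trimws(strsplit(sides[2], "+", fixed = TRUE)[[1]]))
  }
  key <- function(met, atoms) paste0(met, "{", paste(sort(atoms), collapse = ","), "}")
  seen <- character(0)
  visit <- function(met, atoms) {
    k <- key(met, atoms)
    if (k %in% seen || grepl("^(Subs_|Ind_)", met)) return(invisible())
    seen <<- c(seen, k)
    for (rx in rxns) for (pi in which(rx$prods == met)) {
      pstrs <- if (met %in% sym) c(rx$pstr[pi], revstr(rx$pstr[pi])) else rx$pstr[pi]
      for (ps in pstrs) {
        need <- strsplit(ps, "")[[1]][atoms]
        for (si in seq_along(rx$subs)) {
          sstrs <- if (rx$subs[si] %in% sym)
            c(rx$sstr[si], revstr(rx$sstr[si])) else rx$sstr[si]
          for (ss in sstrs) {
            pos <- which(strsplit(ss, "")[[1]] %in% need)
            if (length(pos)) visit(rx$subs[si], pos)
          }
        }
      }
    }
  }
  for (t in targets) visit(t$met, t$atoms)
  seen
}

test_that("atom tracing reproduces the hand-derived transitions", {
  m <- parse_config(tca_config())

  # condensation: citrate-synthase product positions map back to OAA / ACCOA
  tr <- trace_emu(m, emu("IsoCit", c(1, 5)))
  expect_length(tr, 1L)
  expect_identical(tr[[1]]$flux_id, "R3")
  expect_setequal(vapply(tr[[1]]$precursors, emuflux:::emu_id, ""),
                  c("ACCOA:1", "OAA:4"))

  # symmetric succinate scrambles the AKG-derived carbon half-and-half
  tr <- trace_emu(m, emu("Sym_SUC", 1))
  r5 <- tr[vapply(tr, `[[`, "", "flux_id") == "R5"]
  expect_length(r5, 2L)
  expect_equal(sort(vapply(r5, function(x) emuflux:::emu_id(x$precursors[[1]]), "")),
               c("AKG:1", "AKG:4"))
  expect_equal(vapply(r5, `[[`, 0, "weight"), c(0.5, 0.5))

  # identity map passes the EMU through unchanged
  mc <- parse_config(chain_config())
  tr <- trace_emu(mc, emu("B", 1))
  expect_length(tr, 1L)
  expect_identical(emuflux:::emu_id(tr[[1]]$precursors[[1]]), "A:1")
  expect_equal(tr[[1]]$weight, 1)
})

test_that("tracing through an unmapped producing reaction is an error", {
  cfg <- data.frame(FluxID = c("R1", "R2"),
                    Rxns = c("A -> B", "B -> C"),
                    Carbon_transitions = c("", "a -> a"))
  m <- suppressWarnings(parse_config(cfg))
  expect_error(trace_emu(m, emu("B", 1)), "R1.*no atom map")
})

test_that("symmetric-expansion weights sum to one per producing reaction", {
  m <- parse_config(tca_config())
  for (target in list(emu("Sym_SUC", 1:2), emu("Sym_SUC", c(1, 3)),
                      emu("OAA", 1:4))) {
    tr <- trace_emu(m, target)
    w <- tapply(vapply(tr, `[[`, 0, "weight"),
                vapply(tr, `[[`, "", "flux_id"), sum)
    expect_true(all(abs(w - 1) < 1e-12))
  }
})

test_that("network closure matches an exhaustive recursive enumeration", {
  m <- parse_config(tca_config())
  targets <- list(emu("OAA", 1:4), emu("Sym_SUC", 1:4))
  net <- build_emu_network(m, targets)
  oracle <- emu_closure_oracle(tca_config(), targets, sym = "Sym_SUC")
  expect_identical(net$n_unknown, length(oracle))
  # every size level is covered, precursor sizes never exceed product sizes
  for (s in net$sizes) {
    lv <- net$levels[[as.character(s)]]
    expect_true(length(lv$unknown) > 0L)
  }
})

test_that("a linear chain yields one unknown EMU per reaction and no size mixing", {
  n <- 5L
  cfg <- data.frame(
    FluxID = c(paste0("R", 1:n), "Rd"),
    Rxns = c("Subs_S -> M1", paste0("M", 1:(n - 1), " -> M", 2:n),
             paste0("M", n, " -> [M_B]")),
    Carbon_transitions = c(rep("abc -> abc", n), ""))
  m <- parse_config(cfg)
  net <- build_emu_network(m, list(emu(paste0("M", n), 1:3)))
  expect_identical(net$n_unknown, n)
  expect_identical(net$sizes, 3L)
})

test_that("an empty target list gives an empty network", {
  m <- parse_config(tca_config())
  net <- build_emu_network(m, list())
  expect_identical(net$n_unknown, 0L)
  expect_length(net$sizes, 0L)
})

test_that("balance matrices satisfy the per-EMU mass-balance row identity", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac))
  v <- exp$truth
  solved <- list()
  for (s in net$sizes) {
    asm <- assemble_balance_matrices(net, s, v, exp$labeling, solved)
    # -outflux + unknown inflows + known inflows = 0 at steady state
    expect_lt(max(abs(rowSums(asm$A) - rowSums(asm$B))), 1e-9)
    Z <- solve(asm$A, asm$B %*% asm$Y)
    for (i in seq_along(asm$unknown)) solved[[asm$unknown[i]]] <- Z[i, ]
  }
})

test_that("the one-reaction system gives the textbook 1x1 balance", {
  m <- parse_config(single_pool_config(), fixed = c(R1 = 2))
  lab <- substrate_labeling(
    data.frame(Metabolite = "Subs_S", Pattern = "1", Fraction = 1), m)
  net <- build_emu_network(m, list(emu("A", 1)))
  asm <- assemble_balance_matrices(net, 1, c(R1 = 2, R2 = 2), lab)
  expect_equal(asm$A, matrix(-2, 1, 1, dimnames = list("A:1", "A:1")))
  expect_equal(asm$B, matrix(-2, 1, 1))
  expect_equal(asm$Y[1, ], c(0, 1))   # fully labeled source
})

test_that("steady-state MDVs are invariant to scaling the flux vector", {
  exp <- tca_experiment()
  net <- build_emu_network(exp$model, msreac_targets(exp$msreac))
  s1 <- simulate_stationary(net, exp$truth, exp$labeling)
  s2 <- simulate_stationary(net, 2 * exp$truth, exp$labeling)
  expect_equal(unlist(s1), unlist(s2), tolerance = 1e-12)
})
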