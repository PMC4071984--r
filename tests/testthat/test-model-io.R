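test_that("the benchmark TCA worksheet parses with the expected structure", {
  m <- parse_config(tca_config())
  expect_s3_class(m, "mfa_model")
  expect_length(m$reactions, 16L)

  kinds <- vapply(m$reactions, `[[`, "", "kind")
  expect_identical(unname(kinds[c("R1", "R14")]),
                   rep("substrate_input", 2L))
  expect_identical(unname(kinds[paste0("R", 8:13)]),
                   rep("biomass_drain", 6L))
  expect_true(all(vapply(m$reactions[paste0("R", 8:13)],
                         function(rx) is.null(rx$atom_reactants), TRUE)))

  # balanced metabolites exclude Ind_/Subs_/sink species
  expect_setequal(rownames(m$S),
                  c("PYR", "ACCOA", "IsoCit", "AKG", "Sym_SUC", "OAA"))
  expect_false(any(grepl("^(Ind_|Subs_)", rownames(m$S))))

  r3 <- m$reactions$R3
  expect_identical(r3$substrates$name, c("ACCOA", "OAA"))
  expect_identical(r3$products$name, "IsoCit")
  expect_identical(r3$atom_reactants, c("ab", "cdef"))
  expect_identical(r3$atom_products, "fedbac")

  # reversible-pair tags
  tags <- vapply(m$reactions, `[[`, 0L, "pair_tag")
  expect_identical(unname(tags[c("R6", "R15")]), c(1L, 1L))
  expect_identical(unname(tags[c("R7", "R16")]), c(2L, 2L))
})

test_that("the packaged worksheet file parses identically to the in-code table", {
  f <- system.file("extdata", "tca", "Metabolic_network.csv",
                   package = "emuflux")
  expect_true(nzchar(f))
  m1 <- parse_config(f)
  m2 <- parse_config(tca_config())
  expect_identical(format_config(m1), format_config(m2))
})

test_that("a one-row conversion gives the expected 2x1 stoichiometry", {
  cfg <- data.frame(FluxID = "R1", Rxns = "A -> B",
                    Carbon_transitions = "ab -> ab")
  expect_warning(m <- parse_config(cfg), "dead-end")
  expect_identical(dim(m$S), c(2L, 1L))
  expect_identical(m$S["A", "R1"], -1)
  expect_identical(m$S["B", "R1"], 1)
})

test_that("atom-map and configuration errors are caught by name", {
  bad <- data.frame(FluxID = "R1", Rxns = "A -> B",
                    Carbon_transitions = "ab -> ac")
  expect_error(parse_config(bad), "R1.*not balanced")

  dup <- data.frame(FluxID = c("R1", "R1"),
                    Rxns = c("A -> B", "B -> A"),
                    Carbon_transitions = c("a -> a", "a -> a"))
  expect_error(parse_config(dup), "duplicate FluxID")

  conflict <- data.frame(FluxID = c("R1", "R2"),
                         Rxns = c("A -> B", "B -> C"),
                         Carbon_transitions = c("ab -> ab", "abc -> abc"))
  expect_error(parse_config(conflict), "conflicting carbon counts")

  arity <- data.frame(FluxID = "R1", Rxns = "A + B -> C",
                      Carbon_transitions = "ab -> ab")
  expect_error(parse_config(arity), "species count")
})

test_that("both arrow dialects and whitespace variants are accepted", {
  for (arrow in c("->", "→", "=")) {
    cfg <- data.frame(FluxID = c("R1", "R2"),
                      Rxns = paste("Subs_A", arrow, "B"),
                      Carbon_transitions = paste("a", arrow, "a"))
    cfg$Rxns[2] <- paste("B", arrow, "[B_B]")
    cfg$Carbon_transitions[2] <- ""
    m <- parse_config(cfg)
    expect_length(m$reactions, 2L)
    expect_identical(rownames(m$S), "B")
  }
})

test_that("a cyclic network reports the rank deficiency", {
  cfg <- data.frame(FluxID = c("R1", "R2", "R3"),
                    Rxns = c("A -> B", "B -> C", "C -> A"),
                    Carbon_transitions = c("a -> a", "a -> a", "a -> a"))
  m <- parse_config(cfg)
  st <- build_stoichiometry(m)
  expect_identical(st$rank, 2L)        # one free cycle flux
  expect_identical(nrow(st$S), 3L)
})

test_that("serialization round-trips through the parser", {
  m <- parse_config(tca_config())
  m2 <- parse_config(format_config(m))
  expect_identical(format_config(m2), format_config(m))
  expect_identical(m2$metabolites, m$metabolites)
  expect_equal(m2$S, m$S)
})

test_that("atom-letter conservation holds for every parsed mapped reaction", {
  m <- parse_config(tca_config())
  for (rx in m$reactions) {
    if (is.null(rx$atom_reactants)) next
    lr <- sort(unlist(strsplit(rx$atom_reactants, "")))
    lp <- sort(unlist(strsplit(rx$atom_products, "")))
    expect_identical(lr, lp)
  }
})

test_that("measurement loading handles time courses, replicates and guards", {
  exp <- tca_experiment()
  dir <- withr::local_tempdir()
  simulate_dataset(exp, "inst", seed = 3, outdir = dir)
  files <- sort(list.files(dir, "Abundance", full.names = TRUE))
  expect_length(files, 17L)
  ms <- load_measurements(as.list(files), exp$msreac_inst,
                          time_course = exp$times)
  expect_identical(ms$ns, 17L)
  expect_length(ms$entries, 17L * 2L)
  expect_true(all(vapply(ms$entries, function(e) abs(sum(e$mdv) - 1) < 1e-9,
                         TRUE)))

  # stationary single-table special case
  ms1 <- load_measurements(read.csv(files[1]), exp$msreac_inst)
  expect_identical(ms1$ns, 1L)
  expect_true(all(is.na(vapply(ms1$entries, `[[`, 0, "time"))))

  # guards
  expect_error(load_measurements(as.list(files[1:3]), exp$msreac_inst,
                                 time_course = exp$times),
               "mismatch")
  zero <- data.frame(Fragment = "OAA", M0 = 0, M1 = 0, M2 = 0, M3 = 0, M4 = 0)
  expect_error(load_measurements(zero, exp$msreac_inst), "degenerate")
  expect_error(load_measurements(read.csv(files[1]), exp$msreac_inst,
                                 correct = TRUE),
               "Components")
  comp_missing <- exp$components[exp$components$Fragment == "OAA", ]
  expect_error(load_measurements(read.csv(files[1]), exp$msreac_inst,
                                 components = comp_missing, correct = TRUE),
               "missing from Components")
})
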