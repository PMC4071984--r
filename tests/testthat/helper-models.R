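# Small models and datasets shared across tests; everything is generated
# in code, nothing is read from disk except the packaged worksheet.

chain_config <- function() {
  # Subs_S -> A -> B -> drain, single carbon, identity maps
  data.frame(
    FluxID = c("R1", "R2", "R3"),
    Rxns = c("Subs_S -> A", "A -> B", "B -> [B_B]"),
    Carbon_transitions = c("a -> a", "a -> a", ""),
    stringsAsFactors = FALSE)
}

# one balanced pool fed by a fixed-labeling source, plus efflux: the
# labeling ODE has the closed form
# MDV(t) = MDV_in + (MDV0 - MDV_in) * exp(-v t / X)
single_pool_config <- function() {
  data.frame(
    FluxID = c("R1", "R2"),
    Rxns = c("Subs_S -> A", "A -> [A_B]"),
    Carbon_transitions = c("a -> a", ""),
    stringsAsFactors = FALSE)
}

# linear two-source mixing toy: MDV of B is linear in the free flux R1
# (B = R1 * MDV_A + (1 - R1) * MDV_C at fixed total throughput 1)
mixing_config <- function() {
  data.frame(
    FluxID = c("R1", "R2", "R3"),
    Rxns = c("Subs_A -> B", "Subs_C -> B", "B -> [B_B]"),
    Carbon_transitions = c("a -> a", "a -> a", ""),
    stringsAsFactors = FALSE)
}

mixing_model <- function() parse_config(mixing_config(), fixed = c(R3 = 1))

mixing_labeling <- function(model) {
  substrate_labeling(data.frame(
    Metabolite = c("Subs_A", "Subs_C"),
    Pattern = c("1", "0"),
    Fraction = c(1, 1)), model)
}

# measurements object built directly from MDV vectors
manual_measurements <- function(mdvs, metabolite, atoms, sd = 0.01,
                                times = NULL) {
  entries <- lapply(seq_along(mdvs), function(k) list(
    fragment = metabolite,
    metabolite = metabolite,
    atoms = atoms,
    time = if (is.null(times)) NA_real_ else times[k],
    replicate = k,
    mdv = mdvs[[k]],
    sd = rep_len(sd, length(mdvs[[k]]))))
  structure(list(entries = entries,
                 times = if (is.null(times)) numeric(0) else times,
                 ns = length(mdvs)),
            class = "mfa_measurements")
}

keep_fragments <- function(ms, fragments) {
  keep <- vapply(ms$entries, function(e) e$fragment %in% fragments, TRUE)
  structure(list(entries = ms$entries[keep], times = ms$times, ns = ms$ns),
            class = "mfa_measurements")
}
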