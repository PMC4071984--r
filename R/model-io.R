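#' Parse a metabolic network configuration into a flux model
#'
#' Reads the declarative configuration table that defines a carbon-labeling
#' model: one row per reaction, with the reaction equation in an `Rxns`
#' column and the carbon-atom transitions in a `Carbon_transitions` column
#' (lowercase-letter strings, one per species, e.g. `"ab + cdef -> fedbac"`).
#' Metabolite roles are declared through naming conventions:
#'
#' * `Subs_` prefix — extracellular carbon source (never mass-balanced);
#' * `Sym_`  prefix — rotationally symmetric molecule (e.g. succinate),
#'   whose atom maps are scrambled half-and-half between the written and
#'   the reversed atom order;
#' * `Ind_`  prefix — metabolite excluded from mass balancing (e.g. CO2);
#' * `[...]` brackets on a product — biomass/sink pseudo-metabolite, never
#'   balanced or traced (conventionally suffixed `_B`);
#' * `_EX`   suffix on a product — excreted metabolite.
#'
#' Reactions with an empty `Carbon_transitions` cell (typically biomass
#' drains) participate in the stoichiometric matrix but carry no atom map.
#' A `Net flux` column, when present, is read as a reversible-pair tag:
#' rows sharing the same nonzero value are the forward/backward directions
#' of one reversible reaction; `0` marks an irreversible reaction.
#'
#' @param config a `data.frame` with columns `FluxID`, `Rxns`,
#'   `Carbon_transitions` and optionally `Net flux`, or the path of a CSV
#'   file with those columns.  Arrows may be written `→`, `->` or `=`.
#' @param fixed optional named numeric vector of predetermined fluxes
#'   (same effect as [set_fixed_fluxes()]).
#' @return an object of class `mfa_model`: list with elements `reactions`
#'   (list of parsed reactions), `metabolites` (role table), `S`
#'   (stoichiometric matrix over balanced metabolites), `fixed_fluxes`.
#' @seealso [build_stoichiometry()], [build_emu_network()]
#' @export
parse_config <- function(config, fixed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read.csv(config, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(config))
  cols <- tolower(gsub("[ _]", "", names(config)))
  need <- c("fluxid", "rxns", "carbontransitions")
  if (!all(need %in% cols))
    stop("configuration must have columns FluxID, Rxns, Carbon_transitions",
         call. = FALSE)
  id_col  <- which(cols == "fluxid")[1]
  rxn_col <- which(cols == "rxns")[1]
  map_col <- which(cols == "carbontransitions")[1]
  tag_col <- which(cols == "netflux")
  ids  <- trimws(as.character(config[[id_col]]))
  if (anyDuplicated(ids))
    stop("duplicate FluxID: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)

  reactions <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rx <- parse_reaction_string(as.character(config[[rxn_col]][i]), ids[i])
    map_raw <- as.character(config[[map_col]][i])
    if (length(map_raw) == 0L || is.na(map_raw)) map_raw <- ""
    am <- parse_atom_map(map_raw, rx, ids[i])
    tag <- if (length(tag_col)) suppressWarnings(as.integer(config[[tag_col[1]]][i])) else NA_integer_
    if (is.na(tag)) tag <- 0L
    rx$atom_reactants <- am$reactants
    rx$atom_products  <- am$products
    rx$pair_tag <- tag
    reactions[[i]] <- rx
  }
  names(reactions) <- ids

  metabolites <- infer_roles(reactions)
  reactions <- lapply(reactions, classify_reaction, metabolites = metabolites)
  model <- structure(
    list(reactions = reactions, metabolites = metabolites,
         S = NULL, fixed_fluxes = numeric(0)),
    class = "mfa_model")
  st <- build_stoichiometry(model)
  model$S <- st$S
  if (!is.null(fixed)) model <- set_fixed_fluxes(model, fixed)
  model
}

# -- parsing internals -------------------------------------------------------

split_sides <- function(x, what, id) {
  parts <- strsplit(x, "→|->|=")[[1]]
  if (length(parts) != 2L)
    stop("reaction ", id, ": ", what, " must have exactly one arrow", call. = FALSE)
  lapply(parts, function(s) {
    toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    toks[nzchar(toks)]
  })
}

parse_species_token <- function(tok, id) {
  m <- regmatches(tok, regexec("^([0-9]*\\.?[0-9]*)\\s*\\*?\\s*(.+)$", tok))[[1]]
  coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
  name <- trimws(m[3])
  sink <- grepl("^\\[.+\\]$", name)
  if (sink) name <- sub("^\\[(.+)\\]$", "\\1", name)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name))
    stop("reaction ", id, ": cannot parse species token '", tok, "'", call. = FALSE)
  list(name = name, coef = coef, sink = sink)
}

parse_reaction_string <- function(rxn, id) {
  sides <- split_sides(rxn, "Rxns", id)
  parse_side <- function(toks) {
    sp <- lapply(toks, parse_species_token, id = id)
    data.frame(name = vapply(sp, `[[`, "", "name"),
               coef = vapply(sp, `[[`, 0, "coef"),
               sink = vapply(sp, `[[`, FALSE, "sink"),
               stringsAsFactors = FALSE)
  }
  subs <- parse_side(sides[[1]])
  prods <- parse_side(sides[[2]])
  if (!nrow(subs) || !nrow(prods))
    stop("reaction ", id, ": empty reaction side", call. = FALSE)
  if (any(subs$sink))
    stop("reaction ", id, ": bracketed sink species cannot be a substrate", call. = FALSE)
  list(flux_id = id, substrates = subs, products = prods)
}

parse_atom_map <- function(map_raw, rx, id) {
  map_raw <- trimws(map_raw)
  if (!nzchar(map_raw)) return(list(reactants = NULL, products = NULL))
  sides <- split_sides(map_raw, "Carbon_transitions", id)
  ok <- function(x) all(grepl("^[a-z]+$", x))
  if (!ok(sides[[1]]) || !ok(sides[[2]]))
    stop("reaction ", id, ": atom strings must be contiguous lowercase letters",
         call. = FALSE)
  if (length(sides[[1]]) != nrow(rx$substrates) ||
      length(sides[[2]]) != nrow(rx$products))
    stop("reaction ", id, ": atom-map species count does not match the reaction",
         call. = FALSE)
  if (any(rx$substrates$coef != 1) || any(rx$products$coef != 1))
    stop("reaction ", id, ": atom-mapped species must have unit stoichiometry; ",
         "write repeated species as separate terms", call. = FALSE)
  letters_of <- function(ss) unlist(strsplit(ss, ""))
  lr <- letters_of(sides[[1]]); lp <- letters_of(sides[[2]])
  if (anyDuplicated(lr) || anyDuplicated(lp))
    stop("reaction ", id, ": atom letters must be distinct within one side",
         call. = FALSE)
  if (!identical(sort(lr), sort(lp)))
    stop("reaction ", id, ": atom letters not balanced between sides",
         call. = FALSE)
  list(reactants = sides[[1]], products = sides[[2]])
}

infer_roles <- function(reactions) {
  recs <- list()
  note <- function(name, sink, carbons) {
    prev <- recs[[name]]
    if (is.null(prev)) {
      recs[[name]] <<- list(name = name, sink = sink, carbons = carbons)
    } else {
      if (!is.na(carbons)) {
        if (!is.na(prev$carbons) && prev$carbons != carbons)
          stop("metabolite ", name, ": conflicting carbon counts (",
               prev$carbons, " vs ", carbons, ")", call. = FALSE)
        recs[[name]]$carbons <<- carbons
      }
      recs[[name]]$sink <<- prev$sink || sink
    }
  }
  for (rx in reactions) {
    for (side in c("substrates", "products")) {
      sp <- rx[[side]]
      strs <- if (side == "substrates") rx$atom_reactants else rx$atom_products
      for (k in seq_len(nrow(sp)))
        note(sp$name[k], sp$sink[k],
             if (is.null(strs)) NA_integer_ else nchar(strs[k]))
    }
  }
  df <- data.frame(
    name = vapply(recs, `[[`, "", "name"),
    carbons = vapply(recs, function(r) ifelse(is.na(r$carbons), 0L, as.integer(r$carbons)), 0L),
    is_sink = vapply(recs, `[[`, FALSE, "sink"),
    stringsAsFactors = FALSE, row.names = NULL)
  df$is_symmetric  <- startsWith(df$name, "Sym_")
  df$is_unbalanced <- startsWith(df$name, "Ind_")
  df$is_source     <- startsWith(df$name, "Subs_")
  df$balanced <- !(df$is_sink | df$is_unbalanced | df$is_source)
  df[order(df$name), , drop = FALSE]
}

classify_reaction <- function(rx, metabolites) {
  role <- function(n, what) metabolites[[what]][match(n, metabolites$name)]
  kind <-
    if (any(role(rx$substrates$name, "is_source"))) "substrate_input"
    else if (any(rx$products$sink)) "biomass_drain"
    else if (any(endsWith(rx$products$name, "_EX") & !rx$products$sink)) "excretion"
    else "internal"
  rx$kind <- kind
  rx
}

#' Build the stoichiometric matrix of a model
#'
#' Assembles `S` over the *balanced* metabolites only: sources (`Subs_`),
#' unbalanced species (`Ind_`) and bracketed sink pseudo-metabolites are
#' excluded from mass balance.  At metabolic steady state the flux vector
#' satisfies `S v = 0`.
#'
#' @param model an `mfa_model`.
#' @return list with `S` (balanced metabolites x reactions), `metabolites`
#'   (row names), and `rank` (numerical rank of `S`).  Emits a warning for
#'   balanced metabolites that are only produced or only consumed.
#' @export
build_stoichiometry <- function(model) {
  mets <- model$metabolites$name[model$metabolites$balanced]
  rxns <- names(model$reactions)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    rx <- model$reactions[[j]]
    for (k in seq_len(nrow(rx$substrates))) {
      i <- match(rx$substrates$name[k], mets)
      if (!is.na(i)) S[i, j] <- S[i, j] - rx$substrates$coef[k]
    }
    for (k in seq_len(nrow(rx$products))) {
      if (rx$products$sink[k]) next
      i <- match(rx$products$name[k], mets)
      if (!is.na(i)) S[i, j] <- S[i, j] + rx$products$coef[k]
    }
  }
  one_sided <- mets[apply(S, 1, function(r) all(r <= 0) || all(r >= 0))]
  if (length(one_sided))
    warning("dead-end balanced metabolite(s): ", paste(one_sided, collapse = ", "),
            call. = FALSE)
  list(S = S, metabolites = mets, rank = qr(S)$rank)
}

#' Declare predetermined fluxes
#'
#' Fixes a subset of fluxes (substrate uptake, biomass drains, excretion
#' rates measured outside the labeling experiment) to known values.  Fixed
#' fluxes are held exactly during fitting; only the remaining degrees of
#' freedom are estimated.
#'
#' @param model an `mfa_model`.
#' @param fixed named numeric vector, names are flux ids.
#' @return the model with `fixed_fluxes` set.
#' @export
set_fixed_fluxes <- function(model, fixed) {
  stopifnot(is.numeric(fixed), !is.null(names(fixed)))
  bad <- setdiff(names(fixed), names(model$reactions))
  if (length(bad))
    stop("unknown flux id(s) in fixed fluxes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  model$fixed_fluxes <- fixed
  model
}

#' @export
print.mfa_model <- function(x, ...) {
  kinds <- table(vapply(x$reactions, `[[`, "", "kind"))
  cat("<mfa_model> ", length(x$reactions), " reactions, ",
      nrow(x$S), " balanced metabolites (rank ", qr(x$S)$rank, ")\n", sep = "")
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  if (length(x$fixed_fluxes))
    cat("  fixed:", paste(names(x$fixed_fluxes), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a model back to its configuration table
#'
#' Inverse of [parse_config()]: returns a `data.frame` with `FluxID`,
#' `Rxns`, `Net flux` and `Carbon_transitions` columns that reparses to a
#' structurally identical model.
#'
#' @param model an `mfa_model`.
#' @return a `data.frame` in configuration layout.
#' @export
format_config <- function(model) {
  fmt_side <- function(sp) paste(ifelse(
    sp$sink, paste0("[", sp$name, "]"),
    ifelse(sp$coef == 1, sp$name, paste0(sp$coef, " ", sp$name))), collapse = " + ")
  rows <- lapply(model$reactions, function(rx) {
    map <- if (is.null(rx$atom_reactants)) "" else
      paste(paste(rx$atom_reactants, collapse = " + "), "->",
            paste(rx$atom_products, collapse = " + "))
    data.frame(FluxID = rx$flux_id,
               Rxns = paste(fmt_side(rx$substrates), "->", fmt_side(rx$products)),
               `Net flux` = rx$pair_tag,
               Carbon_transitions = map,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load measured (or simulated) labeling spectra
#'
#' Collects per-fragment mass spectra, optionally over a labeling time
#' course, into the measurement container used by [fit_fluxes()].  One
#' abundance table per sampling point; the stationary case is the
#' single-point special case.
#'
#' @param abundance a `data.frame`, path, or list of them (one per sampling
#'   time, in `Time_course` order).  Columns: `Fragment`, then `M0`, `M1`,
#'   ... raw intensities.
#' @param msreac fragment definition table (or CSV path): columns
#'   `Fragment`, `Metabolite`, `First_atom`, `Last_atom`.
#' @param time_course optional numeric vector of sampling times (or CSV
#'   path with a `Time` column); required when `abundance` has more than
#'   one table.
#' @param components optional fragment elemental-composition table (or CSV
#'   path) as used by [build_correction_matrix()]; required when
#'   `correct = TRUE`.
#' @param correct logical; correct raw intensities for natural isotope
#'   abundance before normalization.
#' @param sd measurement standard deviation per mass channel (scalar or
#'   vector recycled per channel) used as the diagonal of the measurement
#'   covariance.
#' @return an object of class `mfa_measurements`: list of entries with
#'   fragment, metabolite, atom positions, time (NA for stationary
#'   replicates), replicate index, `mdv`, `sd`.
#' @export
load_measurements <- function(abundance, msreac, time_course = NULL,
                              components = NULL, correct = FALSE, sd = 0.01) {
  read_tab <- function(x) if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
  if (is.data.frame(abundance) || is.character(abundance) && length(abundance) == 1L)
    abundance <- list(abundance)
  tabs <- lapply(abundance, read_tab)
  msreac <- read_tab(msreac)
  if (!is.null(time_course)) {
    if (is.character(time_course)) time_course <- read_tab(time_course)$Time
    time_course <- as.numeric(time_course)
    if (is.unsorted(time_course, strictly = TRUE))
      stop("Time_course must be strictly increasing", call. = FALSE)
    if (length(time_course) != length(tabs))
      stop("time count mismatch: ", length(time_course), " sampling times but ",
           length(tabs), " abundance tables", call. = FALSE)
  }
  # multiple tables without a time course are stationary replicate spectra
  if (correct && is.null(components))
    stop("natural-abundance correction requires a Components table", call. = FALSE)
  if (!is.null(components)) components <- read_tab(components)

  entries <- list()
  for (k in seq_along(tabs)) {
    tab <- tabs[[k]]
    for (i in seq_len(nrow(tab))) {
      frag <- as.character(tab$Fragment[i])
      raw <- suppressWarnings(as.numeric(tab[i, -match("Fragment", names(tab)), drop = TRUE]))
      raw <- raw[!is.na(raw)]
      if (!length(raw) || all(raw == 0))
        stop("degenerate spectrum for fragment ", frag, call. = FALSE)
      m <- match(frag, msreac$Fragment)
      if (is.na(m))
        stop("fragment ", frag, " not defined in MSReac", call. = FALSE)
      atoms <- seq.int(msreac$First_atom[m], msreac$Last_atom[m])
      if (correct) {
        cm <- match(frag, components$Fragment)
        if (is.na(cm))
          stop("fragment ", frag, " missing from Components: correction impossible",
               call. = FALSE)
        K <- build_correction_matrix(components[cm, , drop = FALSE],
                                     window = length(raw))
        mdv <- correct_spectrum(raw, K)
      } else {
        mdv <- as_mdv(raw)
      }
      entries[[length(entries) + 1L]] <- list(
        fragment = frag,
        metabolite = as.character(msreac$Metabolite[m]),
        atoms = atoms,
        time = if (is.null(time_course)) NA_real_ else time_course[k],
        replicate = k,
        mdv = mdv,
        sd = rep_len(sd, length(mdv)))
    }
  }
  structure(list(entries = entries,
                 times = if (is.null(time_course)) numeric(0) else time_course,
                 ns = length(tabs)),
            class = "mfa_measurements")
}

#' @export
print.mfa_measurements <- function(x, ...) {
  frs <- unique(vapply(x$entries, `[[`, "", "fragment"))
  cat("<mfa_measurements> ", length(x$entries), " spectra; fragments: ",
      paste(frs, collapse = ", "), "; sampling points Ns = ", x$ns, "\n", sep = "")
  invisible(x)
}
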