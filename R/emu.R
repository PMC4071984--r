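#' Elementary metabolite units
#'
#' An EMU is a specific subset of a metabolite's carbon atoms.  Labeling
#' simulation only needs the mass distribution of the EMUs that feed the
#' measured fragments, which decouples the problem into small linear
#' systems stratified by EMU size.
#'
#' @param metabolite metabolite name.
#' @param atoms integer vector of 1-based atom positions (positions follow
#'   the letter order of the metabolite's atom-transition strings).
#' @return an object of class `emu`.
#' @examples
#' emu("OAA", 1:4)
#' @export
emu <- function(metabolite, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  if (!length(atoms) || any(atoms < 1L))
    stop("an EMU needs a non-empty set of positive atom positions", call. = FALSE)
  structure(list(met = metabolite, atoms = atoms, size = length(atoms)),
            class = "emu")
}

emu_id <- function(e) paste0(e$met, ":", paste(e$atoms, collapse = ","))

#' @export
print.emu <- function(x, ...) {
  cat("<emu> ", emu_id(x), " (size ", x$size, ")\n", sep = "")
  invisible(x)
}

# orientation variants of an atom string: symmetric molecules scramble
# half-and-half between the written and the fully reversed atom order.
orientations <- function(s, symmetric) {
  if (!symmetric) return(list(list(str = s, w = 1)))
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  list(list(str = s, w = 0.5), list(str = r, w = 0.5))
}

#' Trace an EMU one reaction layer back
#'
#' For every reaction producing the target EMU's metabolite, maps the
#' target atom positions through the carbon-transition strings onto the
#' precursor metabolite(s).  A target drawing atoms from two substrates
#' yields a condensation (two precursor EMUs, combined by MDV
#' convolution).  Symmetric (`Sym_`) metabolites on either side are
#' expanded into half-weight forward/reversed variants.
#'
#' @param model an `mfa_model`.
#' @param target an [emu()].
#' @return list of EMU reactions: each a list with `flux_id`, `product`
#'   (target id), `precursors` (list of `emu`, length 1 or 2), `weight`.
#' @export
trace_emu <- function(model, target) {
  met_tab <- model$metabolites
  sym <- function(n) met_tab$is_symmetric[match(n, met_tab$name)]
  out <- list()
  for (rx in model$reactions) {
    hits <- which(rx$products$name == target$met & !rx$products$sink)
    if (!length(hits)) next
    if (is.null(rx$atom_products))
      stop("EMU ", emu_id(target), " is produced by reaction ", rx$flux_id,
           " which has no atom map", call. = FALSE)
    for (pi in hits) {
      pvars <- orientations(rx$atom_products[pi], sym(target$met))
      svars_per <- lapply(seq_len(nrow(rx$substrates)), function(k)
        orientations(rx$atom_reactants[k], sym(rx$substrates$name[k])))
      grid <- expand.grid(lapply(c(list(seq_along(pvars)),
                                   lapply(svars_per, seq_along)), identity))
      for (g in seq_len(nrow(grid))) {
        pv <- pvars[[grid[g, 1]]]
        w <- pv$w
        need <- strsplit(pv$str, "")[[1]][target$atoms]
        precursors <- list()
        for (k in seq_len(nrow(rx$substrates))) {
          sv <- svars_per[[k]][[grid[g, k + 1L]]]
          w0 <- sv$w
          pos <- which(strsplit(sv$str, "")[[1]] %in% need)
          w <- w * w0
          if (length(pos))
            precursors[[length(precursors) + 1L]] <-
              emu(rx$substrates$name[k], pos)
        }
        stopifnot(sum(vapply(precursors, `[[`, 0L, "size")) == target$size)
        out[[length(out) + 1L]] <- list(flux_id = rx$flux_id,
                                        product = emu_id(target),
                                        precursors = precursors, weight = w)
      }
    }
  }
  # merge duplicate variants (e.g. symmetric orientations mapping to the
  # same precursor set)
  key <- vapply(out, function(er) paste(
    er$flux_id, paste(sort(vapply(er$precursors, emu_id, "")), collapse = "|")), "")
  merged <- lapply(split(seq_along(out), key), function(ix) {
    er <- out[[ix[1]]]
    er$weight <- sum(vapply(out[ix], `[[`, 0, "weight"))
    er
  })
  unname(merged)
}

#' Build the EMU cascade network for a set of target fragments
#'
#' Performs a breadth-first closure from the measured target EMUs back to
#' the carbon sources, collecting exactly the EMUs whose mass
#' distributions are required.  EMUs of `Subs_` sources and of unbalanced
#' `Ind_` carbon donors are sources with fixed distributions; all others
#' are unknowns, grouped by size for the per-size linear balances.
#'
#' @param model an `mfa_model`.
#' @param targets list of [emu()] targets (e.g. from [msreac_targets()]).
#' @return an object of class `emu_network` with per-size levels holding
#'   the unknown-EMU index, known (source/convolution) entries, and the
#'   sparse coefficient structure of the balance matrices.
#' @export
build_emu_network <- function(model, targets) {
  met_tab <- model$metabolites
  role <- function(n, what) met_tab[[what]][match(n, met_tab$name)]
  is_src_emu <- function(e) isTRUE(role(e$met, "is_source")) ||
    isTRUE(role(e$met, "is_unbalanced"))

  emus <- list(); reacts <- list(); queue <- list()
  push <- function(e) {
    id <- emu_id(e)
    if (is.null(emus[[id]])) {
      emus[[id]] <<- e
      if (!is_src_emu(e)) queue[[length(queue) + 1L]] <<- e
    }
  }
  for (t in targets) push(t)
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    ers <- trace_emu(model, e)
    reacts <- c(reacts, ers)
    for (er in ers) for (p in er$precursors) push(p)
  }

  all_ids <- names(emus)
  unknown_ids <- all_ids[!vapply(emus[all_ids], is_src_emu, TRUE)]
  sizes <- sort(unique(vapply(emus[unknown_ids], `[[`, 0L, "size")))

  consumption <- consumption_table(model)
  levels <- list()
  for (s in sizes) {
    uk <- unknown_ids[vapply(emus[unknown_ids], `[[`, 0L, "size") == s]
    uk <- sort(uk)
    idx <- setNames(seq_along(uk), uk)
    known <- list(); kidx <- integer(0)
    A_trip <- list(); B_trip <- list()
    kkey <- function(spec, key) {
      if (is.null(known[[key]])) {
        known[[key]] <<- spec
        kidx[[key]] <<- length(known)
      }
      kidx[[key]]
    }
    for (er in reacts) {
      pid <- er$product
      if (is.na(idx[pid])) next
      i <- idx[[pid]]
      if (length(er$precursors) == 1L) {
        p <- er$precursors[[1]]
        stopifnot(p$size == s)
        pid2 <- emu_id(p)
        if (is_src_emu(p)) {
          j <- kkey(list(type = "source", met = p$met, atoms = p$atoms),
                    paste0("src:", pid2))
          B_trip[[length(B_trip) + 1L]] <- c(i = i, j = j,
                                             f = match(er$flux_id, names(model$reactions)),
                                             w = er$weight)
        } else {
          A_trip[[length(A_trip) + 1L]] <- c(i = i, j = idx[[pid2]],
                                             f = match(er$flux_id, names(model$reactions)),
                                             w = er$weight)
        }
      } else {
        ps <- er$precursors
        stopifnot(length(ps) == 2L, all(vapply(ps, `[[`, 0L, "size") < s))
        part <- function(p) {
          if (is_src_emu(p)) list(type = "source", met = p$met, atoms = p$atoms)
          else list(type = "unknown", id = emu_id(p), size = p$size)
        }
        pid_sorted <- sort(vapply(ps, emu_id, ""))
        j <- kkey(list(type = "conv", parts = lapply(ps, part)),
                  paste0("conv:", paste(pid_sorted, collapse = "|")))
        B_trip[[length(B_trip) + 1L]] <- c(i = i, j = j,
                                           f = match(er$flux_id, names(model$reactions)),
                                           w = er$weight)
      }
    }
    diag_terms <- list()
    for (id in uk) {
      met <- emus[[id]]$met
      ct <- consumption[[met]]
      if (is.null(ct) || !nrow(ct))
        stop("metabolite ", met, " has no consuming reaction: singular balance",
             call. = FALSE)
      for (r in seq_len(nrow(ct)))
        diag_terms[[length(diag_terms) + 1L]] <-
          c(i = idx[[id]], f = ct$flux_index[r], w = ct$coef[r])
    }
    to_df <- function(l, nms) {
      if (!length(l)) return(as.data.frame(setNames(rep(list(numeric(0)), length(nms)), nms)))
      as.data.frame(do.call(rbind, l))
    }
    levels[[as.character(s)]] <- list(
      size = s, unknown = uk,
      met = vapply(emus[uk], `[[`, "", "met"),
      known = known,
      A_trip = to_df(A_trip, c("i", "j", "f", "w")),
      B_trip = to_df(B_trip, c("i", "j", "f", "w")),
      diag = to_df(diag_terms, c("i", "f", "w")))
  }
  structure(list(sizes = sizes, levels = levels, emus = emus,
                 targets = vapply(targets, emu_id, ""),
                 flux_ids = names(model$reactions),
                 n_unknown = length(unknown_ids)),
            class = "emu_network")
}

consumption_table <- function(model) {
  out <- list()
  for (j in seq_along(model$reactions)) {
    rx <- model$reactions[[j]]
    for (k in seq_len(nrow(rx$substrates))) {
      n <- rx$substrates$name[k]
      out[[n]] <- rbind(out[[n]],
                        data.frame(flux_index = j, coef = rx$substrates$coef[k]))
    }
  }
  out
}

#' @export
print.emu_network <- function(x, ...) {
  cat("<emu_network> ", x$n_unknown, " unknown EMUs over sizes {",
      paste(x$sizes, collapse = ", "), "}; targets: ",
      paste(x$targets, collapse = ", "), "\n", sep = "")
  for (s in as.character(x$sizes)) {
    lv <- x$levels[[s]]
    cat("  size ", s, ": ", length(lv$unknown), " unknown, ",
        length(lv$known), " known entries\n", sep = "")
  }
  invisible(x)
}

#' Assemble the per-size EMU balance matrices
#'
#' Builds the linear system `A_s Z_s = B_s Y_s` for one EMU size: the
#' diagonal of `A_s` carries minus the total flux consuming each unknown
#' EMU's metabolite, off-diagonal entries the fluxes between unknown EMUs
#' of this size, and `B_s` (with negative sign) the inflows from known
#' EMUs — carbon-source EMUs and convolutions of already-solved smaller
#' EMUs.
#'
#' @param net an `emu_network`.
#' @param size EMU size (must be one of `net$sizes`).
#' @param v named flux vector over all reactions.
#' @param labeling an [substrate_labeling()] object resolving source EMUs.
#' @param solved named list (EMU id -> MDV) of already-solved smaller
#'   unknowns; may be empty if this size has no convolution inputs.
#' @return list with numeric matrices `A`, `B`, `Y` and the `unknown` ids.
#' @export
assemble_balance_matrices <- function(net, size, v, labeling, solved = list()) {
  lv <- net$levels[[as.character(size)]]
  if (is.null(lv)) stop("no EMUs of size ", size, " in this network", call. = FALSE)
  v <- flux_vec(net$flux_ids, v)
  n <- length(lv$unknown); m <- length(lv$known)
  A <- matrix(0, n, n, dimnames = list(lv$unknown, lv$unknown))
  B <- matrix(0, n, max(m, 1L))
  if (nrow(lv$diag)) {
    dsum <- rowsum(v[lv$diag$f] * lv$diag$w, lv$diag$i)
    A[cbind(as.integer(rownames(dsum)), as.integer(rownames(dsum)))] <- -dsum[, 1]
  }
  if (any(diag(A) == 0)) {
    bad <- lv$unknown[which(diag(A) == 0)]
    stop("zero total consumption flux for ", paste(unique(lv$met[match(bad, lv$unknown)]),
         collapse = ", "), ": balance is singular", call. = FALSE)
  }
  if (nrow(lv$A_trip))
    for (r in seq_len(nrow(lv$A_trip)))
      A[lv$A_trip$i[r], lv$A_trip$j[r]] <-
        A[lv$A_trip$i[r], lv$A_trip$j[r]] + lv$A_trip$w[r] * v[lv$A_trip$f[r]]
  if (nrow(lv$B_trip))
    for (r in seq_len(nrow(lv$B_trip)))
      B[lv$B_trip$i[r], lv$B_trip$j[r]] <-
        B[lv$B_trip$i[r], lv$B_trip$j[r]] - lv$B_trip$w[r] * v[lv$B_trip$f[r]]
  Y <- matrix(0, max(m, 1L), size + 1L)
  for (j in seq_len(m)) {
    Y[j, ] <- known_mdv(lv$known[[j]], labeling, solved, size)
  }
  list(A = A, B = B, Y = Y, unknown = lv$unknown)
}

known_mdv <- function(spec, labeling, solved, size) {
  if (spec$type == "source") {
    source_mdv(labeling, spec$met, spec$atoms)
  } else {
    part <- function(p) {
      if (p$type == "source") source_mdv(labeling, p$met, p$atoms)
      else {
        md <- solved[[p$id]]
        if (is.null(md)) stop("convolution input ", p$id, " not solved yet",
                              call. = FALSE)
        md
      }
    }
    md <- convolve_mdv(part(spec$parts[[1]]), part(spec$parts[[2]]))
    stopifnot(length(md) == size + 1L)
    md
  }
}

# normalize a flux vector against the model's reaction order
flux_vec <- function(flux_ids, v) {
  if (is.null(names(v))) {
    if (length(v) != length(flux_ids))
      stop("flux vector length does not match the model", call. = FALSE)
    return(setNames(as.numeric(v), flux_ids))
  }
  miss <- setdiff(flux_ids, names(v))
  if (length(miss))
    stop("flux vector missing: ", paste(miss, collapse = ", "), call. = FALSE)
  setNames(as.numeric(v[flux_ids]), flux_ids)
}

#' Measured-fragment targets from an MSReac table
#'
#' @param msreac fragment definition table or CSV path: columns
#'   `Fragment`, `Metabolite`, `First_atom`, `Last_atom`.
#' @return named list of [emu()] targets (names are fragment labels).
#' @export
msreac_targets <- function(msreac) {
  if (is.character(msreac)) msreac <- read.csv(msreac, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(msreac)), function(i)
    emu(as.character(msreac$Metabolite[i]),
        seq.int(msreac$First_atom[i], msreac$Last_atom[i])))
  names(out) <- as.character(msreac$Fragment)
  out
}
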