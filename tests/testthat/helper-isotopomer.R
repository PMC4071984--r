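# Independent steady-state oracle over full positional isotopomers.
#
# Works directly from the configuration table (not through the package's
# EMU machinery): every balanced metabolite carries a distribution over
# its 2^c positional labeling patterns; a Jacobi fixed-point iteration
# balances isotopomer-resolved production against total consumption.
# Exponential-cost, only usable for tiny networks -- which is the point:
# it is an exhaustive cross-check for the EMU cascade.

iso_oracle <- function(config, v, sources, sym = character(0),
                       tol = 1e-13, max_iter = 200000L) {
  # parse the table minimally and independently
  rxns <- list()
  carbons <- list()
  for (i in seq_len(nrow(config))) {
    map <- trimws(config$Carbon_transitions[i])
    eq <- strsplit(config$Rxns[i], "->", fixed = TRUE)[[1]]
    subs <- trimws(strsplit(eq[1], "+", fixed = TRUE)[[1]])
    prods <- trimws(strsplit(eq[2], "+", fixed = TRUE)[[1]])
    if (nzchar(map)) {
      sides <- strsplit(map, "->", fixed = TRUE)[[1]]
      sstr <- trimws(strsplit(sides[1], "+", fixed = TRUE)[[1]])
      pstr <- trimws(strsplit(sides[2], "+", fixed = TRUE)[[1]])
      for (k in seq_along(subs)) carbons[[subs[k]]] <- nchar(sstr[k])
      for (k in seq_along(prods)) carbons[[prods[k]]] <- nchar(pstr[k])
    } else { sstr <- NULL; pstr <- NULL }
    rxns[[config$FluxID[i]]] <- list(id = config$FluxID[i], subs = subs,
                                     prods = prods, sstr = sstr, pstr = pstr)
  }
  balanced <- setdiff(names(carbons),
                      c(names(sources),
                        grep("^(Subs_|Ind_)|\\[", names(carbons), value = TRUE)))
  balanced <- balanced[!grepl("^\\[", balanced)]

  nb <- function(m) carbons[[m]]
  bit <- function(p, k) bitwAnd(bitwShiftR(p, k - 1L), 1L)

  # source distributions over patterns (list: met -> numeric(2^c));
  # unbalanced Ind_ donors are unlabeled
  dist0 <- function(m) {
    c <- nb(m); d <- numeric(2^c)
    if (!is.null(sources[[m]])) {
      for (r in seq_len(nrow(sources[[m]]))) {
        bits <- as.integer(strsplit(sources[[m]]$pattern[r], "")[[1]])
        d[sum(bits * 2^(seq_along(bits) - 1L)) + 1L] <-
          sources[[m]]$fraction[r]
      }
    } else d[1] <- 1
    d
  }

  # expand symmetric orientations of every mapped reaction
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  variants <- list()
  for (rx in rxns) {
    if (is.null(rx$sstr)) next
    s_opts <- lapply(seq_along(rx$subs), function(k)
      if (rx$subs[k] %in% sym)
        list(list(rx$sstr[k], 0.5), list(revstr(rx$sstr[k]), 0.5))
      else list(list(rx$sstr[k], 1)))
    p_opts <- lapply(seq_along(rx$prods), function(k)
      if (rx$prods[k] %in% sym)
        list(list(rx$pstr[k], 0.5), list(revstr(rx$pstr[k]), 0.5))
      else list(list(rx$pstr[k], 1)))
    grid <- expand.grid(c(lapply(s_opts, seq_along), lapply(p_opts, seq_along)))
    for (g in seq_len(nrow(grid))) {
      w <- 1; sstr <- character(length(rx$subs)); pstr <- character(length(rx$prods))
      for (k in seq_along(rx$subs)) {
        o <- s_opts[[k]][[grid[g, k]]]; sstr[k] <- o[[1]]; w <- w * o[[2]]
      }
      for (k in seq_along(rx$prods)) {
        o <- p_opts[[k]][[grid[g, length(rx$subs) + k]]]
        pstr[k] <- o[[1]]; w <- w * o[[2]]
      }
      variants[[length(variants) + 1L]] <-
        list(id = rx$id, subs = rx$subs, prods = rx$prods,
             sstr = sstr, pstr = pstr, w = w)
    }
  }

  # total consumption flux per balanced metabolite
  outflux <- setNames(numeric(length(balanced)), balanced)
  for (rx in rxns) for (s in rx$subs)
    if (s %in% balanced) outflux[s] <- outflux[s] + v[rx$id]

  state <- lapply(setNames(balanced, balanced),
                  function(m) { d <- numeric(2^nb(m)); d[1] <- 1; d })
  get_dist <- function(m) if (m %in% balanced) state[[m]] else dist0(m)

  for (it in seq_len(max_iter)) {
    inflow <- lapply(setNames(balanced, balanced),
                     function(m) numeric(2^nb(m)))
    for (va in variants) {
      hit <- which(va$prods %in% balanced)
      if (!length(hit)) next
      dists <- lapply(va$subs, get_dist)
      ncarb <- vapply(va$sstr, nchar, 0L)
      # joint enumeration over all substrate patterns
      idx <- rep(0L, length(dists))
      repeat {
        pr <- va$w * v[va$id] *
          prod(vapply(seq_along(dists), function(k) dists[[k]][idx[k] + 1L], 0))
        if (pr > 0) {
          # letter -> 13C lookup for this joint pattern
          lab <- list()
          for (k in seq_along(va$subs)) {
            letters_k <- strsplit(va$sstr[k], "")[[1]]
            for (a in seq_along(letters_k))
              lab[[letters_k[a]]] <- bit(idx[k], a)
          }
          for (pk in hit) {
            pl <- strsplit(va$pstr[pk], "")[[1]]
            pat <- 0L
            for (a in seq_along(pl))
              if (lab[[pl[a]]] == 1L) pat <- pat + 2L^(a - 1L)
            inflow[[va$prods[pk]]][pat + 1L] <-
              inflow[[va$prods[pk]]][pat + 1L] + pr
          }
        }
        k <- 1L
        while (k <= length(idx)) {
          idx[k] <- idx[k] + 1L
          if (idx[k] < 2L^ncarb[k]) break
          idx[k] <- 0L; k <- k + 1L
        }
        if (k > length(idx)) break
      }
    }
    newstate <- lapply(setNames(balanced, balanced),
                       function(m) inflow[[m]] / outflux[m])
    delta <- max(vapply(balanced, function(m)
      max(abs(newstate[[m]] - state[[m]])), 0))
    state <- newstate
    if (delta < tol) break
  }

  # aggregate to MDVs
  mdvs <- lapply(setNames(balanced, balanced), function(m) {
    c <- nb(m); md <- numeric(c + 1L)
    for (p in 0:(2^c - 1L)) {
      n13 <- sum(vapply(1:c, function(k) bit(p, k), 0L))
      md[n13 + 1L] <- md[n13 + 1L] + state[[m]][p + 1L]
    }
    md
  })
  list(mdvs = mdvs, iterations = it, delta = delta)
}

tca_oracle_sources <- function() {
  list(
    Subs_PYR_EX = data.frame(pattern = c("100", "111"),
                             fraction = c(0.5, 0.5)),
    Subs_GLU_EX = data.frame(pattern = "10000", fraction = 1))
}
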