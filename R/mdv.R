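#' Mass distribution vectors
#'
#' A mass distribution vector (MDV) holds the relative abundances
#' `m+0, m+1, ..., m+n` of the molecules of a fragment carrying 0 to n
#' tracer (13C) carbons.  Entries are nonnegative and sum to 1.  MDVs are
#' represented as plain numeric vectors throughout the package; these
#' helpers validate and combine them.
#'
#' @param x numeric vector of fractional abundances.
#' @param tol numerical slack allowed below zero and around the unit sum.
#' @return `as_mdv()` returns the validated, renormalized numeric vector.
#' @examples
#' as_mdv(c(2, 1, 1))          # normalized to c(0.5, 0.25, 0.25)
#' @export
as_mdv <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("an MDV must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(x)))
    stop("MDV contains non-finite entries", call. = FALSE)
  if (any(x < -tol))
    stop("MDV has negative entries beyond tolerance", call. = FALSE)
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) stop("degenerate spectrum: all MDV entries are zero", call. = FALSE)
  unname(x / s)
}

#' Convolve two mass distribution vectors
#'
#' The MDV of a molecule assembled from two independent precursor units is
#' the discrete convolution of the precursor MDVs.  This is the elementary
#' combination rule behind condensation reactions in the EMU cascade.
#'
#' @param a,b numeric MDVs (length = carbons + 1).
#' @return numeric MDV of length `length(a) + length(b) - 1`, normalized.
#' @examples
#' convolve_mdv(c(0.5, 0.5), c(0.5, 0.5))  # c(0.25, 0.5, 0.25)
#' @export
convolve_mdv <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || !length(a) || !length(b))
    stop("convolve_mdv() needs two non-empty numeric vectors", call. = FALSE)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  s <- sum(out)
  if (s <= 0) stop("degenerate convolution result", call. = FALSE)
  out / s
}

# MDV of a single source metabolite restricted to a set of atom positions,
# given a positional labeling mixture (rows: pattern string, fraction).
mixture_mdv <- function(mix, atoms) {
  k <- length(atoms)
  out <- numeric(k + 1L)
  for (i in seq_len(nrow(mix))) {
    bits <- pattern_bits(mix$pattern[i])
    n13 <- sum(bits[atoms])
    out[n13 + 1L] <- out[n13 + 1L] + mix$fraction[i]
  }
  as_mdv(out)
}

# "100" -> c(1,0,0); also accepts named forms relative to a carbon count.
pattern_bits <- function(pattern, carbons = NULL) {
  p <- trimws(pattern)
  if (grepl("^[01]+$", p)) return(as.integer(strsplit(p, "")[[1]]))
  if (is.null(carbons))
    stop("named labeling pattern '", p, "' needs a carbon count", call. = FALSE)
  if (toupper(p) %in% c("U-13C", "U13C")) return(rep(1L, carbons))
  if (toupper(p) %in% c("UNLABELED", "12C")) return(rep(0L, carbons))
  m <- regmatches(p, regexec("^([0-9,]+)-13C$", p, ignore.case = TRUE))[[1]]
  if (length(m) == 2L) {
    pos <- as.integer(strsplit(m[2], ",")[[1]])
    if (any(pos < 1L | pos > carbons))
      stop("labeled position out of range in pattern '", p, "'", call. = FALSE)
    bits <- rep(0L, carbons)
    bits[pos] <- 1L
    return(bits)
  }
  stop("cannot parse labeling pattern '", p, "'", call. = FALSE)
}
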