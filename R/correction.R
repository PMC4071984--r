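#' Natural isotope abundance table
#'
#' Per-element mass-shift distributions of the naturally occurring
#' isotopes used to build correction matrices.  Values are IUPAC
#' representative isotopic compositions (CIAAW); index k of each vector is
#' the fraction of atoms heavier by k mass units.
#'
#' @return named list of numeric vectors (element -> mass-shift
#'   distribution).
#' @export
natural_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
    Si = c(0.92223, 0.04685, 0.03092))
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (0-based) is the observable mass distribution produced by a
#' fragment carrying exactly `j` tracer 13C atoms on its carbon skeleton:
#' the convolution of the natural-isotope distributions of every
#' non-skeleton atom (including carbons outside the skeleton, e.g. from
#' derivatization), shifted up by `j`.  With `correct_skeleton = TRUE`
#' (default) the natural 13C of the remaining `skeleton - j` unlabeled
#' skeleton positions is convolved in as well.
#'
#' @param composition one-row `data.frame` with element-count columns
#'   (`C`, `H`, `N`, `O`, `S`, `Si`, ... ; missing columns count 0) and a
#'   `Skeleton_C` column giving the number of tracer-labelable carbons,
#'   or a named list/vector of the same.
#' @param window number of observed mass channels (rows of the matrix);
#'   must be at least `Skeleton_C + 1`.
#' @param correct_skeleton also correct natural 13C on unlabeled skeleton
#'   positions.
#' @param abundances isotope table, by default [natural_abundances()].
#' @return `window` x `(Skeleton_C + 1)` matrix `K` mapping a skeleton MDV
#'   to the observable spectrum, `raw = K %*% mdv`.
#' @export
build_correction_matrix <- function(composition, window,
                                    correct_skeleton = TRUE,
                                    abundances = natural_abundances()) {
  comp <- as.list(composition)
  skel <- as.integer(comp$Skeleton_C)
  if (is.null(skel) || is.na(skel))
    stop("composition needs a Skeleton_C entry", call. = FALSE)
  counts <- comp[!(names(comp) %in% c("Fragment", "Skeleton_C"))]
  counts <- counts[vapply(counts, function(x) is.numeric(x) && !is.na(x), TRUE)]
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(abundances), collapse = ", "),
         call. = FALSE)
  nC <- if (is.null(counts$C)) 0L else as.integer(counts$C)
  if (skel > nC && nC > 0)
    stop("Skeleton_C exceeds the fragment's carbon count", call. = FALSE)
  if (window < skel + 1L)
    stop("window too small: need at least Skeleton_C + 1 channels",
         call. = FALSE)
  # fixed envelope from all non-skeleton atoms
  base <- 1
  for (el in names(counts)) {
    k <- as.integer(counts[[el]])
    if (el == "C") k <- k - skel
    if (k < 0) stop("negative count for element ", el, call. = FALSE)
    if (k > 0) for (q in seq_len(k)) base <- conv_raw(base, abundances[[el]])
  }
  pC <- abundances$C[2] / sum(abundances$C[1:2])
  K <- matrix(0, window, skel + 1L)
  for (j in 0:skel) {
    col <- base
    if (correct_skeleton && skel - j > 0)
      col <- conv_raw(col, dbinom(0:(skel - j), skel - j, pC))
    col <- c(rep(0, j), col)  # j tracer carbons shift the envelope up by j
    length(col) <- window     # truncate/pad to the measured window
    col[is.na(col)] <- 0
    K[, j + 1L] <- col
  }
  K
}

# unnormalized discrete convolution (distributions need not sum to 1
# after truncation)
conv_raw <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Correct a raw mass spectrum for natural isotope abundance
#'
#' Recovers the tracer-only (carbon-skeleton) MDV from a raw intensity
#' vector by solving `K m ~ raw` in the least-squares sense with
#' nonnegativity (default), then normalizing to sum 1.
#'
#' @param raw nonnegative intensity vector over the measured mass window.
#' @param K correction matrix from [build_correction_matrix()] with
#'   `nrow(K) == length(raw)`.
#' @param method `"nnls"` (nonnegative least squares, default) or
#'   `"pinv"` (plain least squares, for diagnostics; warns and falls back
#'   to nnls if the unconstrained solution is negative beyond tolerance).
#' @return corrected MDV of length `ncol(K)`.
#' @export
correct_spectrum <- function(raw, K, method = c("nnls", "pinv")) {
  method <- match.arg(method)
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("raw intensities must be nonnegative", call. = FALSE)
  if (all(raw == 0)) stop("degenerate spectrum: all intensities zero", call. = FALSE)
  if (length(raw) != nrow(K))
    stop("window too small: spectrum has ", length(raw),
         " channels but the correction matrix expects ", nrow(K), call. = FALSE)
  if (method == "pinv") {
    m <- qr.solve(K, raw)
    if (any(m < -1e-8)) {
      warning("unconstrained correction went negative; falling back to ",
              "nonnegative least squares", call. = FALSE)
      m <- pracma::lsqnonneg(K, raw)$x
    }
  } else {
    m <- pracma::lsqnonneg(K, raw)$x
  }
  as_mdv(m)
}
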