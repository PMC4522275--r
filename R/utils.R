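#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so package functions never consume
#' ambient randomness.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Spectral angle between two spectra
#'
#' The angle `arccos(<a,b> / (||a|| ||b||))` in degrees; 0 for collinear
#' spectra, 90 for orthogonal ones. Standard measure of endmember
#' similarity in spectral unmixing.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Angle in degrees.
#' @export
#' @examples
#' spectral_angle_deg(c(1, 0), c(0, 1)) # 90
spectral_angle_deg <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# K x K matrix of pairwise spectral angles for a K x B spectra matrix.
pairwise_angles <- function(S) {
  K <- nrow(S)
  A <- matrix(0, K, K, dimnames = list(rownames(S), rownames(S)))
  if (K < 2) return(A)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    A[i, j] <- A[j, i] <- spectral_angle_deg(S[i, ], S[j, ])
  }
  A
}

#' Nearest-rank percentile
#'
#' The k-th smallest value with `k = ceiling(p/100 * n)`: the classical
#' nearest-rank definition, used for deriving scoring thresholds from
#' control cells.
#'
#' @param x Numeric vector (non-empty).
#' @param p Percentile in (0, 100].
#' @return A single value of `x`.
#' @export
#' @examples
#' nearest_rank(1:100 / 100, 95) # 0.95
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1, is.finite(p), p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Peak-normalize rows of a spectra matrix to max 1; errors on all-zero rows.
peak_normalize <- function(S) {
  m <- apply(S, 1, max)
  if (any(m <= 0)) {
    stop("cannot peak-normalize: all-zero spectrum for ",
         paste(rownames(S)[m <= 0], collapse = ", "))
  }
  sweep(S, 1, m, "/")
}

# Canonical tissue-region labels, in tie-break priority order
# (follicle > t_zone > stroma > other); background is never a tissue class.
REGION_LEVELS <- c("follicle", "t_zone", "stroma", "other", "background")

# Four-class cell phenotypes.
PHENOTYPE_LEVELS <- c("lin-/dim", "lin+/dim", "lin+/bright", "lin-/bright")
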