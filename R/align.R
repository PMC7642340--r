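#' Smith-Waterman alignment score
#'
#' Scores with a linear gap cost (`gap` per gap position). `local` is the
#' classic maximal-scoring local alignment with score floor 0; `semilocal`
#' aligns the whole of `a` end-to-end while end gaps on `b` are free,
#' which locates a barcode anywhere inside a longer read.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-8, the
#'   scheme used for barcode dissimilarity and read labeling).
#' @param mode `"local"` or `"semilocal"`.
#' @return Integer alignment score (symmetric in `local` mode).
#' @export
#' @examples
#' sw_score("ACGT", "ACGT")  # 4
sw_score <- function(a, b, match = 1L, mismatch = -1L, gap = -8L,
                     mode = c("local", "semilocal")) {
  mode <- match.arg(mode)
  check_dna(a, "first sequence")
  check_dna(b, "second sequence")
  if (mode == "local")
    cpp_sw_local(a, b, as.integer(match), as.integer(mismatch), as.integer(gap))
  else
    cpp_sw_semilocal(a, b, as.integer(match), as.integer(mismatch),
                     as.integer(gap))
}

z_normalize <- function(x) {
  # degenerate rule: signals of length < 2 or zero spread pass unchanged
  if (length(x) < 2) return(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  (x - mean(x)) / s
}

#' Dynamic time warping distance between two signals
#'
#' Classic DTW with steps (i-1,j), (i,j-1), (i-1,j-1) and local cost
#' |a - b|; the accumulated cost is divided by the optimal warping path
#' length so sequences of different lengths are comparable. Inputs are
#' z-normalized first (skipped for signals of length < 2 or zero spread).
#' When given squiggles, the per-k-mer `event_levels` are compared, the
#' representation used for barcode separability.
#'
#' @param s1,s2 numeric vectors or [squiggle()] objects.
#' @param normalize z-normalize inputs before warping (default TRUE).
#' @return Nonnegative distance; 0 iff the normalized signals are
#'   identical. Symmetric, but not a metric (DTW violates the triangle
#'   inequality).
#' @export
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1), normalize = FALSE)  # 0
dtw_distance <- function(s1, s2, normalize = TRUE) {
  get_vec <- function(s) {
    if (inherits(s, "squiggle")) {
      v <- if (!is.null(s$event_levels)) s$event_levels else s$samples
    } else v <- as.numeric(s)
    if (length(v) == 0) stop("empty signal in DTW")
    v
  }
  x <- get_vec(s1)
  y <- get_vec(s2)
  if (normalize) {
    x <- z_normalize(x)
    y <- z_normalize(y)
  }
  r <- cpp_dtw(x, y)
  r$cost / r$path_length
}

# distances from one event-level vector to a list of them (z-normalized)
dtw_vs_set <- function(x, ys, normalize = TRUE) {
  if (normalize) {
    x <- z_normalize(x)
    ys <- lapply(ys, z_normalize)
  }
  cpp_dtw_vs_set(x, ys)
}
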