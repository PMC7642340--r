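#' Linear code specification
#'
#' Parameters of the random linear block code used for tags: codeword
#' length `n` (one bit per molbit), message length `k`, and guaranteed
#' correction radius `t`. A code with minimum distance `d` uniquely
#' corrects `floor((d - 1) / 2)` bit errors, so `required_min_distance`
#' defaults to `2 t + 1`.
#'
#' @param n codeword length in bits (default 96).
#' @param k message length in bits (default 32).
#' @param t guaranteed correction radius in bit errors (default 9).
#' @param required_min_distance minimum codeword weight demanded of an
#'   accepted generator matrix (default `2 * t + 1`).
#' @return An object of class `code_spec`.
#' @export
code_spec <- function(n = 96, k = 32, t = 9,
                      required_min_distance = 2 * t + 1) {
  if (k >= n) stop("k must be < n")
  if (t != (required_min_distance - 1) %/% 2)
    stop("t must equal floor((required_min_distance - 1) / 2)")
  structure(list(n = as.integer(n), k = as.integer(k), t = as.integer(t),
                 required_min_distance = as.integer(required_min_distance)),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf("[%d,%d] binary code spec, corrects t=%d errors (min distance >= %d)\n",
              x$n, x$k, x$t, x$required_min_distance))
  invisible(x)
}

as_bits <- function(x, len = NULL, what = "bit vector") {
  if (is.character(x) && length(x) == 1)
    x <- as.integer(strsplit(x, "")[[1]])
  x <- as.integer(x)
  if (any(is.na(x)) || any(!x %in% c(0L, 1L)))
    stop(what, " must contain only 0s and 1s")
  if (!is.null(len) && length(x) != len)
    stop(what, " must have length ", len, ", got ", length(x))
  x
}

#' Convert ASCII text to bits and back
#'
#' 8 bits per character, most significant bit first, so a 4-character
#' string such as "MISL" becomes a 32-bit message.
#'
#' @param text a printable ASCII string.
#' @param bits integer 0/1 vector with length a multiple of 8.
#' @return `ascii_to_bits`: integer 0/1 vector of length `8 * nchar(text)`;
#'   `bits_to_ascii`: the decoded string.
#' @export
#' @examples
#' ascii_to_bits("M")  # 0 1 0 0 1 1 0 1  (ASCII 77)
#' bits_to_ascii(ascii_to_bits("MISL"))  # "MISL"
ascii_to_bits <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  codes <- utf8ToInt(text)
  if (any(codes > 127)) stop("non-ASCII character in message text")
  as.integer(unlist(lapply(codes, function(cc)
    as.integer(intToBits(cc))[8:1])))
}

#' @rdname ascii_to_bits
#' @export
bits_to_ascii <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) %% 8 != 0) stop("bit length must be a multiple of 8")
  codes <- vapply(split(bits, rep(seq_len(length(bits) / 8), each = 8)),
                  function(b) sum(b * 2^(7:0)), numeric(1))
  intToUtf8(codes)
}

#' Search for the minimum nonzero codeword weight of a generator matrix
#'
#' For `k <= 20` all `2^k` codewords are enumerated, giving the exact
#' minimum distance. Otherwise an information-set search is used:
#' repeatedly Gaussian-eliminate the matrix to systematic form on a
#' random column set and record the weights of the rows and all pairwise
#' row sums. The result is then an upper bound on the true minimum
#' distance that converges quickly for low-weight codewords.
#'
#' @param G a [generator_matrix()] or 0/1 matrix.
#' @param iters number of information sets to try.
#' @param seed optional seed.
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) full enumeration;
#'   default `NULL` picks by `k`.
#' @return Smallest nonzero codeword weight found.
#' @export
min_weight_search <- function(G, iters = 20000, seed = NULL,
                              exhaustive = NULL) {
  M <- gm_bits(G)
  if (is.null(exhaustive)) exhaustive <- nrow(M) <= 20
  if (exhaustive) {
    if (nrow(M) > 24) stop("exhaustive enumeration limited to k <= 24")
    return(cpp_min_weight_exhaustive(M))
  }
  with_seed(seed, cpp_min_weight_isd(M, as.integer(iters), TRUE))
}

gm_bits <- function(G) {
  if (inherits(G, "generator_matrix")) return(G$bits)
  M <- as.matrix(G)
  storage.mode(M) <- "integer"
  if (any(!M %in% c(0L, 1L))) stop("generator matrix must be 0/1")
  M
}

#' Construct a random generator matrix with verified distance
#'
#' Rejection-samples uniform k-by-n binary matrices of full rank over
#' GF(2), accepting the first whose low-weight search (a quick scan, then
#' `search_iters` information sets) finds no nonzero codeword of weight
#' below `spec$required_min_distance`. The accepted matrix therefore has
#' verified minimum distance at least that value up to search error,
#' guaranteeing unique correction of `spec$t` bit errors.
#'
#' @param spec a [code_spec()].
#' @param seed integer seed; the construction is deterministic given it.
#' @param search_iters information sets used to certify the accepted
#'   matrix (a cheaper scan rejects bad candidates early).
#' @param max_matrices candidate budget before giving up.
#' @return An object of class `generator_matrix` with fields `bits`
#'   (k x n 0/1 matrix), `seed`, `verified_weight_floor` and `spec`.
#' @export
make_generator_matrix <- function(spec = code_spec(), seed = 1,
                                  search_iters = 20000,
                                  max_matrices = 5000) {
  with_seed(seed, {
    exhaustive <- spec$k <= 20
    for (i in seq_len(max_matrices)) {
      M <- matrix(sample(0:1, spec$k * spec$n, replace = TRUE),
                  nrow = spec$k)
      if (cpp_gf2_rank(M) < spec$k) next
      if (exhaustive) {
        w <- cpp_min_weight_exhaustive(M)
      } else {
        # quick scan to reject obviously bad candidates cheaply
        w <- cpp_min_weight_isd(M, 2000L, TRUE)
        if (w >= spec$required_min_distance)
          w <- cpp_min_weight_isd(M, as.integer(search_iters), TRUE)
      }
      if (w >= spec$required_min_distance) {
        return(structure(list(bits = M, seed = seed,
                              verified_weight_floor = spec$required_min_distance,
                              candidates_tried = i,
                              search_iters = search_iters,
                              spec = spec),
                         class = "generator_matrix"))
      }
    }
    stop("no matrix with min weight >= ", spec$required_min_distance,
         " found in ", max_matrices, " candidates; consider lowering ",
         "required_min_distance")
  })
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat(sprintf("[%d,%d] random generator matrix (seed %s), no codeword of weight < %d found\n",
              x$spec$n, x$spec$k, format(x$seed), x$verified_weight_floor))
  invisible(x)
}

#' Encode a message with a generator matrix
#'
#' Codeword = message x G over GF(2).
#'
#' @param message k-bit 0/1 vector (or "0101..." string).
#' @param G a [generator_matrix()].
#' @return n-bit 0/1 integer vector.
#' @export
encode_message <- function(message, G) {
  M <- gm_bits(G)
  m <- as_bits(message, len = nrow(M), what = "message")
  as.integer((m %*% M) %% 2L)
}

#' Decode a received word to the nearest codeword
#'
#' `exhaustive` enumerates all `2^k` codewords (only for `k <= 24`);
#' `isd` uses information-set decoding: sample k columns forming an
#' invertible submatrix, re-encode the message they imply, and accept as
#' soon as a codeword within Hamming distance `spec$t` of the received
#' word is found. A decoding is reported `unique` only when its distance
#' is at most `t` (which the code's verified minimum distance makes
#' provably unique); anything further away is a `failure` carrying the
#' best distance seen.
#'
#' @param received n-bit 0/1 vector.
#' @param G a [generator_matrix()].
#' @param spec a [code_spec()]; defaults to the one stored in `G`.
#' @param strategy `"auto"` picks exhaustive for `k <= 24`, else ISD.
#' @param iters information sets for ISD.
#' @param seed optional seed for ISD column sampling.
#' @return An object of class `decode_result` with fields `message`,
#'   `distance`, `candidates_tried`, `status` (`"unique"`/`"failure"`).
#' @export
decode_nearest <- function(received, G, spec = NULL,
                           strategy = c("auto", "exhaustive", "isd"),
                           iters = 2000, seed = NULL) {
  strategy <- match.arg(strategy)
  M <- gm_bits(G)
  if (is.null(spec)) {
    spec <- if (inherits(G, "generator_matrix")) G$spec
            else stop("spec required when G is a plain matrix")
  }
  r <- as_bits(received, len = ncol(M), what = "received word")
  if (strategy == "auto")
    strategy <- if (nrow(M) <= 24) "exhaustive" else "isd"
  if (strategy == "exhaustive") {
    res <- cpp_decode_exhaustive(r, M)
    unique_ok <- res$distance <= spec$t && res$n_at_min == 1L
    out <- list(message = res$message, distance = res$distance,
                candidates_tried = 2L^nrow(M),
                status = if (unique_ok) "unique" else "failure")
  } else {
    res <- with_seed(seed, cpp_decode_isd(r, M, spec$t, as.integer(iters)))
    out <- list(message = res$message, distance = res$distance,
                candidates_tried = res$candidates_tried,
                status = if (res$found) "unique" else "failure")
  }
  structure(out, class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  if (x$status == "unique") {
    cat(sprintf("decoded (distance %d): %s", x$distance,
                paste(x$message, collapse = "")))
    if (length(x$message) %% 8 == 0)
      cat(sprintf('  ("%s")', bits_to_ascii(x$message)))
    cat("\n")
  } else {
    cat(sprintf("decoding failure (best distance %d)\n", x$distance))
  }
  if (!is.null(x$threshold_used))
    cat(sprintf("  count threshold %.4g, %d candidate decodings tried\n",
                x$threshold_used, x$candidates_tried))
  invisible(x)
}

#' Fit a per-molbit count scaling vector from calibration runs
#'
#' Per-molbit read counts vary widely (tens-fold) but consistently across
#' runs. Counts are normalized within each calibration run (divided by
#' the run total over present molbits), the per-molbit expected relative
#' abundance is the mean across runs where the molbit was present, and
#' the scaling factor is its reciprocal, renormalized to mean 1. Scaled
#' counts of present molbits are then comparable across molbits.
#'
#' @param calibration list of count vectors (length n each), or a single
#'   matrix with runs in rows.
#' @param presence list (or matrix) of known 0/1 presence vectors, one
#'   per calibration run.
#' @return An object of class `scaling_vector`: positive numeric factors
#'   of length n, mean 1 over calibrated molbits.
#' @export
fit_scaling_vector <- function(calibration, presence) {
  if (is.matrix(calibration))
    calibration <- split(calibration, row(calibration))
  if (is.matrix(presence))
    presence <- split(presence, row(presence))
  stopifnot(length(calibration) == length(presence))
  calibration <- lapply(calibration, count_values)
  n <- length(calibration[[1]])
  rel <- matrix(NA_real_, length(calibration), n)
  for (i in seq_along(calibration)) {
    cnt <- calibration[[i]]
    pres <- as_bits(presence[[i]], len = n, what = "presence vector") == 1L
    tot <- sum(cnt[pres])
    if (tot <= 0) stop("calibration run ", i, " has no reads on present molbits")
    rel[i, pres] <- cnt[pres] / tot
  }
  expected <- colMeans(rel, na.rm = TRUE)
  never <- !is.finite(expected) | is.nan(expected)
  if (any(never)) {
    warning(sum(never), " molbit(s) never present in calibration; factor 1 used")
    expected[never] <- NA
  }
  factors <- ifelse(is.na(expected) | expected <= 0, NA, 1 / expected)
  factors <- factors / mean(factors, na.rm = TRUE)
  factors[is.na(factors)] <- 1
  structure(factors, class = "scaling_vector",
            source = names(calibration))
}

count_values <- function(counts) {
  if (inherits(counts, "count_vector")) counts <- counts$counts
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts
}

#' Decode a molecular tag from per-molbit read counts
#'
#' Scales the counts, then sweeps a presence threshold over the midpoints
#' between consecutive distinct sorted scaled counts: at each threshold
#' the counts are binarized (`count > threshold` is a 1) and decoded to
#' the nearest codeword. Among thresholds whose decoding lies within the
#' correction radius `t`, the minimum-distance decoding is returned (ties
#' resolved toward the lowest threshold); if no threshold succeeds the
#' result is a failure carrying the best distance observed. Thresholds
#' outside the observed count range are deliberately excluded: they
#' binarize to the all-zero (or all-one) word, and the all-zero word is
#' itself a codeword at distance zero, which would preempt every true
#' decoding. Counts with fewer than two distinct values consequently
#' cannot be binarized and fail.
#'
#' @param counts length-n nonnegative counts (or a `count_vector`).
#' @param G a [generator_matrix()].
#' @param spec a [code_spec()]; defaults to the one stored in `G`.
#' @param scaling optional [fit_scaling_vector()] result (or positive
#'   vector); `NULL` decodes raw counts.
#' @param iters,seed passed to [decode_nearest()] for ISD.
#' @return A `decode_result` with extra fields `threshold_used` and
#'   `binarized`.
#' @export
decode_tag <- function(counts, G, spec = NULL, scaling = NULL,
                       iters = 2000, seed = NULL) {
  M <- gm_bits(G)
  if (is.null(spec)) {
    spec <- if (inherits(G, "generator_matrix")) G$spec
            else stop("spec required when G is a plain matrix")
  }
  cnt <- count_values(counts)
  if (length(cnt) != spec$n)
    stop("counts must have length ", spec$n)
  if (!is.null(scaling)) {
    fac <- as.numeric(scaling)
    if (length(fac) != spec$n || any(fac <= 0))
      stop("scaling must be ", spec$n, " positive factors")
    cnt <- cnt * fac
  }
  u <- sort(unique(cnt))
  if (length(u) < 2) {
    return(structure(list(message = rep(NA_integer_, spec$k),
                          distance = NA_integer_,
                          threshold_used = NA_real_, binarized = NULL,
                          candidates_tried = 0L, status = "failure"),
                     class = "decode_result"))
  }
  thresholds <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  tried <- 0L
  for (th in thresholds) {
    bits <- as.integer(cnt > th)
    res <- decode_nearest(bits, G, spec, iters = iters, seed = seed)
    tried <- tried + 1L
    if (is.null(best) || res$distance < best$distance) {
      best <- res
      best$threshold_used <- th
      best$binarized <- bits
    }
  }
  best$candidates_tried <- tried
  # a result within t is a provably unique decoding; otherwise failure
  best$status <- if (best$distance <= spec$t) "unique" else "failure"
  best
}

#' Classify a read by raw signal length
#'
#' The spacer length channel: short (400 nt spacer) and long (1600 nt
#' spacer) molbits separate cleanly by raw signal length; a read at or
#' below the cutoff is called short.
#'
#' @param signal_length raw signal length(s) in samples.
#' @param cutoff decision boundary (default 9800 samples; the boundary
#'   itself is called short).
#' @return Character vector of `"short"`/`"long"`.
#' @export
#' @examples
#' classify_by_length(c(5768, 16968))  # "short" "long"
classify_by_length <- function(signal_length, cutoff = 9800) {
  if (any(signal_length <= 0)) stop("signal_length must be positive")
  ifelse(signal_length <= cutoff, "short", "long")
}

#' Estimate the probability of incorrect tag decoding
#'
#' `binomial_tail` returns `P(Binomial(n, p_bit) > t)`, the chance that
#' more bit errors occur than the code is guaranteed to correct — an
#' upper bound on the decoding failure probability. `monte_carlo` flips
#' each bit of random codewords independently with probability `p_bit`,
#' decodes, and reports the observed fraction of incorrect decodings
#' (wrong message or failure) with a 95% confidence interval.
#'
#' @param p_bit per-bit corruption probability.
#' @param spec a [code_spec()].
#' @param G a [generator_matrix()] (required for `monte_carlo`).
#' @param method `"binomial_tail"` or `"monte_carlo"`.
#' @param trials Monte-Carlo trials.
#' @param seed optional seed.
#' @return For `binomial_tail`, a probability. For `monte_carlo`, a list
#'   with `estimate`, `ci` (95% binomial), and `trials`.
#' @export
estimate_error_probability <- function(p_bit, spec = code_spec(), G = NULL,
                                       method = c("binomial_tail", "monte_carlo"),
                                       trials = 1000, seed = NULL) {
  method <- match.arg(method)
  if (p_bit < 0 || p_bit > 1) stop("p_bit must be in [0, 1]")
  if (method == "binomial_tail")
    return(pbinom(spec$t, spec$n, p_bit, lower.tail = FALSE))
  if (is.null(G)) stop("monte_carlo requires a generator matrix")
  M <- gm_bits(G)
  with_seed(seed, {
    wrong <- 0L
    for (i in seq_len(trials)) {
      m <- sample(0:1, spec$k, replace = TRUE)
      cw <- as.integer((m %*% M) %% 2L)
      flips <- rbinom(spec$n, 1L, p_bit)
      res <- decode_nearest(as.integer(xor(cw, flips)), G, spec)
      if (res$status != "unique" || !identical(res$message, m))
        wrong <- wrong + 1L
    }
    p <- wrong / trials
    se <- sqrt(max(p * (1 - p), 1e-12) / trials)
    list(estimate = p, ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
         trials = trials)
  })
}
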