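#' Squiggle objects
#'
#' A squiggle is the raw ionic current time series produced as a DNA
#' strand translocates a nanopore, here either simulated from a pore
#' model or supplied as measured samples.
#'
#' @param samples numeric vector of current values.
#' @param event_levels optional per-k-mer expected level vector.
#' @param seq_id provenance identifier.
#' @param normalized logical; TRUE once the signal has been MAD-rescaled.
#' @return An object of class `squiggle`.
#' @export
squiggle <- function(samples, event_levels = NULL, seq_id = "",
                     normalized = FALSE) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("squiggle samples must be nonempty")
  structure(list(samples = samples, event_levels = event_levels,
                 seq_id = seq_id, normalized = isTRUE(normalized)),
            class = "squiggle")
}

#' @export
print.squiggle <- function(x, ...) {
  cat(sprintf("squiggle%s: %d samples%s%s\n",
              if (nzchar(x$seq_id)) paste0(" '", x$seq_id, "'") else "",
              length(x$samples),
              if (!is.null(x$event_levels))
                sprintf(" (%d event levels)", length(x$event_levels)) else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.squiggle <- function(x, type = "l", xlab = "sample",
                          ylab = if (x$normalized) "normalized current"
                                 else "current (pA)", ...) {
  plot(x$samples, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Simulate a nanopore squiggle from a DNA sequence
#'
#' Slides the pore model over the sequence: event level i is the model
#' mean for the k-mer starting at position i. Each event level is then
#' held for a dwell (fixed `samples_per_base` samples, or geometric with
#' that mean), and Gaussian noise at the k-mer's `level_stdv` is added in
#' `noisy` mode.
#'
#' @param seq DNA string of length >= model k.
#' @param model a [pore_model()].
#' @param mode `"noiseless"` (pure level trace) or `"noisy"`.
#' @param dwell_model `"fixed"` (every event lasts exactly
#'   `samples_per_base` samples) or `"geometric"` (dwell ~ 1 + geometric,
#'   mean `samples_per_base`), emulating stochastic enzyme stepping.
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @return A [squiggle()] with `event_levels` of length
#'   `nchar(seq) - k + 1`.
#' @export
#' @examples
#' m <- synthetic_pore_model(4, seed = 1)
#' s <- simulate_squiggle(strrep("ACGT", 10), m, mode = "noiseless")
#' length(s$event_levels)  # 40 - 4 + 1
simulate_squiggle <- function(seq, model,
                              mode = c("noiseless", "noisy"),
                              dwell_model = c("fixed", "geometric"),
                              seed = NULL) {
  mode <- match.arg(mode)
  dwell_model <- match.arg(dwell_model)
  stopifnot(inherits(model, "pore_model"))
  check_dna(seq)
  k <- model$k
  n <- nchar(seq)
  if (n < k) stop("sequence shorter than model k-mer length")
  with_seed(seed, {
    starts <- seq_len(n - k + 1)
    kmers <- substring(seq, starts, starts + k - 1)
    levels <- unname(model$lookup[kmers])
    stdvs <- unname(model$noise[kmers])
    spb <- model$samples_per_base
    dwells <- if (dwell_model == "fixed") {
      rep.int(max(1L, as.integer(round(spb))), length(levels))
    } else {
      # dwell >= 1 sample, mean samples_per_base
      1L + rgeom(length(levels), prob = 1 / spb)
    }
    samples <- rep.int(levels, dwells)
    if (mode == "noisy")
      samples <- samples + rnorm(length(samples), 0, rep.int(stdvs, dwells))
    squiggle(samples, event_levels = levels, seq_id = seq,
             normalized = FALSE)
  })
}

#' Signal preprocessing configuration
#'
#' Parameters for the raw-signal preprocessing applied before
#' classification: MAD rescaling, stall trimming, and truncation to the
#' first `truncate_to` samples.
#'
#' @param truncate_to keep at most this many samples (default 3000).
#' @param mad_scale_constant MAD consistency constant (1.4826 makes the
#'   MAD a consistent estimator of the SD under normality).
#' @param stall_window rolling window (samples) used to detect the end of
#'   the low-variance stall region.
#' @param stall_sd_fraction a window counts as "live" once its SD exceeds
#'   this fraction of the global SD.
#' @param fixed_skip samples always dropped from the start of a read.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(truncate_to = 3000,
                              mad_scale_constant = 1.4826,
                              stall_window = 50,
                              stall_sd_fraction = 0.2,
                              fixed_skip = 200) {
  if (truncate_to <= 0) stop("truncate_to must be > 0")
  if (stall_window < 1) stop("stall_window must be >= 1")
  structure(list(truncate_to = as.integer(truncate_to),
                 mad_scale_constant = mad_scale_constant,
                 stall_window = as.integer(stall_window),
                 stall_sd_fraction = stall_sd_fraction,
                 fixed_skip = as.integer(fixed_skip)),
            class = "preprocess_config")
}

#' Rescale a raw signal by its median absolute deviation
#'
#' Centers at the median and divides by `mad_scale_constant * MAD`,
#' giving a robust z-score insensitive to current offset and gain.
#'
#' @param samples numeric vector.
#' @param config a [preprocess_config()].
#' @return Rescaled numeric vector with median 0.
#' @export
mad_normalize <- function(samples, config = preprocess_config()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty signal")
  med <- median(samples)
  m <- median(abs(samples - med))
  if (m == 0)
    stop("degenerate signal: MAD is zero (constant input)")
  (samples - med) / (config$mad_scale_constant * m)
}

#' Trim the leading stall region from a normalized signal
#'
#' Nanopore reads begin with a variable-length, low-variance "stall"
#' before the strand translocates. After dropping `fixed_skip` samples,
#' leading samples are removed until a rolling window of `stall_window`
#' samples has standard deviation above `stall_sd_fraction` times the
#' global SD. If no such window exists the fixed skip alone is applied,
#' so the result is never empty.
#'
#' @param samples numeric vector (normalized signal).
#' @param config a [preprocess_config()].
#' @return Trimmed numeric vector (never empty for nonempty input).
#' @export
trim_stall <- function(samples, config = preprocess_config()) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n == 0) stop("empty signal")
  skip <- min(config$fixed_skip, n - 1L)
  x <- samples[(skip + 1L):n]
  w <- config$stall_window
  if (length(x) <= w) return(x)
  gsd <- sd(x)
  if (!is.finite(gsd) || gsd == 0) return(x)
  thr <- config$stall_sd_fraction * gsd
  # rolling SD over non-overlapping-free sliding windows via cumulative sums
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  nw <- length(x) - w + 1L
  s1 <- cs[w:length(x)] - c(0, cs[seq_len(nw - 1L)])
  s2 <- cs2[w:length(x)] - c(0, cs2[seq_len(nw - 1L)])
  v <- pmax((s2 - s1^2 / w) / (w - 1L), 0)
  live <- which(sqrt(v) > thr)
  if (length(live) == 0) return(x)  # all-stall fallback: fixed skip only
  x[live[1]:length(x)]
}

#' Preprocess a raw signal for classification
#'
#' Composition of [mad_normalize()], [trim_stall()] and truncation to the
#' first `truncate_to` samples. Signals shorter than `truncate_to` are
#' kept unpadded (padding to a fixed input length is the classifier's
#' concern).
#'
#' @param samples numeric vector or a [squiggle()].
#' @param config a [preprocess_config()].
#' @param seq_id provenance carried into the result.
#' @return A normalized [squiggle()] of length <= `config$truncate_to`.
#' @export
preprocess_signal <- function(samples, config = preprocess_config(),
                              seq_id = "") {
  if (inherits(samples, "squiggle")) {
    if (!nzchar(seq_id)) seq_id <- samples$seq_id
    samples <- samples$samples
  }
  x <- mad_normalize(samples, config)
  x <- trim_stall(x, config)
  x <- x[seq_len(min(length(x), config$truncate_to))]
  squiggle(x, seq_id = seq_id, normalized = TRUE)
}
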