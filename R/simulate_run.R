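#' Synthetic sequencing-run model configuration
#'
#' Statistical model of a tag-decoding sequencing run: reads arrive as a
#' Poisson process at `reads_per_minute`; each present molbit carries a
#' static log-normal abundance factor (σ = 0.67 by default, which over 96
#' molbits gives a median max/min count spread around 25x, matching the
#' tens-fold dispersion seen between molbits in real runs); and each read
#' is independently misassigned to a uniformly random molbit with
#' probability `misassign_rate`, producing the nonzero background counts
#' observed for absent molbits.
#'
#' @param reads_per_minute mean read rate (default 10000).
#' @param abundance_sigma log-normal sigma of per-molbit abundance
#'   (default 0.67).
#' @param misassign_rate per-read misassignment probability (default 0.005).
#' @param duration run duration in minutes.
#' @param emit_signals also simulate a squiggle per read.
#' @param seed optional seed stored for convenience.
#' @return An object of class `run_model_config`.
#' @export
run_model_config <- function(reads_per_minute = 10000,
                             abundance_sigma = 0.67,
                             misassign_rate = 0.005,
                             duration = 1,
                             emit_signals = FALSE,
                             seed = NULL) {
  if (reads_per_minute <= 0 || duration <= 0) stop("rates must be positive")
  if (misassign_rate < 0 || misassign_rate >= 1)
    stop("misassign_rate must be in [0, 1)")
  if (abundance_sigma < 0) stop("abundance_sigma must be >= 0")
  structure(list(reads_per_minute = reads_per_minute,
                 abundance_sigma = abundance_sigma,
                 misassign_rate = misassign_rate,
                 duration = duration,
                 emit_signals = isTRUE(emit_signals),
                 seed = seed),
            class = "run_model_config")
}

draw_abundance <- function(codeword, sigma) {
  a <- numeric(length(codeword))
  ones <- which(codeword == 1L)
  a[ones] <- rlnorm(length(ones), 0, sigma)
  a
}

#' Simulate per-molbit read counts for a tag
#'
#' Reads are multinomial over the present (1-bit) molbits with
#' probabilities proportional to their abundance factors; each read is
#' then misassigned to a uniformly random molbit with probability
#' `config$misassign_rate`, which is what gives absent (0-bit) molbits
#' nonzero counts. Total reads are conserved.
#'
#' @param codeword n-bit 0/1 vector (at least one 1).
#' @param total_reads number of reads to distribute.
#' @param config a [run_model_config()].
#' @param seed optional seed.
#' @param abundance optional fixed per-molbit abundance factors (length
#'   n); by default drawn log-normal for the 1-bits. Supplying the same
#'   vector across runs models the run-to-run consistency that count
#'   rescaling exploits.
#' @return A [count_vector()] with attributes `abundance` and `codeword`
#'   (the ground truth).
#' @export
simulate_counts <- function(codeword, total_reads, config = run_model_config(),
                            seed = NULL, abundance = NULL) {
  codeword <- as_bits(codeword, what = "codeword")
  if (total_reads <= 0) stop("total_reads must be > 0")
  if (sum(codeword) == 0)
    stop("all-zero codeword cannot generate reads")
  with_seed(seed, {
    n <- length(codeword)
    if (is.null(abundance))
      abundance <- draw_abundance(codeword, config$abundance_sigma)
    stopifnot(length(abundance) == n)
    p <- abundance * (codeword == 1L)
    counts <- as.numeric(rmultinom(1, total_reads, p / sum(p)))
    # uniform misassignment moves reads to random molbits
    moved <- rbinom(n, counts, config$misassign_rate)
    counts <- counts - moved
    dest <- tabulate(sample.int(n, sum(moved), replace = TRUE), nbins = n)
    counts <- counts + dest
    cv <- count_vector(counts, total_reads = total_reads)
    attr(cv, "abundance") <- abundance
    attr(cv, "codeword") <- codeword
    cv
  })
}

#' Simulate a timed sequencing run
#'
#' Draws a Poisson number of reads over `config$duration` minutes with
#' uniform order-statistic timestamps, assigns each read a true molbit
#' (proportional to abundance over the 1-bits), applies per-read uniform
#' misassignment, and optionally emits a simulated squiggle per read.
#'
#' @param codeword n-bit 0/1 vector.
#' @param config a [run_model_config()].
#' @param barcodes optional character vector of n barcode sequences
#'   (required with `emit_signals`).
#' @param model optional [pore_model()] (required with `emit_signals`).
#' @param seed optional seed.
#' @param abundance optional fixed abundance factors, as in
#'   [simulate_counts()].
#' @return An object of class `simulated_run`: `reads` data.frame
#'   (timestamp in minutes, true and observed 0-based molbit ids),
#'   optional `squiggles`, plus the ground-truth `codeword` and
#'   `abundance`.
#' @export
simulate_run <- function(codeword, config = run_model_config(),
                         barcodes = NULL, model = NULL, seed = NULL,
                         abundance = NULL) {
  codeword <- as_bits(codeword, what = "codeword")
  if (sum(codeword) == 0) stop("all-zero codeword cannot generate reads")
  with_seed(seed, {
    n <- length(codeword)
    n_reads <- rpois(1, config$reads_per_minute * config$duration)
    ts <- sort(runif(n_reads, 0, config$duration))
    if (is.null(abundance))
      abundance <- draw_abundance(codeword, config$abundance_sigma)
    p <- abundance * (codeword == 1L)
    true_id <- sample.int(n, n_reads, replace = TRUE, prob = p / sum(p)) - 1L
    observed <- true_id
    mis <- runif(n_reads) < config$misassign_rate
    observed[mis] <- sample.int(n, sum(mis), replace = TRUE) - 1L
    squiggles <- NULL
    if (config$emit_signals) {
      if (is.null(barcodes) || is.null(model))
        stop("emit_signals requires barcodes and a pore model")
      stopifnot(length(barcodes) == n)
      squiggles <- lapply(observed + 1L, function(i)
        simulate_squiggle(barcodes[i], model, mode = "noisy",
                          dwell_model = "geometric"))
    }
    structure(list(reads = data.frame(timestamp = ts,
                                      true_molbit = true_id,
                                      observed_molbit = observed),
                   squiggles = squiggles,
                   codeword = codeword,
                   abundance = abundance,
                   config = config),
              class = "simulated_run")
  })
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf("simulated run: %d reads over %.2f min (%d-bit tag, %d present)%s\n",
              nrow(x$reads), x$config$duration, length(x$codeword),
              sum(x$codeword),
              if (!is.null(x$squiggles)) ", with signals" else ""))
  invisible(x)
}

#' Aggregate a simulated run into a count vector
#'
#' @param run a [simulate_run()] result.
#' @param up_to only reads with timestamp <= `up_to` minutes.
#' @return A [count_vector()].
#' @export
run_counts <- function(run, up_to = Inf) {
  stopifnot(inherits(run, "simulated_run"))
  obs <- run$reads$observed_molbit[run$reads$timestamp <= up_to]
  cv <- count_vector(tabulate(obs + 1L, nbins = length(run$codeword)),
                     total_reads = length(obs))
  attr(cv, "codeword") <- run$codeword
  attr(cv, "abundance") <- run$abundance
  cv
}

#' Remap an observed tag onto a new codeword
#'
#' Simulates a different tag from the same observations: the old
#' 1-positions are randomly bijected onto the new codeword's
#' 1-positions (and old 0s onto new 0s), and counts are permuted
#' accordingly. The new codeword must have the same number of 1-bits.
#'
#' @param x a [count_vector()]/numeric counts or a `simulated_run`.
#' @param new_codeword target n-bit codeword with matching popcount.
#' @param old_codeword the source codeword (taken from `x` if present).
#' @param seed optional seed.
#' @return Remapped counts (a [count_vector()]) or a remapped
#'   `simulated_run` when `x` is a run.
#' @export
remap_tag <- function(x, new_codeword, old_codeword = NULL, seed = NULL) {
  new_codeword <- as_bits(new_codeword, what = "new codeword")
  if (inherits(x, "simulated_run")) {
    old <- x$codeword
  } else {
    old <- if (!is.null(old_codeword)) as_bits(old_codeword)
           else attr(x, "codeword")
    if (is.null(old)) stop("old_codeword required for plain counts")
  }
  if (sum(old) != sum(new_codeword))
    stop("popcount mismatch: old tag has ", sum(old), " 1-bits, new has ",
         sum(new_codeword))
  with_seed(seed, {
    n <- length(old)
    perm <- integer(n)
    perm[which(old == 1L)] <- sample(which(new_codeword == 1L))
    perm[which(old == 0L)] <- sample(which(new_codeword == 0L))
    if (inherits(x, "simulated_run")) {
      x$reads$true_molbit <- perm[x$reads$true_molbit + 1L] - 1L
      x$reads$observed_molbit <- perm[x$reads$observed_molbit + 1L] - 1L
      x$codeword <- new_codeword
      ab <- numeric(n)
      ab[perm] <- x$abundance
      x$abundance <- ab
      return(x)
    }
    cnt <- count_values(x)
    out <- numeric(n)
    out[perm] <- cnt
    cv <- count_vector(out, total_reads =
                         if (inherits(x, "count_vector")) x$total_reads
                         else sum(out))
    attr(cv, "codeword") <- new_codeword
    cv
  })
}

#' Decoding distance as a function of sequencing time
#'
#' For each requested time point, subsamples (without replacement) the
#' reads observed by that time, accumulates counts, and decodes the tag,
#' with `reps` repetitions per time point. Mirrors the timed-decoding
#' experiment: minimum decoding distance falls as reads accumulate until
#' the tag decodes correctly.
#'
#' @param run a [simulate_run()] result.
#' @param G a [generator_matrix()].
#' @param spec a [code_spec()]; defaults to the one in `G`.
#' @param times time points in minutes (default 8 points up to the run
#'   duration).
#' @param reps repetitions per time point (default 10).
#' @param true_message optional k-bit message to score correctness
#'   against (defaults to decoding the run's own codeword).
#' @param iters ISD iterations per decode.
#' @param seed optional seed.
#' @return data.frame with one row per (time, rep): reads used, decoding
#'   distance, status and correctness.
#' @export
decode_time_curve <- function(run, G, spec = NULL, times = NULL, reps = 10,
                              true_message = NULL, iters = 2000,
                              seed = NULL) {
  stopifnot(inherits(run, "simulated_run"))
  if (is.null(spec)) spec <- G$spec
  if (is.null(true_message)) {
    dec <- decode_nearest(run$codeword, G, spec)
    if (dec$status != "unique" || dec$distance != 0)
      stop("run codeword is not a codeword of G; supply true_message")
    true_message <- dec$message
  }
  if (is.null(times))
    times <- seq(run$config$duration / 8, run$config$duration, length.out = 8)
  obs <- run$reads$observed_molbit
  ts <- run$reads$timestamp
  n <- length(run$codeword)
  with_seed(seed, {
    out <- list()
    for (tm in times) {
      avail <- which(ts <= tm)
      n_take <- length(avail)
      for (r in seq_len(reps)) {
        take <- if (n_take < length(obs)) sample(seq_along(obs), n_take)
                else seq_along(obs)
        cnt <- tabulate(obs[take] + 1L, nbins = n)
        res <- decode_tag(cnt, G, spec, iters = iters)
        out[[length(out) + 1]] <- data.frame(
          time = tm, rep = r, reads = n_take,
          distance = res$distance,
          status = res$status,
          correct = res$status == "unique" &&
            identical(res$message, true_message))
      }
    }
    do.call(rbind, out)
  })
}
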