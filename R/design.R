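#' Barcode design configuration
#'
#' Constraints and optimizer settings for evolving mutually separable
#' molbit barcodes. Independent constraints apply to each sequence alone:
#' GC content within `[gc_min, gc_max]`, folding energy no more stable
#' than `mfe_floor`, absence of `forbidden_motifs` (by default the BsaI
#' recognition site GGTCTC and its reverse complement GAGACC, since the
#' enzyme acts on double-stranded DNA during Golden Gate assembly), and
#' homopolymer runs of at most `max_homopolymer_at` (A/T) and
#' `max_homopolymer_cg` (C/G). Dependent constraints relate a sequence to
#' the rest of the set: pairwise local Smith-Waterman score at most
#' `sw_max_score` and pairwise squiggle DTW distance at least
#' `dtw_floor`.
#'
#' @param n_barcodes number of barcodes (default 96).
#' @param barcode_length length in nt (default 40).
#' @param gc_min,gc_max allowed GC fraction (defaults 0.30, 0.70).
#' @param mfe_floor folding energy floor in kcal/mol (default -8).
#' @param forbidden_motifs character vector of excluded motifs.
#' @param max_homopolymer_at,max_homopolymer_cg homopolymer limits (nt).
#' @param sw_max_score maximum pairwise local SW score (default 15).
#' @param sw_match,sw_mismatch,sw_gap SW scoring (defaults +1/-1/-8).
#' @param dtw_floor minimum pairwise DTW distance; `NULL` (default) uses
#'   the initial set's global minimum, fixed at initialization.
#' @param max_tries mutation attempts per sequence per round (default 100).
#' @param max_rounds evolution round cap (default 50).
#' @param stall_rounds stop after this many consecutive rounds in which
#'   accepted mutations touch at most two distinct sequences (default 3).
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_barcodes = 96, barcode_length = 40,
                          gc_min = 0.30, gc_max = 0.70,
                          mfe_floor = -8,
                          forbidden_motifs = c("GGTCTC", "GAGACC"),
                          max_homopolymer_at = 5, max_homopolymer_cg = 4,
                          sw_max_score = 15,
                          sw_match = 1L, sw_mismatch = -1L, sw_gap = -8L,
                          dtw_floor = NULL,
                          max_tries = 100, max_rounds = 50,
                          stall_rounds = 3) {
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1))
    stop("need 0 <= gc_min < gc_max <= 1")
  if (max_tries < 1) stop("max_tries must be >= 1")
  if (sw_match <= 0) stop("sw_match must be positive")
  structure(list(n_barcodes = as.integer(n_barcodes),
                 barcode_length = as.integer(barcode_length),
                 gc_min = gc_min, gc_max = gc_max,
                 mfe_floor = mfe_floor,
                 forbidden_motifs = forbidden_motifs,
                 max_homopolymer_at = as.integer(max_homopolymer_at),
                 max_homopolymer_cg = as.integer(max_homopolymer_cg),
                 sw_max_score = as.integer(sw_max_score),
                 sw_match = as.integer(sw_match),
                 sw_mismatch = as.integer(sw_mismatch),
                 sw_gap = as.integer(sw_gap),
                 dtw_floor = dtw_floor,
                 max_tries = as.integer(max_tries),
                 max_rounds = as.integer(max_rounds),
                 stall_rounds = as.integer(stall_rounds)),
            class = "design_config")
}

max_run <- function(v, bases) {
  r <- rle(v %in% bases)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Check the single-sequence (independent) design constraints
#'
#' Evaluates GC bounds, folding energy, forbidden motifs and homopolymer
#' limits, reporting every failure rather than only the first.
#'
#' @param seq DNA string of length `config$barcode_length`.
#' @param config a [design_config()].
#' @return An object of class `constraint_report`: list with `passed`
#'   (logical) and `failures` (data.frame of constraint name and
#'   measured value).
#' @export
check_independent_constraints <- function(seq, config = design_config()) {
  check_dna(seq)
  if (nchar(seq) != config$barcode_length)
    stop("sequence length ", nchar(seq), " != barcode_length ",
         config$barcode_length)
  v <- seq_to_vec(seq)
  failures <- list()
  fail <- function(name, value)
    failures[[length(failures) + 1]] <<- data.frame(
      constraint = name, value = as.character(value),
      stringsAsFactors = FALSE)
  gc <- mean(v %in% c("G", "C"))
  if (gc < config$gc_min || gc > config$gc_max) fail("gc_content", gc)
  # homopolymer runs are per base, not per class: AATT has max run 2
  run_at <- max(max_run(v, "A"), max_run(v, "T"))
  if (run_at > config$max_homopolymer_at) fail("homopolymer_AT", run_at)
  run_cg <- max(max_run(v, "C"), max_run(v, "G"))
  if (run_cg > config$max_homopolymer_cg) fail("homopolymer_CG", run_cg)
  for (motif in config$forbidden_motifs)
    if (grepl(motif, seq, fixed = TRUE)) fail("forbidden_motif", motif)
  mfe <- fold_energy_proxy(seq)
  if (mfe < config$mfe_floor) fail("fold_energy", mfe)
  failures <- if (length(failures)) do.call(rbind, failures)
    else data.frame(constraint = character(), value = character(),
                    stringsAsFactors = FALSE)
  structure(list(passed = nrow(failures) == 0, failures = failures),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  if (x$passed) cat("all independent constraints passed\n")
  else {
    cat("constraint failures:\n")
    print(x$failures, row.names = FALSE)
  }
  invisible(x)
}

#' Mutate two adjacent nucleotides of a sequence
#'
#' Picks a uniformly random position p and replaces the bases at p and
#' p+1, each with a uniform draw from the three alternative bases, so the
#' output differs from the input at exactly those two adjacent positions.
#'
#' @param seq DNA string of length >= 2.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Mutated DNA string of the same length.
#' @export
mutate_sequence <- function(seq, seed = NULL) {
  check_dna(seq)
  v <- seq_to_vec(seq)
  if (length(v) < 2) stop("sequence must have length >= 2")
  with_seed(seed, {
    p <- sample.int(length(v) - 1L, 1L)
    for (pos in c(p, p + 1L))
      v[pos] <- sample(setdiff(DNA_BASES, v[pos]), 1L)
    vec_to_seq(v)
  })
}

random_constrained_sequence <- function(config, budget = 10000) {
  for (i in seq_len(budget)) {
    s <- vec_to_seq(sample(DNA_BASES, config$barcode_length, replace = TRUE))
    if (check_independent_constraints(s, config)$passed) return(s)
  }
  stop("could not draw a constraint-satisfying sequence in ", budget,
       " tries; consider relaxing the design constraints")
}

design_state <- function(sequences, model, config, dtw_floor,
                         round = 0L, history = NULL) {
  squiggles <- lapply(sequences, simulate_squiggle, model = model,
                      mode = "noiseless", dwell_model = "fixed")
  znorm <- lapply(squiggles, function(s) z_normalize(s$event_levels))
  n <- length(sequences)
  dtw_m <- matrix(0, n, n)
  sw_m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    sw_m[i, i] <- nchar(sequences[i])
    if (i < n) {
      js <- (i + 1):n
      d <- cpp_dtw_vs_set(znorm[[i]], znorm[js])
      dtw_m[i, js] <- d
      dtw_m[js, i] <- d
      s <- cpp_sw_vs_set(sequences[i], sequences[js],
                         config$sw_match, config$sw_mismatch, config$sw_gap)
      sw_m[i, js] <- s
      sw_m[js, i] <- s
    }
  }
  if (is.null(history))
    history <- data.frame(round = integer(), min_dtw = numeric(),
                          mean_dtw = numeric(), n_accepted = integer(),
                          accepted_ids = character(),
                          stringsAsFactors = FALSE)
  structure(list(sequences = sequences, squiggles = squiggles,
                 dtw_matrix = dtw_m, sw_matrix = sw_m,
                 round = round, history = history,
                 config = config, model = model,
                 dtw_floor = dtw_floor, .znorm = znorm),
            class = "molbit_design")
}

offdiag_min <- function(m) min(m[upper.tri(m)])
offdiag_mean <- function(m) mean(m[upper.tri(m)])

#' Initialize a barcode design state
#'
#' `random` draws each barcode by rejection sampling until it passes the
#' independent constraints and scores at most `sw_max_score` against
#' every barcode already accepted. `warm_start` draws `10 * n` such
#' candidates, simulates their squiggles, and greedily selects a
#' max-min-DTW subset (seeded with the most distant pair), which starts
#' the evolution from a better-separated set.
#'
#' @param config a [design_config()].
#' @param model a [pore_model()] used to simulate squiggles.
#' @param strategy `"random"` or `"warm_start"`.
#' @param seed optional seed.
#' @param candidate_factor warm-start candidate pool size as a multiple
#'   of `n_barcodes`.
#' @return An object of class `molbit_design` holding the sequences,
#'   their noiseless squiggles, and the pairwise DTW and SW matrices.
#'   The DTW floor for subsequent evolution is fixed here (the initial
#'   global minimum) unless `config$dtw_floor` is set.
#' @export
init_barcodes <- function(config = design_config(), model,
                          strategy = c("random", "warm_start"),
                          seed = NULL, candidate_factor = 10) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "pore_model"))
  with_seed(seed, {
    n <- config$n_barcodes
    if (strategy == "random") {
      seqs <- character(0)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(10000)) {
          s <- random_constrained_sequence(config)
          if (s %in% seqs) next
          if (length(seqs) == 0 ||
              all(cpp_sw_vs_set(s, seqs, config$sw_match, config$sw_mismatch,
                                config$sw_gap) <= config$sw_max_score)) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place barcode ", i, " under the SW constraint; ",
               "consider relaxing the design constraints")
        seqs <- c(seqs, s)
      }
    } else {
      pool <- unique(replicate(candidate_factor * n,
                               random_constrained_sequence(config)))
      levels <- lapply(pool, function(s) {
        z_normalize(simulate_squiggle(s, model, mode = "noiseless",
                                      dwell_model = "fixed")$event_levels)
      })
      np <- length(pool)
      d <- matrix(0, np, np)
      for (i in seq_len(np - 1)) {
        js <- (i + 1):np
        dd <- cpp_dtw_vs_set(levels[[i]], levels[js])
        d[i, js] <- dd
        d[js, i] <- dd
      }
      sw_ok <- function(cand, chosen)
        all(cpp_sw_vs_set(pool[cand], pool[chosen], config$sw_match,
                          config$sw_mismatch, config$sw_gap) <=
            config$sw_max_score)
      # seed with the most distant SW-compatible pair
      ord <- order(d, decreasing = TRUE)
      chosen <- NULL
      for (idx in ord) {
        i <- (idx - 1) %% np + 1
        j <- (idx - 1) %/% np + 1
        if (i < j && all(cpp_sw_vs_set(pool[i], pool[j], config$sw_match,
                                       config$sw_mismatch, config$sw_gap) <=
                         config$sw_max_score)) {
          chosen <- c(i, j)
          break
        }
      }
      if (is.null(chosen))
        stop("no SW-compatible pair in the warm-start pool; ",
             "consider relaxing the design constraints")
      while (length(chosen) < n) {
        rest <- setdiff(seq_len(np), chosen)
        mins <- vapply(rest, function(cand)
          min(d[cand, chosen]), numeric(1))
        placed <- FALSE
        for (cand in rest[order(mins, decreasing = TRUE)]) {
          if (sw_ok(cand, chosen)) {
            chosen <- c(chosen, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("warm-start pool exhausted under the SW constraint; ",
               "consider relaxing the design constraints")
      }
      seqs <- pool[chosen]
    }
    state <- design_state(seqs, model, config,
                          dtw_floor = config$dtw_floor)
    if (is.null(state$dtw_floor))
      state$dtw_floor <- offdiag_min(state$dtw_matrix)
    state
  })
}

#' Evolve barcodes toward maximal squiggle separability
#'
#' One evolution round visits every sequence in a freshly randomized
#' order and attempts up to `max_tries` two-adjacent-base mutations per
#' sequence. A mutation is accepted only if (a) the mutant passes the
#' independent constraints, (b) its local SW score against every other
#' barcode stays at most `sw_max_score`, (c) its DTW distance to every
#' other squiggle stays at least the DTW floor, and (d) both the minimum
#' and the mean DTW distance between the mutant and all other squiggles
#' strictly exceed their previous values. Evolution stops when accepted
#' mutations have touched at most two distinct sequences for
#' `stall_rounds` consecutive rounds (the optimization "bounces" between
#' a final pair), or after `max_rounds` rounds. The acceptance rule makes
#' the global minimum DTW non-decreasing across rounds.
#'
#' @param state a `molbit_design` from [init_barcodes()].
#' @param config a [design_config()]; defaults to the one in `state`.
#' @param seed optional seed.
#' @param verbose print per-round progress.
#' @return The evolved `molbit_design`, with one `history` row per round
#'   (global min/mean DTW, number and identity of accepted mutations).
#' @export
evolve_barcodes <- function(state, config = NULL, seed = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(state, "molbit_design"))
  if (is.null(config)) config <- state$config
  with_seed(seed, {
    n <- length(state$sequences)
    floor_dtw <- state$dtw_floor
    stall <- 0L
    rounds_done <- 0L
    while (rounds_done < config$max_rounds) {
      accepted <- integer(0)
      for (i in sample.int(n)) {
        old_row <- state$dtw_matrix[i, -i]
        old_min <- min(old_row)
        old_mean <- mean(old_row)
        for (try in seq_len(config$max_tries)) {
          cand <- mutate_sequence(state$sequences[i])
          if (cand %in% state$sequences[-i]) next
          if (!check_independent_constraints(cand, config)$passed) next
          sw <- cpp_sw_vs_set(cand, state$sequences[-i], config$sw_match,
                              config$sw_mismatch, config$sw_gap)
          if (any(sw > config$sw_max_score)) next
          lev <- simulate_squiggle(cand, state$model, mode = "noiseless",
                                   dwell_model = "fixed")$event_levels
          zn <- z_normalize(lev)
          d <- cpp_dtw_vs_set(zn, state$.znorm[-i])
          if (any(d < floor_dtw)) next
          if (!(min(d) > old_min && mean(d) > old_mean)) next
          # accept
          state$sequences[i] <- cand
          state$squiggles[[i]] <- squiggle(
            rep(lev, each = max(1L, round(state$model$samples_per_base))),
            event_levels = lev, seq_id = cand)
          state$.znorm[[i]] <- zn
          state$dtw_matrix[i, -i] <- d
          state$dtw_matrix[-i, i] <- d
          state$sw_matrix[i, -i] <- sw
          state$sw_matrix[-i, i] <- sw
          accepted <- c(accepted, i)
          break
        }
      }
      state$round <- state$round + 1L
      rounds_done <- rounds_done + 1L
      state$history <- rbind(state$history, data.frame(
        round = state$round,
        min_dtw = offdiag_min(state$dtw_matrix),
        mean_dtw = offdiag_mean(state$dtw_matrix),
        n_accepted = length(accepted),
        accepted_ids = paste(sort(unique(accepted)), collapse = ","),
        stringsAsFactors = FALSE))
      if (verbose)
        cat(sprintf("round %d: min DTW %.4f, mean %.4f, %d accepted\n",
                    state$round, offdiag_min(state$dtw_matrix),
                    offdiag_mean(state$dtw_matrix), length(accepted)))
      stall <- if (length(unique(accepted)) <= 2) stall + 1L else 0L
      if (stall >= config$stall_rounds) break
    }
    state
  })
}

#' @export
print.molbit_design <- function(x, ...) {
  cat(sprintf("molbit design: %d barcodes of %d nt, round %d\n",
              length(x$sequences), nchar(x$sequences[1]), x$round))
  cat(sprintf("  pairwise DTW: min %.4f, mean %.4f; max pairwise SW %d\n",
              offdiag_min(x$dtw_matrix), offdiag_mean(x$dtw_matrix),
              max(x$sw_matrix[upper.tri(x$sw_matrix)])))
  invisible(x)
}

#' @export
summary.molbit_design <- function(object, ...) {
  print(object)
  if (nrow(object$history) > 0) {
    cat("evolution history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.molbit_design <- function(x, ...) {
  if (nrow(x$history) == 0) {
    image(x$dtw_matrix, main = "pairwise squiggle DTW distances", ...)
    return(invisible(x))
  }
  h <- x$history
  plot(h$round, h$mean_dtw, type = "l", xlab = "evolution round",
       ylab = "DTW distance",
       ylim = range(c(h$min_dtw, h$mean_dtw)), ...)
  lines(h$round, h$min_dtw, lty = 2)
  legend("bottomright", legend = c("mean", "min"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Partition barcodes into high-separability training sets
#'
#' Splits the barcode set into `n_sets` equal groups such that barcodes
#' within a group are mutually distant: items are assigned greedily (most
#' isolated first) to the non-full set maximizing the item's minimum DTW
#' to the set's current members, so the most easily confused barcodes end
#' up in different sequencing runs.
#'
#' @param state a `molbit_design`.
#' @param n_sets number of groups; must divide the number of barcodes.
#' @return List of `n_sets` integer index vectors partitioning
#'   `seq_along(state$sequences)`.
#' @export
partition_sets <- function(state, n_sets) {
  stopifnot(inherits(state, "molbit_design"))
  n <- length(state$sequences)
  if (n %% n_sets != 0) stop("n_barcodes must be divisible by n_sets")
  cap <- n %/% n_sets
  d <- state$dtw_matrix
  diag(d) <- Inf
  sets <- rep(list(integer(0)), n_sets)
  # most crowded barcodes (smallest nearest-neighbor distance) placed first
  for (i in order(apply(d, 1, min))) {
    scores <- vapply(sets, function(s) {
      if (length(s) >= cap) return(-Inf)
      if (length(s) == 0) return(Inf)
      min(d[i, s])
    }, numeric(1))
    pick <- which.max(scores)
    sets[[pick]] <- c(sets[[pick]], i)
  }
  sets
}

#' Read and write barcode sets as FASTA
#'
#' Record ids are 0-based molbit indices (`molbit_0` ...).
#'
#' @param x a `molbit_design` or character vector of sequences.
#' @param path file path.
#' @return `read_barcodes_fasta`: named character vector of sequences.
#' @export
write_barcodes_fasta <- function(x, path) {
  seqs <- if (inherits(x, "molbit_design")) x$sequences else as.character(x)
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste0("molbit_", seq_along(seqs) - 1L)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @rdname write_barcodes_fasta
#' @export
read_barcodes_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dss), names(dss))
}

#' Write a per-round design report
#'
#' @param state a `molbit_design`.
#' @param path TSV output path.
#' @export
write_design_report <- function(state, path) {
  stopifnot(inherits(state, "molbit_design"))
  write.table(state$history, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
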