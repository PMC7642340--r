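# Shared fixtures, all built in code at test time.

# small synthetic pore model reused across tests
fix_model <- function() synthetic_pore_model(4, seed = 101)

# a small constraint-satisfying barcode set (cached per session)
fix_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- design_config(n_barcodes = 6, barcode_length = 40)
      cache <<- init_barcodes(cfg, fix_model(), "random", seed = 7)
    }
    cache
  }
})

# brute-force local Smith-Waterman oracle (full DP matrix, floor 0)
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -8) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  D <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) match else mismatch
    D[i + 1, j + 1] <- max(0, D[i, j] + s, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
    best <- max(best, D[i + 1, j + 1])
  }
  best
}

# brute-force DTW oracle with full cost matrix and path-length tracking
# (same predecessor tie-break as documented: diagonal, then (i-1,j),
# then (i,j-1))
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n, m)
  L <- matrix(0L, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    c <- abs(x[i] - y[j])
    if (i == 1 && j == 1) { D[i, j] <- c; L[i, j] <- 1L; next }
    cand_d <- c(if (i > 1 && j > 1) D[i - 1, j - 1] else Inf,
                if (i > 1) D[i - 1, j] else Inf,
                if (j > 1) D[i, j - 1] else Inf)
    cand_l <- c(if (i > 1 && j > 1) L[i - 1, j - 1] else 0L,
                if (i > 1) L[i - 1, j] else 0L,
                if (j > 1) L[i, j - 1] else 0L)
    k <- which.min(cand_d)
    D[i, j] <- cand_d[k] + c
    L[i, j] <- cand_l[k] + 1L
  }
  list(cost = D[n, m], path_length = L[n, m],
       normalized = D[n, m] / L[n, m])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# GF(2) encode oracle via plain matrix arithmetic
encode_oracle <- function(m, bits) as.integer((m %*% bits) %% 2)

hamming <- function(a, b) sum(a != b)

flip_bits <- function(cw, positions) {
  cw[positions] <- 1L - cw[positions]
  cw
}

# minimum bit errors over all presence thresholds against a known codeword
min_bit_errors <- function(counts, codeword) {
  u <- sort(unique(counts))
  th <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, max(counts) + 1)
  min(vapply(th, function(t) sum(as.integer(counts > t) != codeword),
             numeric(1)))
}
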