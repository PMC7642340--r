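# Watson-Crick nearest-neighbor stack free energies, DNA/DNA, 37C,
# kcal/mol (SantaLucia & Hicks 2004). Keyed by the top-strand
# dinucleotide 5'->3'; a stack and its reverse complement share a value.
NN_STACK <- c(AA = -1.00, TT = -1.00, AT = -0.88, TA = -0.58,
              CA = -1.45, TG = -1.45, GT = -1.44, AC = -1.44,
              CT = -1.28, AG = -1.28, GA = -1.30, TC = -1.30,
              CG = -2.17, GC = -2.24, GG = -1.84, CC = -1.84)

# hairpin loop initiation penalties (kcal/mol) by loop length; lengths
# beyond the table follow a Jacobson-Stockmayer extrapolation
HAIRPIN_LOOP <- c(`3` = 3.5, `4` = 3.5, `5` = 3.3, `6` = 4.0, `7` = 4.2,
                  `8` = 4.3, `9` = 4.5, `10` = 4.6)

hairpin_loop_penalty <- function(len) {
  if (len <= 10) return(unname(HAIRPIN_LOOP[as.character(len)]))
  4.6 + 1.75 * 0.616 * log(len / 10)
}

#' Estimate hairpin folding energy of a DNA sequence
#'
#' A bounded proxy for the minimum free energy of intramolecular
#' secondary structure, used as a barcode design constraint. It scans all
#' hairpins with a perfect Watson-Crick stem of at least `min_stem` base
#' pairs and a loop of at least 3 nt, scores each stem with
#' nearest-neighbor stack energies plus a loop-length penalty, and
#' returns the most stable (most negative) value, or 0 when the sequence
#' admits no such hairpin. It considers only perfect single hairpins (no
#' bulges, internal loops or multiloops), so it is an upper bound on the
#' stability a full thermodynamic folder would report; the `backend`
#' argument accepts any replacement function of the same signature.
#'
#' @param seq DNA string.
#' @param min_stem minimum stem length (bp), default 4.
#' @param backend `"stack_proxy"` (built-in) or a function `seq -> kcal/mol`.
#' @return Estimated folding energy in kcal/mol, always <= 0.
#' @export
#' @examples
#' fold_energy_proxy(strrep("A", 40))  # 0, no self-complementarity
fold_energy_proxy <- function(seq, min_stem = 4, backend = "stack_proxy") {
  if (is.function(backend)) return(backend(seq))
  check_dna(seq)
  v <- seq_to_vec(seq)
  n <- length(v)
  if (n < 2 * min_stem + 3) return(0)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  for (p in 1:(n - 2 * min_stem - 2)) {
    qmin <- p + 2 * min_stem + 2  # shortest hairpin: stem min_stem, loop 3
    if (qmin > n) break
    for (q in n:qmin) {
      if (comp[v[p]] != v[q]) next
      # extend the stem inward while bases pair and loop stays >= 3
      energy <- 0
      L <- 1
      while (TRUE) {
        loop_len <- (q - L) - (p + L) + 1
        if (L >= min_stem && loop_len >= 3) {
          e <- energy + hairpin_loop_penalty(loop_len)
          if (e < best) best <- e
        }
        if (loop_len - 2 < 3) break  # no room to extend
        if (comp[v[p + L]] != v[q - L]) break
        energy <- energy + unname(NN_STACK[paste0(v[p + L - 1], v[p + L])])
        L <- L + 1
      }
    }
  }
  min(best, 0)
}
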