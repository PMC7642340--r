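#' k-mer pore models
#'
#' A pore model maps every DNA k-mer to the expected ionic current level
#' (pA) and its standard deviation while that k-mer occupies the pore.
#' Together with an expected dwell (samples per base) it fully determines
#' the simulated squiggle of a sequence.
#'
#' @param k k-mer length (nt).
#' @param levels data.frame with columns `kmer`, `level_mean`, `level_stdv`.
#' @param samples_per_base expected dwell time in samples per nucleotide.
#' @param source_tag free-text provenance.
#' @return An object of class `pore_model`.
#' @export
pore_model <- function(k, levels, samples_per_base = 10, source_tag = "") {
  stopifnot(is.data.frame(levels))
  required <- c("kmer", "level_mean", "level_stdv")
  if (!all(required %in% names(levels)))
    stop("pore model table needs columns: ", paste(required, collapse = ", "))
  levels$kmer <- toupper(as.character(levels$kmer))
  if (anyDuplicated(levels$kmer))
    stop("duplicate k-mer in pore model table: ",
         levels$kmer[duplicated(levels$kmer)][1])
  expected <- all_kmers(k)
  missing <- setdiff(expected, levels$kmer)
  if (length(missing) > 0)
    stop("pore model table is incomplete; first missing k-mer: ", missing[1],
         " (", length(missing), " missing of ", length(expected), ")")
  extra <- setdiff(levels$kmer, expected)
  if (length(extra) > 0)
    stop("pore model table has unexpected entries, e.g. ", extra[1])
  if (any(!is.finite(levels$level_mean)) || any(!is.finite(levels$level_stdv)))
    stop("non-finite level in pore model table")
  if (any(levels$level_stdv <= 0))
    stop("all level_stdv must be > 0")
  if (samples_per_base <= 0) stop("samples_per_base must be > 0")
  lookup <- setNames(levels$level_mean, levels$kmer)
  noise <- setNames(levels$level_stdv, levels$kmer)
  structure(list(k = as.integer(k), levels = levels,
                 lookup = lookup, noise = noise,
                 samples_per_base = samples_per_base,
                 source_tag = source_tag),
            class = "pore_model")
}

#' Read a pore model from a TSV file
#'
#' Expects a tab-separated table with header columns `kmer`, `level_mean`
#' and `level_stdv`, one row per k-mer; the table must cover all 4^k
#' k-mers exactly once.
#'
#' @param path file path.
#' @param samples_per_base expected dwell (samples/nt); not stored in the
#'   TSV format, so supplied here.
#' @return A [pore_model()].
#' @export
read_pore_model <- function(path, samples_per_base = 10) {
  tab <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse pore model TSV '", path, "': ",
                             conditionMessage(e)))
  required <- c("kmer", "level_mean", "level_stdv")
  if (!all(required %in% names(tab)))
    stop("pore model TSV must have header columns: ",
         paste(required, collapse = ", "))
  bad <- which(!grepl("^[ACGTacgt]+$", tab$kmer))
  if (length(bad) > 0)
    stop("malformed k-mer in pore model TSV at data row ", bad[1],
         ": '", tab$kmer[bad[1]], "'")
  if (!is.numeric(tab$level_mean) || !is.numeric(tab$level_stdv)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$level_mean))) |
                 is.na(suppressWarnings(as.numeric(tab$level_stdv))))
    stop("non-numeric level in pore model TSV at data row ",
         if (length(bad)) bad[1] else "?")
  }
  k <- nchar(tab$kmer[1])
  pore_model(k, tab, samples_per_base = samples_per_base,
             source_tag = path)
}

#' Write a pore model to TSV
#'
#' @param model a [pore_model()].
#' @param path output file path.
#' @export
write_pore_model <- function(model, path) {
  stopifnot(inherits(model, "pore_model"))
  write.table(model$levels[, c("kmer", "level_mean", "level_stdv")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pore model
#'
#' Draws a deterministic random pore model for testing and simulation:
#' level means uniform in a plausible pA range (60-120 pA by default, the
#' working range of common nanopore chemistries) and level standard
#' deviations uniform in 1-3 pA.
#'
#' @param k k-mer length, 2-8 (realistic pores are 4-8; tiny k is allowed
#'   for fast tests).
#' @param seed integer seed; the same seed always yields the same model.
#' @param samples_per_base expected dwell (samples/nt).
#' @param level_range,stdv_range ranges for the drawn means and sds (pA).
#' @return A [pore_model()].
#' @export
#' @examples
#' m <- synthetic_pore_model(4, seed = 1)
#' nrow(m$levels)  # 256
synthetic_pore_model <- function(k, seed, samples_per_base = 10,
                                 level_range = c(60, 120),
                                 stdv_range = c(1, 3)) {
  if (!(k %in% 2:8)) stop("k must be in 2..8")
  kmers <- all_kmers(k)
  tab <- with_seed(seed, data.frame(
    kmer = kmers,
    level_mean = runif(length(kmers), level_range[1], level_range[2]),
    level_stdv = runif(length(kmers), stdv_range[1], stdv_range[2]),
    stringsAsFactors = FALSE))
  pore_model(k, tab, samples_per_base = samples_per_base,
             source_tag = sprintf("synthetic(k=%d, seed=%d)", k, seed))
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("pore model: %d-mers (%d levels), %.1f samples/base%s\n",
              x$k, nrow(x$levels), x$samples_per_base,
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}
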