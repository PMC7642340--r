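#' Per-molbit count vectors
#'
#' Container for the read counts accumulated for each molbit in one
#' sequencing run (the classified subset of reads).
#'
#' @param counts length-n nonnegative numeric vector.
#' @param run_id free-text run identifier.
#' @param total_reads total reads in the run (>= sum of counts).
#' @return An object of class `count_vector`.
#' @export
count_vector <- function(counts, run_id = "", total_reads = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) > total_reads + 1e-9)
    stop("sum(counts) exceeds total_reads")
  structure(list(counts = counts, run_id = run_id,
                 total_reads = total_reads),
            class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("count vector%s: %d molbits, %s classified reads (of %s total)\n",
              if (nzchar(x$run_id)) paste0(" '", x$run_id, "'") else "",
              length(x$counts), format(sum(x$counts)), format(x$total_reads)))
  invisible(x)
}

#' Read and write per-molbit count tables
#'
#' TSV with columns `molbit_id` (0-based) and `count`.
#'
#' @param path file path.
#' @param counts a [count_vector()] or numeric vector.
#' @param n number of molbits expected (rows may omit zero counts).
#' @return `read_counts_tsv`: a [count_vector()].
#' @export
read_counts_tsv <- function(path, n = 96) {
  tab <- read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("molbit_id", "count") %in% names(tab)))
    stop("counts TSV needs columns molbit_id, count")
  if (any(tab$molbit_id < 0 | tab$molbit_id >= n))
    stop("molbit_id out of range 0..", n - 1)
  cnt <- numeric(n)
  cnt[tab$molbit_id + 1] <- tab$count
  count_vector(cnt, run_id = path)
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  cnt <- count_values(counts)
  write.table(data.frame(molbit_id = seq_along(cnt) - 1L, count = cnt),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bits_to_hex <- function(bits) {
  pad <- (-length(bits)) %% 4
  b <- c(bits, rep(0L, pad))
  nib <- vapply(split(b, rep(seq_len(length(b) / 4), each = 4)),
                function(x) sum(x * c(8L, 4L, 2L, 1L)), numeric(1))
  paste(format.hexmode(as.integer(nib)), collapse = "")
}

hex_to_bits <- function(hex, n) {
  nib <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- unlist(lapply(nib, function(x) as.integer(bitwAnd(x, c(8L, 4L, 2L, 1L)) > 0)))
  bits[seq_len(n)]
}

#' Read and write generator matrices as JSON
#'
#' Rows are stored hex-packed (leftmost bit first) together with the
#' construction seed and verification metadata.
#'
#' @param G a [generator_matrix()].
#' @param path file path.
#' @return `read_generator_matrix`: a [generator_matrix()].
#' @export
write_generator_matrix <- function(G, path) {
  stopifnot(inherits(G, "generator_matrix"))
  obj <- list(n = G$spec$n, k = G$spec$k, t = G$spec$t,
              required_min_distance = G$spec$required_min_distance,
              seed = G$seed,
              verified_weight_floor = G$verified_weight_floor,
              search_iters = G$search_iters,
              rows = apply(G$bits, 1, bits_to_hex))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_matrix
#' @export
read_generator_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- code_spec(obj$n, obj$k, obj$t, obj$required_min_distance)
  bits <- t(vapply(obj$rows, hex_to_bits, integer(obj$n), n = obj$n))
  dimnames(bits) <- NULL
  if (cpp_gf2_rank(bits) < spec$k) stop("stored matrix is rank deficient")
  structure(list(bits = bits, seed = obj$seed,
                 verified_weight_floor = obj$verified_weight_floor,
                 search_iters = obj$search_iters, spec = spec),
            class = "generator_matrix")
}

#' The shipped verified [96,32] generator matrix
#'
#' A [make_generator_matrix()] result distributed with the package so
#' users never pay the construction/search cost: a random [96,32] matrix
#' for which a 100,000-iteration information-set search found no nonzero
#' codeword of weight below 19, guaranteeing unique correction of 9 bit
#' errors.
#'
#' @return A `generator_matrix`.
#' @export
molbit_generator_matrix <- function() {
  read_generator_matrix(system.file("extdata", "generator_matrix_96x32.json",
                                    package = "molbit", mustWork = TRUE))
}
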