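#' Read and write raw-signal containers
#'
#' A signal container is a directory holding `manifest.tsv` (columns
#' `read_id`, `file`, and optionally `label`) plus one little-endian
#' float32 array file per read. It is the on-disk interchange format for
#' raw or simulated reads between the simulator, the labeler and the
#' classifier.
#'
#' @param squiggles list of [squiggle()] objects or numeric vectors.
#' @param dir container directory (created if needed).
#' @param labels optional per-read labels.
#' @param read_ids optional read identifiers (defaults to `read_<i>`).
#' @return `write_signal_container` returns `dir`;
#'   `read_signal_container` returns a list with `squiggles` (named list)
#'   and `labels` (or NULL).
#' @export
write_signal_container <- function(squiggles, dir, labels = NULL,
                                   read_ids = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(squiggles)
  if (is.null(read_ids)) read_ids <- sprintf("read_%05d", seq_len(n))
  files <- paste0(read_ids, ".sig")
  for (i in seq_len(n)) {
    s <- squiggles[[i]]
    if (inherits(s, "squiggle")) s <- s$samples
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(as.numeric(s), con, size = 4, endian = "little")
    close(con)
  }
  manifest <- data.frame(read_id = read_ids, file = files,
                         stringsAsFactors = FALSE)
  if (!is.null(labels)) manifest$label <- as.character(labels)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_signal_container
#' @export
read_signal_container <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv in ", dir)
  manifest <- read.delim(mpath, sep = "\t", stringsAsFactors = FALSE)
  squiggles <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    samples <- readBin(con, numeric(), n = sz / 4, size = 4,
                       endian = "little")
    squiggle(samples, seq_id = manifest$read_id[i])
  })
  names(squiggles) <- manifest$read_id
  list(squiggles = squiggles,
       labels = if ("label" %in% names(manifest)) manifest$label else NULL)
}
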