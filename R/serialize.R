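# On-disk pyramid container for debugging: one CSV per stored band plus a
# JSON header. Bands are written as stored (i.e. on the reflect-extended
# domain for the symmetric boundary) so that read -> reconstruct is exact.

#' Write / read a wavelet pyramid as a directory of CSV bands
#'
#' @param pyr a \linkS4class{WaveletPyramid}.
#' @param dir directory to create/fill; files are \code{meta.json} and
#'   \code{A_j.csv}, \code{LH_j.csv}, \code{HL_j.csv}, \code{HH_j.csv}
#'   per level j.
#' @return the directory (write) or a \linkS4class{WaveletPyramid} (read).
#' @export
writePyramid <- function(pyr, dir) {
  stopifnot(is(pyr, "WaveletPyramid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(levels = pyr@levels, baseShape = pyr@baseShape,
         boundary = pyr@boundary, filterName = pyr@filterName,
         spacing = pyr@spacing),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  dump_band <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  for (j in seq_len(pyr@levels)) {
    dump_band(pyr@approx[[j]], paste0("A_", j))
    dump_band(pyr@detailLH[[j]], paste0("LH_", j))
    dump_band(pyr@detailHL[[j]], paste0("HL_", j))
    dump_band(pyr@detailHH[[j]], paste0("HH_", j))
  }
  invisible(dir)
}

#' @rdname writePyramid
#' @export
readPyramid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  load_band <- function(name)
    as.matrix(utils::read.csv(file.path(dir, paste0(name, ".csv")),
                              header = FALSE))
  J <- meta$levels
  strip <- function(m) { dimnames(m) <- NULL; m }
  new("WaveletPyramid", levels = as.integer(J),
      approx = lapply(seq_len(J), function(j) strip(load_band(paste0("A_", j)))),
      detailLH = lapply(seq_len(J), function(j) strip(load_band(paste0("LH_", j)))),
      detailHL = lapply(seq_len(J), function(j) strip(load_band(paste0("HL_", j)))),
      detailHH = lapply(seq_len(J), function(j) strip(load_band(paste0("HH_", j)))),
      baseShape = as.integer(meta$baseShape), boundary = meta$boundary,
      filterName = meta$filterName, spacing = as.numeric(meta$spacing))
}
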