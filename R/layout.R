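#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a planar (Utah-style) electrode array layout
#'
#' Builds a regular-grid electrode layout. The default reproduces the
#' standard 96-channel Utah array: a 10 x 10 grid at 400 um pitch with the
#' four corner sites unwired.
#'
#' @param nRows,nCols grid dimensions (default 10 x 10).
#' @param pitchUm inter-electrode pitch in micrometres (default 400).
#' @param unwired either the string \code{"corners"} (default; the four
#'   corner sites carry no electrode) or a logical nRows x nCols matrix,
#'   TRUE where a site is wired, or \code{"none"} for a fully wired grid.
#'
#' @return an [ArrayLayout-class].
#' @examples
#' lay <- utahArrayLayout()
#' nChannels(lay)  # 96
#' @export
utahArrayLayout <- function(nRows = 10L, nCols = 10L, pitchUm = 400,
                            unwired = "corners") {
  nRows <- as.integer(nRows)
  nCols <- as.integer(nCols)
  if (is.matrix(unwired)) {
    wired <- unwired
    if (!identical(dim(wired), c(nRows, nCols)))
      stop("wired matrix must be nRows x nCols")
  } else if (identical(unwired, "corners")) {
    wired <- matrix(TRUE, nRows, nCols)
    wired[c(1L, nRows), c(1L, nCols)] <- FALSE
  } else if (identical(unwired, "none")) {
    wired <- matrix(TRUE, nRows, nCols)
  } else stop("unwired must be 'corners', 'none', or a logical matrix")
  idx <- which(wired, arr.ind = TRUE)
  # row-major order: row index varies slowest
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  positions <- cbind(
    x = (idx[, 2L] - 1L) * pitchUm,
    y = (idx[, 1L] - 1L) * pitchUm
  )
  new("ArrayLayout",
    pitchUm = pitchUm, nRows = nRows, nCols = nCols, wired = wired,
    positions = positions,
    channelIds = sprintf("ch%03d", seq_len(nrow(positions))))
}

#' @rdname nChannels
#' @export
setMethod("nChannels", "ArrayLayout", function(x) nrow(x@positions))

#' @rdname channelIds
#' @export
setMethod("channelIds", "ArrayLayout", function(x) x@channelIds)

#' @rdname electrodePositions
#' @export
setMethod("electrodePositions", "ArrayLayout", function(x) x@positions)

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d x %d grid, %g um pitch, %d wired electrodes\n",
    object@nRows, object@nCols, object@pitchUm, nChannels(object)))
})

#' Pairwise electrode distances
#'
#' Euclidean distances between all wired electrodes, in micrometres.
#'
#' @param layout an [ArrayLayout-class].
#' @return symmetric numeric matrix (um) with zero diagonal, dimnames set to
#'   the channel ids.
#' @examples
#' d <- electrodeDistances(utahArrayLayout())
#' range(d[upper.tri(d)])
#' @export
electrodeDistances <- function(layout) {
  stopifnot(is(layout, "ArrayLayout"))
  d <- as.matrix(stats::dist(layout@positions))
  if (any(d[upper.tri(d)] <= 0))
    stop("duplicate electrode positions give zero pairwise distance")
  dimnames(d) <- list(layout@channelIds, layout@channelIds)
  d
}
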