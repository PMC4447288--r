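# Connected-component labeling on binary grids.
#
# EBImage::bwlabel gives fast 4-connected labels per 2D frame; full
# connectivity (8 in 2D, 26 in 3D) is obtained by merging labels that touch
# diagonally (and, in 3D, across adjacent axial slices) through a components
# pass over the small label-adjacency graph.

# collect label pairs (a, b) that co-occur when L is shifted by (dx, dy)
# within a slice, or between slice k and k+1 for the 3D merge
.shift_pairs2d <- function(L, dx, dy) {
  nr <- nrow(L); nc <- ncol(L)
  xs <- seq_len(nr - abs(dx)); ys <- seq_len(nc - abs(dy))
  a <- L[xs + max(dx, 0), ys + max(dy, 0), drop = FALSE]
  b <- L[xs - min(dx, 0), ys - min(dy, 0), drop = FALSE]
  keep <- a > 0 & b > 0 & a != b
  cbind(a[keep], b[keep])
}

.merge_labels <- function(L, pairs) {
  nlab <- max(L)
  if (nlab == 0L) return(L)
  if (length(pairs) == 0L) return(L)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # renumber components compactly in first-appearance order
  lut <- c(0L, as.integer(memb))
  out <- array(lut[L + 1L], dim = dim(L))
  u <- unique(out[out > 0L])
  relut <- integer(max(u) + 1L)
  relut[u + 1L] <- seq_along(u)
  array(relut[out + 1L], dim = dim(L))
}

#' Label connected components of a binary grid
#'
#' 2D matrices are labeled with 8-connectivity, 3D arrays with
#' 26-connectivity -- the robust defaults for noisy PET masks.
#'
#' @param mask logical (or 0/1 numeric) matrix or 3D array.
#' @return Integer array of the same shape; 0 for background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`mask` must be a matrix or a 3D array", call. = FALSE)
  m <- array(as.numeric(mask != 0), dim = d)
  L <- EBImage::bwlabel(m)
  L <- array(as.integer(round(L)), dim = d)
  if (length(d) == 2L) {
    pairs <- rbind(.shift_pairs2d(L, 1L, 1L), .shift_pairs2d(L, 1L, -1L))
    return(.merge_labels(L, pairs))
  }
  # bwlabel restarts labels at 1 in every frame: offset to make them unique
  fmax <- apply(L, 3L, max)
  offset <- cumsum(c(0L, fmax[-d[3]]))
  L <- L + rep(offset, each = d[1] * d[2]) * (L > 0L)
  pairs <- vector("list", 0L)
  for (k in seq_len(d[3])) {
    Lk <- L[, , k]
    pairs[[length(pairs) + 1L]] <- .shift_pairs2d(Lk, 1L, 1L)
    pairs[[length(pairs) + 1L]] <- .shift_pairs2d(Lk, 1L, -1L)
    if (k < d[3]) {
      Lk1 <- L[, , k + 1L]
      for (dx in -1L:1L) for (dy in -1L:1L) {
        nr <- d[1]; nc <- d[2]
        xs <- seq_len(nr - abs(dx)); ys <- seq_len(nc - abs(dy))
        a <- Lk[xs + max(dx, 0), ys + max(dy, 0), drop = FALSE]
        b <- Lk1[xs - min(dx, 0), ys - min(dy, 0), drop = FALSE]
        keep <- a > 0 & b > 0
        if (any(keep))
          pairs[[length(pairs) + 1L]] <- cbind(a[keep], b[keep])
      }
    }
  }
  .merge_labels(L, do.call(rbind, pairs))
}

#' Binary mask derived from an SUV volume
#'
#' @param data logical 3D array.
#' @param spacing voxel spacing in mm, inherited from the source volume.
#' @return Object of class `binary_mask` with elements `data` and `spacing`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  structure(list(data = array(as.logical(data), dim = dim(data)),
                 spacing = as.numeric(spacing)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binary mask: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}
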