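#' Anatomical region masks on the image grid
#'
#' Builds the named boolean masks used for regional averaging of parametric
#' maps. The default geometry mimics a coronal rodent/lagomorph brain slice:
#' a cortical band under the surface, an elliptical hippocampus beneath it,
#' a deeper elliptical thalamus, and a `whole_slice` mask covering the full
#' grid (and hence containing every named region). `background` collects the
#' whole-slice pixels that belong to none of the three structures. Optional
#' depth layers split the cortex band into equal-thickness strata.
#'
#' @param grid_shape Length-2 integer, (depth, lateral) pixel counts.
#' @param n_cortex_layers If > 0, also return `cortex_layer_1..n` masks
#'   splitting the cortical band by depth (layer 1 most superficial).
#' @return A named list of logical matrices of class `region_set`.
#' @examples
#' rs <- region_set(c(64, 64))
#' vapply(rs, sum, integer(1))
#' @export
region_set <- function(grid_shape = c(64L, 64L), n_cortex_layers = 0L) {
  nz <- as.integer(grid_shape[1])
  nx <- as.integer(grid_shape[2])
  if (nz < 8 || nx < 8) abort_param("`grid_shape` must be at least 8 x 8.")
  z <- matrix(seq_len(nz), nz, nx)
  x <- matrix(seq_len(nx), nz, nx, byrow = TRUE)

  cortex_depth <- max(2L, round(nz / 4))
  cortex <- z <= cortex_depth

  in_ellipse <- function(cz, cx, rz, rx) {
    ((z - cz) / rz)^2 + ((x - cx) / rx)^2 <= 1
  }
  hippocampus <- in_ellipse(cz = nz * 0.52, cx = nx * 0.50,
                            rz = nz * 0.11, rx = nx * 0.30) & !cortex
  thalamus <- in_ellipse(cz = nz * 0.80, cx = nx * 0.50,
                         rz = nz * 0.10, rx = nx * 0.26) & !cortex & !hippocampus

  whole_slice <- matrix(TRUE, nz, nx)
  background <- whole_slice & !cortex & !hippocampus & !thalamus

  out <- list(whole_slice = whole_slice, cortex = cortex,
              hippocampus = hippocampus, thalamus = thalamus,
              background = background)
  if (n_cortex_layers > 0L) {
    edges <- round(seq(0, cortex_depth, length.out = n_cortex_layers + 1))
    for (i in seq_len(n_cortex_layers)) {
      out[[paste0("cortex_layer_", i)]] <- z > edges[i] & z <= edges[i + 1]
    }
  }
  for (nm in names(out)) {
    if (!any(out[[nm]])) abort_param(sprintf("Region '%s' is empty.", nm))
  }
  structure(out, class = "region_set", grid_shape = c(nz, nx))
}

#' @export
print.region_set <- function(x, ...) {
  gs <- attr(x, "grid_shape")
  cat(sprintf("<region_set> %d x %d grid\n", gs[1], gs[2]))
  for (nm in names(x)) {
    cat(sprintf("  %-16s %5d px (%.1f%%)\n", nm, sum(x[[nm]]),
                100 * mean(x[[nm]])))
  }
  invisible(x)
}
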