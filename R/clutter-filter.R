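#' Casorati (space x time) matrix of an IQ block
#'
#' Rearranges a depth x lateral x frame IQ block into the 2-D matrix the
#' spatiotemporal SVD filter operates on: rows are pixels flattened in R's
#' column-major order (depth fastest), columns are frames. The reshape is
#' lossless; [from_casorati()] inverts it exactly.
#'
#' @param block An `iq_block`.
#' @return A complex matrix of class `casorati` with the block metadata
#'   attached, dimensions `(nz * nx) x frames`.
#' @export
to_casorati <- function(block) {
  stopifnot(inherits(block, "iq_block"))
  d <- dim(block$data)
  if (any(d == 0)) abort_param("Block is empty.")
  X <- matrix(block$data, d[1] * d[2], d[3])
  structure(X, class = c("casorati", class(X)),
            block_dim = d, block_meta = block[setdiff(names(block), "data")])
}

#' @rdname to_casorati
#' @param x A `casorati` matrix produced by [to_casorati()].
#' @export
from_casorati <- function(x) {
  stopifnot(inherits(x, "casorati"))
  d <- attr(x, "block_dim")
  out <- attr(x, "block_meta")
  out$data <- array(as.complex(x), d)
  out <- out[c("data", setdiff(names(out), "data"))]
  class(out) <- "iq_block"
  out
}

#' SVD clutter filter specification
#'
#' Controls which singular components of the Casorati matrix are discarded
#' as tissue clutter. In `"fixed"` mode the leading `cutoff` components are
#' removed; in `"energy"` mode the smallest leading set accounting for at
#' least a fraction `cutoff` of the total energy (sum of squared singular
#' values) is removed. An optional `noise_cutoff` additionally discards all
#' components of index above it (high-rank noise).
#'
#' @param mode `"fixed"` (remove a fixed count, the default) or `"energy"`.
#' @param cutoff Component count (`"fixed"`) or energy fraction in (0, 1)
#'   (`"energy"`).
#' @param noise_cutoff Optional upper component index to keep; `NULL`
#'   disables the high-rank cut.
#' @return An object of class `svd_filter_spec`.
#' @export
svd_filter_spec <- function(mode = c("fixed", "energy"), cutoff = 2,
                            noise_cutoff = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (cutoff < 0 || cutoff != round(cutoff)) {
      abort_param("`cutoff` must be a nonnegative integer in fixed mode.")
    }
  } else if (cutoff <= 0 || cutoff >= 1) {
    abort_param("`cutoff` must be in (0, 1) in energy mode.")
  }
  if (!is.null(noise_cutoff) && noise_cutoff <= 0) {
    abort_param("`noise_cutoff` must be positive or NULL.")
  }
  structure(list(mode = mode, cutoff = cutoff, noise_cutoff = noise_cutoff),
            class = "svd_filter_spec")
}

#' Spatiotemporal SVD clutter filtering of an IQ block
#'
#' Separates blood echoes from tissue clutter by singular value
#' decomposition of the block's Casorati matrix: tissue is strong, spatially
#' coherent and slowly varying, so it concentrates in the leading singular
#' components, which are removed. The decomposition is computed economically
#' on the thin (time) dimension via the eigen-decomposition of the frames x
#' frames Hermitian cross-product, which is exact and far cheaper than a
#' full SVD when pixels greatly outnumber frames.
#'
#' The filtered and removed blocks partition the input exactly
#' (`filtered + removed = original`), the full singular-value spectrum is
#' returned for diagnostics, and the output energy never exceeds the input
#' energy. Removing every component (cutoff at or beyond the matrix rank
#' dimension) yields an all-zero block with a warning.
#'
#' @param block An `iq_block` (at least 2 frames).
#' @param spec An [svd_filter_spec()].
#' @return A list of class `svd_filtered_block` with elements `block` (the
#'   clutter-filtered `iq_block`), `removed` (the discarded clutter
#'   component as an `iq_block`), `singular_values`, and `removed_components`
#'   (the component indices discarded).
#' @examples
#' cfg <- acquisition_config(grid_shape = c(16, 16), frames_per_block = 40)
#' fld <- scatterer_field(cfg, blood_density = 2, seed = 5)
#' blk <- simulate_iq_block(fld, cfg, seed = 6)
#' flt <- svd_filter(blk, svd_filter_spec(cutoff = 2))
#' head(flt$singular_values)
#' @export
svd_filter <- function(block, spec = svd_filter_spec()) {
  stopifnot(inherits(block, "iq_block"), inherits(spec, "svd_filter_spec"))
  X <- to_casorati(block)
  nt <- ncol(X)
  if (nt < 2) abort_param("SVD filtering needs at least 2 frames.")
  rank_dim <- min(dim(X))

  H <- crossprod(Conj(X), X)          # frames x frames, Hermitian
  eg <- eigen(H, symmetric = TRUE)
  sv <- sqrt(pmax(Re(eg$values), 0))

  n_low <- if (spec$mode == "fixed") {
    as.integer(spec$cutoff)
  } else {
    energy <- cumsum(sv^2) / sum(sv^2)
    which(energy >= spec$cutoff)[1]
  }
  if (n_low >= rank_dim) {
    warning("Cutoff removes every singular component; output is all zero.",
            call. = FALSE)
    removed_idx <- seq_len(rank_dim)
  } else {
    removed_idx <- seq_len(n_low)
    if (!is.null(spec$noise_cutoff) && spec$noise_cutoff < rank_dim) {
      removed_idx <- c(removed_idx,
                       seq(spec$noise_cutoff + 1, rank_dim))
    }
    removed_idx <- removed_idx[removed_idx >= 1]
  }

  if (length(removed_idx) > 0) {
    V <- eg$vectors[, removed_idx, drop = FALSE]
    X_rm <- (X %*% V) %*% Conj(t(V))
  } else {
    V <- NULL
    X_rm <- matrix(0 + 0i, nrow(X), nt)
  }
  X_f <- unclass(X) - X_rm

  wrap <- function(M) {
    from_casorati(structure(M,
                            block_dim = attr(X, "block_dim"),
                            block_meta = attr(X, "block_meta"),
                            class = c("casorati", "matrix", "array")))
  }

  structure(
    list(
      block = wrap(X_f),
      removed = wrap(X_rm),
      singular_values = sv,
      removed_components = sort(unique(removed_idx)),
      removed_basis = V,
      spec = spec
    ),
    class = "svd_filtered_block"
  )
}

#' @export
print.svd_filtered_block <- function(x, ...) {
  cat(sprintf(
    "<svd_filtered_block> removed components [%s] of %d; energy kept %.1f%%\n",
    paste(range(x$removed_components), collapse = "-"),
    length(x$singular_values),
    100 * (1 - sum(x$singular_values[x$removed_components]^2) /
             sum(x$singular_values^2))))
  invisible(x)
}
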