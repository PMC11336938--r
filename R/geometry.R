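#' Multi-electrode sensor geometry
#'
#' Enumerates the unordered electrode pairs of an n-electrode patch in a
#' fixed lexicographic order (0-based indices), so matrix rows are
#' reproducible, and assigns each pair the fraction of its current path
#' that crosses the liver region. Six electrodes yield the 15 pairs of a
#' 15 x 30 impedance matrix.
#'
#' Electrodes are laid out on a 2 x 3 grid (two rows of three), the
#' arrangement natural for a rectangular patch. Default liver weights
#' decline linearly with the rank of the inter-electrode distance:
#' closely spaced pairs sample shallow tissue dominated by the liver
#' region under the patch, widely spaced pairs pick up proportionally
#' more background. The exact values are shipped synthetic-world
#' constants, not measured quantities.
#'
#' @param n_electrodes Number of electrodes (default 6).
#' @param liver_weight Optional numeric vector, one value in `[0, 1]` per
#'   pair; default declines with distance rank from 0.7 to 0.3.
#' @return Object of class `sensor_geometry` with elements `n_electrodes`,
#'   `pairs` (two-column 0-based integer matrix, lexicographic) and
#'   `liver_weight`.
#' @export
sensor_geometry <- function(n_electrodes = 6L, liver_weight = NULL) {
  n_electrodes <- as.integer(n_electrodes)
  if (is.na(n_electrodes) || n_electrodes < 2L) {
    stop("need at least two electrodes", call. = FALSE)
  }
  pairs <- t(utils::combn(seq_len(n_electrodes) - 1L, 2L))
  colnames(pairs) <- c("e1", "e2")
  n_pairs <- nrow(pairs)

  if (is.null(liver_weight)) {
    # 2 x (n/2) grid layout; unit spacing
    ncol_grid <- ceiling(n_electrodes / 2)
    xy <- cbind(((seq_len(n_electrodes) - 1L) %% ncol_grid),
                ((seq_len(n_electrodes) - 1L) %/% ncol_grid))
    d <- sqrt(rowSums((xy[pairs[, 1L] + 1L, , drop = FALSE] -
                       xy[pairs[, 2L] + 1L, , drop = FALSE])^2))
    rk <- rank(d, ties.method = "first")
    liver_weight <- if (n_pairs == 1L) {
      0.7
    } else {
      0.7 - 0.4 * (rk - 1) / (n_pairs - 1)
    }
  }
  if (length(liver_weight) != n_pairs ||
      any(liver_weight < 0) || any(liver_weight > 1)) {
    stop("liver_weight must have one value in [0, 1] per pair",
         call. = FALSE)
  }
  structure(list(n_electrodes = n_electrodes,
                 pairs = pairs,
                 liver_weight = as.numeric(liver_weight)),
            class = "sensor_geometry")
}
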