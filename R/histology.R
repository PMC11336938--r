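# Synthetic stained-section pipeline: ground truth for the classifier is
# derived from lipid-droplet counts, mirroring the histology workflow
# (section imaging -> particle analysis -> size-binned counts -> group
# statistics -> label rule).

#' Specify a synthetic section image
#'
#' A section is a set of bright circular lipid droplets on a darker
#' background with additive Gaussian pixel noise — a stand-in for a
#' thresholded Oil-Red-O-stained section photograph.
#'
#' @param size Image side length in pixels (square canvas).
#' @param centers Two-column matrix of droplet centres (x, y) in pixels.
#' @param radii Droplet radii in pixels (> 0), one per centre.
#' @param bg,fg Background/foreground intensities in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @return Object of class `section_spec`.
#' @export
section_spec <- function(size = 256L, centers = NULL, radii = NULL,
                         bg = 0.15, fg = 0.85, noise_sd = 0.03) {
  size <- as.integer(size)
  if (is.null(centers)) centers <- matrix(numeric(0), 0L, 2L)
  centers <- as.matrix(centers)
  radii <- as.numeric(radii %||% numeric(0))
  if (nrow(centers) != length(radii)) {
    stop("one radius per centre required", call. = FALSE)
  }
  if (length(radii) && any(radii <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  if (nrow(centers)) {
    inside <- centers[, 1L] - radii >= 1 & centers[, 1L] + radii <= size &
      centers[, 2L] - radii >= 1 & centers[, 2L] + radii <= size
    if (!all(inside)) stop("droplet outside canvas", call. = FALSE)
  }
  structure(list(size = size, centers = centers, radii = radii,
                 bg = bg, fg = fg, noise_sd = noise_sd),
            class = "section_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a synthetic section image
#'
#' Rasterises the droplets of a [section_spec()] as filled disks (a pixel
#' is foreground when its centre lies within a droplet radius), adds
#' Gaussian noise, and clamps to `[0, 1]`. Reproducible from `seed`.
#'
#' @param spec A [section_spec()].
#' @param seed Integer noise seed.
#' @return Numeric matrix `size x size` in `[0, 1]`.
#' @export
render_section <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "section_spec"))
  n <- spec$size
  img <- matrix(spec$bg, n, n)
  if (nrow(spec$centers)) {
    xs <- matrix(seq_len(n), n, n)
    ys <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (i in seq_len(nrow(spec$centers))) {
      d2 <- (xs - spec$centers[i, 1L])^2 + (ys - spec$centers[i, 2L])^2
      img[d2 <= spec$radii[i]^2] <- spec$fg
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + with_local_seed(seed, {
      matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    })
  }
  pmin(pmax(img, 0), 1)
}

#' Segment lipid droplets from a section image
#'
#' Global automatic (Otsu) threshold on the intensity histogram, connected
#' component labelling, minimum-size filter, then per-object area and
#' equivalent diameter (`2 * sqrt(area / pi)`). Touching droplets merge
#' into one object; no watershed splitting is attempted.
#'
#' @param image Single-channel numeric matrix in `[0, 1]`.
#' @param min_size Minimum object area in pixels (objects below are
#'   discarded). Default 4.
#' @param threshold Optional fixed threshold; `NULL` (default) uses Otsu's
#'   method.
#' @param min_contrast Minimum difference between the mean intensity above
#'   and below the automatic threshold for any foreground to be accepted;
#'   prevents Otsu from splitting pure sensor noise on droplet-free
#'   sections. Stain contrast (~0.7) far exceeds sensor noise (~0.03), so
#'   the default 0.2 sits well between the two. Ignored when `threshold`
#'   is supplied explicitly.
#' @return Data frame of class `droplet_table`: one row per retained
#'   object with `area`, `equiv_diameter`, `cx`, `cy`.
#' @export
segment_droplets <- function(image, min_size = 4L, threshold = NULL,
                             min_contrast = 0.2) {
  if (!is.matrix(image)) stop("image must be a matrix", call. = FALSE)
  if (any(!is.finite(image))) stop("non-finite pixels", call. = FALSE)
  if (is.null(threshold)) {
    rng <- range(image)
    if (diff(rng) < 1e-8) {
      threshold <- rng[2L] + 1       # flat image: nothing is foreground
    } else {
      threshold <- EBImage::otsu(EBImage::Image(image), range = rng)
      hi <- image > threshold
      if (!any(hi) || all(hi) ||
          mean(image[hi]) - mean(image[!hi]) < min_contrast) {
        threshold <- rng[2L] + 1     # no real bimodality: noise only
      }
    }
  }
  mask <- EBImage::Image(image > threshold)
  lab <- EBImage::bwlabel(mask)
  n_obj <- max(lab)
  if (n_obj == 0) {
    out <- data.frame(area = numeric(0), equiv_diameter = numeric(0),
                      cx = numeric(0), cy = numeric(0))
    class(out) <- c("droplet_table", "data.frame")
    return(out)
  }
  labm <- EBImage::imageData(lab)
  area <- tabulate(labm[labm > 0], nbins = n_obj)
  cx <- vapply(seq_len(n_obj), function(i) mean(row(labm)[labm == i]), 0)
  cy <- vapply(seq_len(n_obj), function(i) mean(col(labm)[labm == i]), 0)
  keep <- area >= min_size
  out <- data.frame(area = area[keep],
                    equiv_diameter = 2 * sqrt(area[keep] / pi),
                    cx = cx[keep], cy = cy[keep])
  class(out) <- c("droplet_table", "data.frame")
  out
}

#' Size-binned droplet counts
#'
#' Counts droplets whose equivalent diameter falls in each half-open bin
#' `[b_i, b_{i+1})`. The standard report uses break points 2, 7, 13
#' (equivalent-diameter pixels): a small-droplet bin 2--7 and a larger
#' bin 7--13.
#'
#' @param table A `droplet_table` from [segment_droplets()].
#' @param bins Strictly increasing numeric break points (default
#'   `c(2, 7, 13)`).
#' @param group Optional group label stored with the histogram.
#' @return Object of class `size_histogram`: integer counts named by bin.
#' @export
size_distribution <- function(table, bins = c(2, 7, 13), group = NA) {
  if (length(bins) < 2L || any(diff(bins) <= 0)) {
    stop("bins must be strictly increasing with at least two breaks",
         call. = FALSE)
  }
  d <- table$equiv_diameter
  counts <- vapply(seq_len(length(bins) - 1L), function(i) {
    sum(d >= bins[i] & d < bins[i + 1L])
  }, 0L)
  names(counts) <- paste0("[", bins[-length(bins)], ",", bins[-1L], ")")
  structure(list(counts = counts, bins = bins, group = group),
            class = "size_histogram")
}

#' Per-bin ANOVA between two groups of droplet histograms
#'
#' For each size bin, compares the per-subject counts of group A against
#' group B by one-way analysis of variance. Optionally adds the two-way
#' (group x bin) decomposition on the long table. Degenerate bins where
#' both groups have zero variance and equal means are reported as F = 0,
#' p = 1 by convention.
#'
#' @param group_a,group_b Lists of `size_histogram` over identical bins
#'   (>= 2 subjects each).
#' @param two_way Also fit the group x bin two-way ANOVA (default FALSE).
#' @return Data frame with one row per bin: `bin`, `F`, `p`,
#'   `mean_a`, `mean_b`. With `two_way = TRUE`, the two-way table is
#'   attached as attribute `"two_way"`.
#' @export
compare_groups <- function(group_a, group_b, two_way = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  bins <- group_a[[1L]]$bins
  ok <- all(vapply(c(group_a, group_b),
                   function(h) identical(h$bins, bins), TRUE))
  if (!ok) stop("histograms must share the same bins", call. = FALSE)
  ca <- do.call(rbind, lapply(group_a, function(h) h$counts))
  cb <- do.call(rbind, lapply(group_b, function(h) h$counts))
  res <- lapply(seq_len(ncol(ca)), function(j) {
    y <- c(ca[, j], cb[, j])
    g <- factor(rep(c("a", "b"), c(nrow(ca), nrow(cb))))
    if (stats::var(y) < 1e-12) {
      c(F = 0, p = 1)
    } else {
      tab <- stats::anova(stats::lm(y ~ g))
      c(F = tab$`F value`[1L], p = tab$`Pr(>F)`[1L])
    }
  })
  out <- data.frame(bin = colnames(ca),
                    F = vapply(res, `[[`, 0, "F"),
                    p = vapply(res, `[[`, 0, "p"),
                    mean_a = colMeans(ca), mean_b = colMeans(cb),
                    row.names = NULL)
  if (two_way) {
    long <- data.frame(
      count = c(as.vector(ca), as.vector(cb)),
      group = factor(rep(c("a", "b"), c(length(ca), length(cb)))),
      bin = factor(c(rep(colnames(ca), each = nrow(ca)),
                     rep(colnames(cb), each = nrow(cb)))))
    attr(out, "two_way") <- stats::anova(stats::lm(count ~ group * bin,
                                                   data = long))
  }
  out
}

#' Label a subject from its droplet histogram
#'
#' Early fatty liver shows a surge of small lipid droplets; the rule
#' therefore calls a subject `nafld` when the count in the small-droplet
#' bins (equivalent diameter in `[small_range[1], small_range[2])`)
#' exceeds `threshold`. The default threshold of 40 sits between the
#' groups generated by [generate_sections()] under its defaults.
#'
#' @param histogram A `size_histogram` over the standard bins.
#' @param threshold Count threshold (default 40).
#' @param small_range Diameter range defining "small" (default
#'   `c(2, 7)`).
#' @return `"nafld"` or `"healthy"`.
#' @export
label_from_droplets <- function(histogram, threshold = 40,
                                small_range = c(2, 7)) {
  stopifnot(inherits(histogram, "size_histogram"))
  b <- histogram$bins
  lo <- match(small_range[1L], b)
  hi <- match(small_range[2L], b)
  if (is.na(lo) || is.na(hi) || hi <= lo) {
    stop("histogram lacks the requested small-droplet bins",
         call. = FALSE)
  }
  small <- sum(histogram$counts[lo:(hi - 1L)])
  if (small > threshold) "nafld" else "healthy"
}

#' Generate a two-group cohort of section specs
#'
#' Draws per-subject droplet populations emulating the histological
#' contrast between groups: fatty-liver subjects carry many more small
#' droplets (diameter 2--7 px) and moderately more large ones (7--13 px)
#' than healthy controls. Counts are Poisson around the group means;
#' droplet centres are uniform on the canvas (overlaps allowed and then
#' counted as one object, consistent with the segmenter).
#'
#' @param n_per_group Subjects per group (default 20).
#' @param seed Integer master seed.
#' @param size Canvas side, pixels.
#' @param mean_small,mean_large Named lists with `healthy`/`nafld` mean
#'   droplet counts per size class.
#' @return List with `healthy` and `nafld`, each a list of
#'   `section_spec`.
#' @export
generate_sections <- function(n_per_group = 20L, seed = 1L, size = 256L,
                              mean_small = list(healthy = 12, nafld = 90),
                              mean_large = list(healthy = 8, nafld = 25)) {
  draw <- function(label) {
    ns <- stats::rpois(1L, mean_small[[label]])
    nl <- stats::rpois(1L, mean_large[[label]])
    r <- c(stats::runif(ns, 1.2, 3.4),    # equivalent diameter ~ 2.4-6.8
           stats::runif(nl, 3.6, 6.4))    # equivalent diameter ~ 7.2-12.8
    n <- length(r)
    cx <- stats::runif(n, 1 + r, size - r)
    cy <- stats::runif(n, 1 + r, size - r)
    section_spec(size, cbind(cx, cy), r)
  }
  with_local_seed(seed, {
    list(healthy = lapply(seq_len(n_per_group),
                          function(i) draw("healthy")),
         nafld = lapply(seq_len(n_per_group), function(i) draw("nafld")))
  })
}
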