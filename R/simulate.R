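# Run code under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Per-subject generative parameters
#'
#' Bundles everything needed to simulate one subject's impedance matrix:
#' the class label, Cole dispersions for the liver and background current
#' paths, one Randles contact model per electrode, and the multiplicative
#' measurement-noise scale.
#'
#' @param label `"healthy"` or `"nafld"`.
#' @param liver,background [tissue_dispersion()] objects for the liver and
#'   the non-liver portion of the current path.
#' @param contacts List of [electrode_skin_model()], one per electrode.
#' @param noise_sigma Log-scale standard deviation of the per-cell
#'   multiplicative noise (>= 0, dimensionless).
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(label, liver, background, contacts,
                           noise_sigma = 0.03) {
  label <- match.arg(label, c("healthy", "nafld"))
  stopifnot(inherits(liver, "tissue_dispersion"),
            inherits(background, "tissue_dispersion"))
  if (!is.list(contacts) ||
      !all(vapply(contacts, inherits, TRUE, "electrode_skin_model"))) {
    stop("contacts must be a list of electrode_skin_model objects",
         call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  structure(list(label = label, liver = liver, background = background,
                 contacts = contacts, noise_sigma = noise_sigma),
            class = "subject_params")
}

#' Default cohort generator settings
#'
#' Class-conditional means of the synthetic world. The fatty-liver class
#' carries a raised zero-frequency liver plateau (lipid bilayers block
#' low-frequency current) while the high-frequency plateaus and the
#' background path are shared, so the class contrast concentrates at the
#' low-frequency end of the sweep, as it does in tissue. Between-subject
#' spread is log-normal around these means with the listed coefficients
#' of variation.
#'
#' @return Nested list of generator settings; override fields and pass to
#'   [generate_cohort()].
#' @export
default_generator_config <- function() {
  list(
    grid = list(f_min = 1e3, f_max = 1e5, n = 30L),
    geometry = list(n_electrodes = 6L),
    liver = list(
      healthy = list(R0 = 1400, Rinf = 350, fc = 25e3, alpha = 0.85),
      nafld   = list(R0 = 3200, Rinf = 450, fc = 18e3, alpha = 0.80)
    ),
    background = list(R0 = 900, Rinf = 300, fc = 30e3, alpha = 0.90),
    contact = list(R_d = 150, C_dl = 0.5e-6, R_e = 2e4),
    cv = list(dispersion = 0.06, contact = 0.05, alpha_jitter = 0.02),
    noise_sigma = 0.03
  )
}

#' Simulate one impedance-magnitude matrix
#'
#' Forward model for a single subject: for electrode pair p and frequency
#' f the measured impedance is the series sum of the two contact
#' impedances and a lumped tissue path that mixes the liver and
#' background dispersions by the pair's liver weight,
#' `Z = Z_c(e1) + Z_c(e2) + w_p Z_liver + (1 - w_p) Z_bg`,
#' and the recorded magnitude is `|Z|` times a log-normal noise factor
#' with median 1 and log-sd `noise_sigma`.
#'
#' @param subject A [subject_params()] whose `contacts` length matches the
#'   geometry.
#' @param geometry A [sensor_geometry()].
#' @param grid A [frequency_grid()].
#' @param rng_seed Integer seed for the noise draw; the same seed gives a
#'   bitwise-identical matrix.
#' @param subject_id Identifier stored with the matrix.
#' @return Object of class `impedance_matrix`: list with `magnitudes`
#'   (pairs x frequencies, ohm), `phase` (radians, retained internally),
#'   `label`, `subject_id`.
#' @export
simulate_matrix <- function(subject, geometry, grid, rng_seed = 1L,
                            subject_id = "s1") {
  stopifnot(inherits(subject, "subject_params"),
            inherits(geometry, "sensor_geometry"),
            inherits(grid, "frequency_grid"))
  if (length(subject$contacts) != geometry$n_electrodes) {
    stop("contacts length must equal the number of electrodes",
         call. = FALSE)
  }
  f <- as.numeric(grid)
  n_pairs <- nrow(geometry$pairs)
  n_f <- length(f)

  zc <- vapply(subject$contacts, electrode_skin_impedance, complex(n_f),
               f = f)                      # n_f x n_electrodes
  zl <- tissue_path_impedance(subject$liver, f)
  zb <- tissue_path_impedance(subject$background, f)

  z <- matrix(0i, n_pairs, n_f)
  for (p in seq_len(n_pairs)) {
    e1 <- geometry$pairs[p, 1L] + 1L
    e2 <- geometry$pairs[p, 2L] + 1L
    w <- geometry$liver_weight[p]
    z[p, ] <- zc[, e1] + zc[, e2] + w * zl + (1 - w) * zb
  }

  mag <- Mod(z)
  if (subject$noise_sigma > 0) {
    noise <- with_local_seed(rng_seed, {
      matrix(exp(stats::rnorm(n_pairs * n_f, 0, subject$noise_sigma)),
             n_pairs, n_f)
    })
    mag <- mag * noise
  }
  stopifnot(all(is.finite(mag)), all(mag > 0))
  structure(list(magnitudes = mag, phase = Arg(z),
                 label = subject$label, subject_id = subject_id),
            class = "impedance_matrix")
}

# Draw one subject's parameters around the class-conditional means.
# Multiplicative log-normal spread on resistances/capacitances/fc; small
# clamped jitter on alpha, which is bounded in (0, 1].
draw_subject <- function(label, cfg) {
  ln <- function(mean, cv) mean * exp(stats::rnorm(1L, 0, cv))
  lv <- cfg$liver[[label]]
  cvd <- cfg$cv$dispersion
  liver <- tissue_dispersion(
    R0 = ln(lv$R0, cvd), Rinf = ln(lv$Rinf, cvd), fc = ln(lv$fc, cvd),
    alpha = min(1, max(0.4, lv$alpha * exp(stats::rnorm(1L, 0, cfg$cv$alpha_jitter))))
  )
  bg <- cfg$background
  background <- tissue_dispersion(
    R0 = ln(bg$R0, cvd), Rinf = ln(bg$Rinf, cvd), fc = ln(bg$fc, cvd),
    alpha = min(1, max(0.4, bg$alpha * exp(stats::rnorm(1L, 0, cfg$cv$alpha_jitter))))
  )
  cvc <- cfg$cv$contact
  contacts <- lapply(seq_len(cfg$geometry$n_electrodes), function(i) {
    electrode_skin_model(R_d = ln(cfg$contact$R_d, cvc),
                         C_dl = ln(cfg$contact$C_dl, cvc),
                         R_e = ln(cfg$contact$R_e, cvc))
  })
  subject_params(label, liver, background, contacts,
                 noise_sigma = cfg$noise_sigma)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_healthy + n_nafld` subjects with label-conditional log-normal
#' parameter spread around the configured means, simulates each subject's
#' impedance matrix, and returns them with labels attached. The default
#' study-sized cohort is 40 subjects, 20 per class. Everything is a pure
#' function of `(config, seed)`.
#'
#' @param n_healthy,n_nafld Subject counts (>= 0).
#' @param config Generator settings, see [default_generator_config()].
#' @param seed Integer master seed.
#' @return Object of class `cohort_dataset`: list with `matrices` (list of
#'   `impedance_matrix`), `labels`, `subject_ids`, `seed`, `geometry`,
#'   `grid`.
#' @export
generate_cohort <- function(n_healthy = 20L, n_nafld = 20L,
                            config = default_generator_config(),
                            seed = 1L) {
  n_healthy <- as.integer(n_healthy); n_nafld <- as.integer(n_nafld)
  if (is.na(n_healthy) || is.na(n_nafld) || n_healthy < 0 || n_nafld < 0) {
    stop("subject counts must be non-negative integers", call. = FALSE)
  }
  geometry <- sensor_geometry(config$geometry$n_electrodes)
  grid <- frequency_grid(config$grid$f_min, config$grid$f_max,
                         config$grid$n)
  labels <- c(rep("healthy", n_healthy), rep("nafld", n_nafld))
  n <- length(labels)

  matrices <- with_local_seed(seed, {
    noise_seeds <- if (n > 0) sample.int(.Machine$integer.max, n) else integer(0)
    lapply(seq_len(n), function(i) {
      sp <- draw_subject(labels[i], config)
      simulate_matrix(sp, geometry, grid, rng_seed = noise_seeds[i],
                      subject_id = sprintf("s%02d_%s", i, labels[i]))
    })
  })
  structure(list(matrices = matrices,
                 labels = labels,
                 subject_ids = vapply(matrices, `[[`, "", "subject_id"),
                 seed = as.integer(seed),
                 geometry = geometry, grid = grid),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d subjects (%d healthy, %d nafld), seed %d\n",
              length(x$matrices), sum(x$labels == "healthy"),
              sum(x$labels == "nafld"), x$seed))
  if (length(x$matrices)) {
    d <- dim(x$matrices[[1L]]$magnitudes)
    cat(sprintf("matrices: %d x %d (pairs x frequencies)\n", d[1L], d[2L]))
  }
  invisible(x)
}

#' Stack a cohort into a numeric array
#'
#' @param cohort A `cohort_dataset`.
#' @return Array `subjects x pairs x frequencies`.
#' @export
cohort_array <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  n <- length(cohort$matrices)
  if (n == 0L) return(array(numeric(0), c(0L, 0L, 0L)))
  d <- dim(cohort$matrices[[1L]]$magnitudes)
  out <- array(NA_real_, c(n, d[1L], d[2L]))
  for (i in seq_len(n)) out[i, , ] <- cohort$matrices[[i]]$magnitudes
  out
}
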