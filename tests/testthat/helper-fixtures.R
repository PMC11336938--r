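# Small shared fixtures, built in code at test time.

tiny_net_config <- function(use_attention = TRUE, init_seed = 7L) {
  network_config(in_shape = c(5L, 6L), stem_channels = 4L, n_blocks = 2L,
                 reduction_ratio = 2L, spatial_kernel = 3L,
                 use_attention = use_attention, init_seed = init_seed)
}

# a cohort small enough for fast training but with the default physics
small_cohort <- function(seed = 1L, n = 4L) {
  generate_cohort(n, n, default_generator_config(), seed = seed)
}

# deterministic non-overlapping disk layout on a grid
grid_section <- function(n_disks, radius = 6, size = 256L, spacing = 40L) {
  per_row <- floor((size - spacing) / spacing)
  stopifnot(n_disks <= per_row^2)
  i <- seq_len(n_disks) - 1L
  centers <- cbind(spacing * (i %% per_row) + spacing,
                   spacing * (i %/% per_row) + spacing)
  section_spec(size, centers, rep(radius, n_disks))
}
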