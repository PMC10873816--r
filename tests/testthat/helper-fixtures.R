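# Fixtures built in code: tiny integer volumes, slice-stack folders, and
# small phantoms shared across test files.

make_int_volume <- function(dims = c(8, 8, 4), bits = 16L, seed = 1) {
  withr::with_seed(seed, {
    vals <- sample.int(2^bits, prod(dims), replace = TRUE) - 1L
  })
  volume_scan(array(as.numeric(vals), dims), voxel_size = 0.02, day = 7,
              scan_label = "fix", bit_depth = bits)
}

write_stack_dir <- function(scan, root, name) {
  dir <- file.path(root, name)
  write_volume_stack(scan, dir)
  dir
}

small_phantom <- function(n_timepoints = 2, seed = 1, noise_sigma = 0.02, ...) {
  generate_sequence(phantom_spec(seed = seed, noise_sigma = noise_sigma, ...),
                    n_timepoints)
}
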