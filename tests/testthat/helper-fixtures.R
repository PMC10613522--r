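# Shared fixtures, built once per test run.  Sizes are kept small so the
# whole suite stays fast; the phantom geometry scales with grid size.

tiny_net <- function(n_classes = 9) {
  unet_config(n_levels = 2, base_channels = 2, n_classes = n_classes)
}

# one 16^3 moving phantom used by several files
fixture_env <- new.env()

small_phantom <- function() {
  if (is.null(fixture_env$ph)) {
    fixture_env$ph <- generate_phantom(phantom_config(grid_size = 16,
                                                      seed = 11))
  }
  fixture_env$ph
}

# a quick deterministic label array
toy_labels <- function(dims = c(6, 6, 6), values = 0:2) {
  array(rep_len(values, prod(dims)), dims)
}
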