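# One small synthetic experiment shared across test files, rendered once
# per run into the session temp directory.
fixture_dir <- file.path(tempdir(), "morphopipe-fixture")
fixture_cfg <- experiment_config(
  n_plates = 2, n_treatments = 4, n_moa_classes = 2, sites_per_well = 1,
  image_shape = c(96, 96), crop_size = 32, cells_per_site_mean = 8,
  seed = 42)
unlink(fixture_dir, recursive = TRUE)
fixture_bundle <- generate_experiment(fixture_cfg, fixture_dir)
write_bundle(fixture_bundle, fixture_dir, overwrite = TRUE)
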