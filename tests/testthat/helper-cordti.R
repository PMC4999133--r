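# Shared fixtures: everything is generated in code, nothing on disk.

tiny_spec <- function(grid = c(24L, 24L, 2L), ...) {
  phantom_spec(grid = grid, ...)
}

# A quick single-subject noiseless study under a given protocol.
tiny_study <- function(protocol, spec = tiny_spec(), subject_id = "WT01",
                       group = "WT", timepoint = "week17", seed = 1L,
                       sigma = 0) {
  sub <- make_subject(spec, subject_id, group, timepoint, seed = seed)
  st <- simulate_study(sub, protocol, sigma = sigma, seed = seed)
  list(subject = sub, study = st, mask = sub$label_map > 0L)
}

# Per-voxel ground-truth metric vector over cord voxels, raster order.
truth_by_voxel <- function(subject, metric) {
  tr <- subject$truth
  lab_names <- names(which(cordti:::ROI_LABELS > 0))
  lut <- setNames(tr$value[tr$metric == metric][match(lab_names,
                    tr$roi[tr$metric == metric])], lab_names)
  labs <- subject$label_map[subject$label_map > 0L]
  unname(lut[match(labs, cordti:::ROI_LABELS[lab_names])])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
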