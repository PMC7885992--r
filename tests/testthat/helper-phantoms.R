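# Shared fixtures: small deterministic phantoms built in code.

# A clean (speckle-free) phantom with one known lesion, handy for exact
# geometric checks.
clean_phantom <- function(seed = 42L, n_frames = 12L, speckle = 0,
                          depth = 5L, thickness = 8L, half_width = 10L,
                          center = 20L) {
  spec <- phantom_spec(
    n_frames = n_frames, n_alines = 64L, n_radial = 64L,
    lesions = data.frame(start_frame = max(2L, min(4L, n_frames - 1L)),
                         end_frame = min(9L, n_frames),
                         center_aline = center,
                         half_width_alines = half_width,
                         depth_px = depth, thickness_px = thickness),
    guidewire_center_aline = 48L, guidewire_width_alines = 5L,
    speckle_scale = speckle, attenuation_per_px = 0.03, seed = seed)
  generate_pullback(spec)
}

# Speckled study-scale phantom.
noisy_phantom <- function(seed = 7L) {
  generate_pullback(phantom_study_spec(seed))
}

# Truth-based preprocessing context for one frame of a phantom.
truth_context <- function(truth, f, roi = 48L) {
  preproc_context(truth$lumen_index[f, ], truth$guidewire_alines,
                  roi, ncol(truth$masks[f, , ]))
}
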