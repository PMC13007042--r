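# Shared phantom recipes and a cached default phantom so the suite only
# generates it once.

# Training-corpus phantom: one nerve covering most of a 64 x 64 frame so an
# 8 x 48 x 48 patch always contains class contrast, fascicles >= 4 voxels in
# radius, no scheduled events.
train_phantom_spec <- function(seed, ...) {
  phantom_spec(shape = c(24L, 64L, 64L), n_fascicles_initial = 4L,
               fascicle_radius_range_um = c(45, 85),
               nerve_ellipse_semiaxes_um = c(300, 300),
               epineurium_margin_um = 25,
               n_splits = 0L, n_merges = 0L, seed = seed, ...)
}

# Event phantom at the full default frame, radii small enough to pack the
# extra tracks that splits introduce.
event_phantom_spec <- function(seed, n_splits, n_merges) {
  phantom_spec(n_splits = n_splits, n_merges = n_merges,
               n_fascicles_initial = max(8L, n_splits + 2L * n_merges + 1L),
               fascicle_radius_range_um = c(28, 70), seed = seed)
}

tiny_arch <- function() {
  arch_config(3L, c(8L, 16L, 32L), list(c(1, 1, 1), c(2, 2, 2), c(2, 2, 2)))
}

tiny_patch <- c(8L, 48L, 48L)

# Cache across test files within one run.
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]])) .phantom_cache[[key]] <- generate_phantom(spec)
  .phantom_cache[[key]]
}

default_phantom <- function() cached_phantom("default", phantom_spec(seed = 5L))
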