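# Shared small phantoms, generated once per test run.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, spec) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(spec)
  .phantom_cache[[key]]
}

# default desk phantom at reduced grid for unit tests
small_phantom <- function() {
  cached_phantom("small48", phantom_spec(dims = c(48, 48, 48), seed = 1))
}

# noise- and artifact-free variant
clean_phantom <- function() {
  cached_phantom("clean48",
                 phantom_spec(dims = c(48, 48, 48), ciss_sigma = 0,
                              tof_sigma = 0, flow_void = list(),
                              pulsation = NULL, seed = 1))
}

# erode a logical mask by one 26-connected step (interior voxels only)
erode1 <- function(mask) {
  out <- mask
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & nvcfuse:::shift3(mask, dx, dy, dz, FALSE)
  }
  out
}

dilate26 <- function(mask) nvcfuse:::dilate1(mask, 26)

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
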