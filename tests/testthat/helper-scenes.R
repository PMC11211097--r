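# Shared fixtures: small, fast synthetic scenes and the series configuration
# a user would fix on a reference image of the generator's default world
# (DAPI threshold halfway between background and the 180 nuclear level;
# background threshold between the 5 background and 30 cytosol levels).

default_thresholds <- function() threshold_config(90, 15)

small_scene_params <- function(seed = NULL, ...) {
  args <- utils::modifyList(
    list(width = 128L, height = 128L, n_nuclei = 3L, seed = seed),
    list(...))
  do.call(scene_params, args)
}

# a tiny deterministic compartment layout used by several worked examples:
# 3x3 image, center pixel is the (only) nucleus, corners bright cytosol,
# edge midpoints dim background
tiny_map <- function() {
  green <- matrix(10, 3, 3)
  green[2, 2] <- 100
  green[c(1, 3), c(1, 3)] <- 50
  labels <- matrix(0L, 3, 3)
  labels[2, 2] <- 1L
  map <- classify_compartments(green, labels, threshold_config(0, 30,
                                                               min_nucleus_area = 0))
  list(green = green, map = map)
}
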