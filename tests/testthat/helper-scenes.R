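# Shared scene fixtures, built in code. `noiseless` switches off every
# detection noise source while keeping injected spurious detections.

smallSceneConfig <- function(seed = 7, noiseless = TRUE, ...) {
  args <- list(
    area_width = 80, area_height = 80,
    street_axes = list(cbind(c(0, 80), c(40, 40))),
    park_tree_density = 10,
    building_rects = list(c(10, 60, 25, 75)),
    n_clutter = 3,
    n_truth_samples = 400,
    seed = seed)
  if (noiseless)
    args <- c(args, list(bearing_noise_sd = 0, distance_noise_sd = 0,
                         detection_miss_rate = 0, false_detection_rate = 0,
                         point_noise_sd = 0))
  do.call(sceneConfig, utils::modifyList(args, list(...)))
}

# one tree of known height/crown at (5, 9): a single stub axis with spacing
# longer than the axis yields exactly the s = 0 tree
oneTreeConfig <- function(height = 10, crown = 2, seed = 3, ...) {
  sceneConfig(area_width = 20, area_height = 20,
              street_axes = list(cbind(c(5, 15), c(5, 5))),
              street_tree_spacing = 20, street_tree_offset = 4,
              park_tree_density = 0, building_rects = list(),
              n_clutter = 0, height_range = c(height, height),
              crown_radius_range = c(crown, crown),
              bearing_noise_sd = 0, distance_noise_sd = 0,
              detection_miss_rate = 0, false_detection_rate = 0,
              point_noise_sd = 0.1, n_truth_samples = 100, seed = seed, ...)
}

# separable two-class feature set: `sep` controls the class mean gap in sd
# units on the informative feature; the rest is noise
separableTrainingSet <- function(n = 200, sep = 15, p_noise = 5, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    cls <- factor(rep(c("NOT_TREE", "TREE"), each = n / 2),
                  levels = c("NOT_TREE", "TREE"))
    x <- data.frame(f_sep = rnorm(n, ifelse(cls == "TREE", sep, 0), 1))
    for (k in seq_len(p_noise)) x[[paste0("f_noise", k)]] <- rnorm(n)
    x$class <- cls
    x
  })
}
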