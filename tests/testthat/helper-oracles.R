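# Independent brute-force oracles used to validate the vectorized /
# compiled implementations. These deliberately use naive double loops and
# direct point-in-region tests, and share no code with the package paths
# they check.

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracle_iou <- function(cc) if (cc$TP + cc$FP + cc$FN == 0) 1 else cc$TP / (cc$TP + cc$FP + cc$FN)
oracle_dice <- function(cc) if (2 * cc$TP + cc$FP + cc$FN == 0) 1 else 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)

# count voxels above threshold in one slice by explicit double loop
oracle_count_above <- function(slice, threshold, inclusive = FALSE) {
  n <- 0L
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      v <- slice[i, j]
      if ((inclusive && v >= threshold) || (!inclusive && v > threshold))
        n <- n + 1L
    }
  }
  n
}

# brute-force point-in-region rasterization of a phantom's calcified arcs:
# voxel centre (i, j) is calcified on slice s iff it lies in the annular
# sector of some arc covering s
oracle_calcium_voxels <- function(spec) {
  total <- 0L
  for (s in seq_len(spec$n_slices)) {
    ci <- spec$vessel_path[s, 1]; cj <- spec$vessel_path[s, 2]
    r <- spec$vessel_radius_profile[s]
    for (i in seq_len(spec$image_size)) {
      for (j in seq_len(spec$image_size)) {
        d <- sqrt((i - ci)^2 + (j - cj)^2)
        hit <- FALSE
        for (ca in spec$calcifications) {
          if (s < ca$slice_range[1] || s > ca$slice_range[2]) next
          if (d > r || d <= r - ca$radial_thickness) next
          th <- atan2(i - ci, j - cj)
          width <- (ca$angular_arc[2] - ca$angular_arc[1]) %% (2 * pi)
          rel <- (th - ca$angular_arc[1]) %% (2 * pi)
          if (rel <= width) { hit <- TRUE; break }
        }
        if (hit) total <- total + 1L
      }
    }
  }
  total
}

random_mask_pair <- function(n = 16L, p_pred = 0.3, p_truth = 0.3) {
  list(pred = matrix(rbinom(n * n, 1L, p_pred), n, n),
       truth = matrix(rbinom(n * n, 1L, p_truth), n, n))
}

# small noise-free phantom with one calcified arc, used across test files
small_test_spec <- function(seed = 1L, image_size = 32L, n_slices = 6L,
                            noise_sigma = 0) {
  random_phantom_spec(seed = seed, image_size = image_size,
                      n_slices = n_slices, noise_sigma = noise_sigma)
}
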