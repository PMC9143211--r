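# Shared fixture builders. Everything is generated in code; no stored data.

unit_frame <- function(n = c(20, 20, 20), spacing = 1, origin = c(0, 0, 0)) {
  image_frame(origin, rep(spacing, 3), n)
}

# axis-aligned box mask in mm bounds
box_mask <- function(frame, lo, hi) {
  xyz <- voxel_centers(frame)
  inside <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
    xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
    xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
  binary_volume(frame, array(inside, dim = frame$shape))
}

sphere_mask <- function(frame, center, radius) {
  xyz <- voxel_centers(frame)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  binary_volume(frame, array(d2 <= radius^2, dim = frame$shape))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# horseshoe with two distinct bumps: a mirror-free shape for registration
# fixtures (the bare horseshoe is mirror-symmetric, which makes recovering a
# unique transform ill-posed)
asym_horseshoe_mesh <- function(spacing = 1) {
  ph <- make_phantom("horseshoe", spacing = spacing)
  xyz <- voxel_centers(ph$frame)
  bump <- function(center, r)
    (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
      (xyz[, 3] - center[3])^2 <= r^2
  mask <- (ph$hu > 0) | array(bump(c(26, 10, 2), 5) | bump(c(-24, 6, -3), 3),
                              dim = ph$frame$shape)
  mesh_from_mask(binary_volume(ph$frame, mask))
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of rank
# assignments (independent oracle for small group sizes)
mww_exact_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  obs <- sum(rank(c(a, b))[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  r <- rank(c(a, b))
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  # two-sided: double the smaller tail of the permutation distribution of U
  lo <- mean(us <= obs)
  hi <- mean(us >= obs)
  min(1, 2 * min(lo, hi))
}
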