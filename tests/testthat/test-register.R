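# Registration fixtures share one mirror-free phantom mesh, built once per
# file (see helper-phantoms.R).
mesh_reg <- asym_horseshoe_mesh()
tf_known <- rigid_transform(rot_z(15), c(5, -3, 2))

test_that("registering a mesh to itself is the identity", {
  reg <- register_rigid(mesh_reg, mesh_reg)
  expect_lt(reg$rms_mm, 1e-6)
  expect_lt(rotation_angle_deg(reg$transform), 1e-4)
  expect_lt(sqrt(sum(reg$transform$translation^2)), 1e-4)
  expect_false(reg$warning_flag)
})

test_that("a known 15-degree + (5,-3,2) mm transform is recovered", {
  moved <- surface_mesh(apply_transform(tf_known, mesh_reg$vertices),
                        mesh_reg$faces)
  reg <- register_rigid(moved, mesh_reg)
  resid <- compose_transforms(reg$transform, tf_known)
  expect_lt(rotation_angle_deg(resid), 0.5)
  expect_lt(sqrt(sum(apply_transform(resid, c(0, 0, 0))^2)), 0.1)
  # RMS decreases monotonically over point-to-point ICP iterations
  expect_true(all(diff(reg$rms_history[1:5]) <= 1e-9))
})

test_that("a 60% partial copy registers back onto the full model", {
  keep <- mesh_reg$vertices[, 1] < quantile(mesh_reg$vertices[, 1], 0.6)
  part <- surface_mesh(apply_transform(tf_known, mesh_reg$vertices[keep, ]),
                       matrix(1:3, 1))
  reg <- register_rigid(part, mesh_reg)
  expect_lt(reg$rms_mm, 0.5)
})

test_that("two segments register independently to the fixed model", {
  keepL <- mesh_reg$vertices[, 1] < median(mesh_reg$vertices[, 1])
  tfB <- rigid_transform(rot_z(-10), c(-4, 2, 1))
  segs <- list(
    surface_mesh(apply_transform(tf_known, mesh_reg$vertices[keepL, ]),
                 matrix(1:3, 1)),
    surface_mesh(apply_transform(tfB, mesh_reg$vertices[!keepL, ]),
                 matrix(1:3, 1)))
  regs <- register_two_segment(segs, mesh_reg)
  expect_lt(regs[[1]]$rms_mm, 0.5)
  expect_lt(regs[[2]]$rms_mm, 0.5)
  resid1 <- compose_transforms(regs[[1]]$transform, tf_known)
  resid2 <- compose_transforms(regs[[2]]$transform, tfB)
  expect_lt(rotation_angle_deg(resid1), 0.5)
  expect_lt(rotation_angle_deg(resid2), 0.5)
  # identical untransformed halves give identity transforms
  segs0 <- list(surface_mesh(mesh_reg$vertices[keepL, ], matrix(1:3, 1)),
                surface_mesh(mesh_reg$vertices[!keepL, ], matrix(1:3, 1)))
  regs0 <- register_two_segment(segs0, mesh_reg)
  for (r in regs0) expect_lt(rotation_angle_deg(r$transform), 0.1)
})

test_that("a segment with almost no true overlap raises the warning flag", {
  # a large flat plate has no counterpart on the bone surface
  gx <- as.matrix(expand.grid(x = seq(-120, 120, by = 4),
                              y = seq(-120, 120, by = 4)))
  plate <- surface_mesh(cbind(gx, 60), matrix(1:3, 1))
  reg <- register_rigid(plate, mesh_reg, init = rigid_transform(),
                        max_iter = 3)
  expect_true(reg$warning_flag)
})
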