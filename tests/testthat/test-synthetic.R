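test_that("phantom pairs are deterministic and label disjoint regions", {
  sp <- phantom_spec(noise_sd = 0.1, artifact_fraction = 0.1, seed = 77)
  a <- generate_phantom_pair(sp)
  b <- generate_phantom_pair(sp)
  expect_identical(a$t0$vertices, b$t0$vertices)
  expect_identical(a$t1$vertices, b$t1$vertices)
  expect_length(intersect(a$truth$roi1$vertex_indices,
                          a$truth$roi2$vertex_indices), 0)
  expect_identical(a$t0$faces, a$t1$faces)      # shared topology
  # null phantom: postop identical to plan
  null <- generate_phantom_pair(phantom_spec())
  expect_identical(null$t0$vertices, null$t1$vertices)
  expect_error(phantom_spec(cranial_semi_axes = c(0, 1, 1)), "degenerate")
  expect_error(phantom_spec(artifact_fraction = 0.5), "artifact_fraction")
})

test_that("phantom noise and artifacts land where specified", {
  sp0 <- phantom_spec(seed = 3)
  spn <- phantom_spec(noise_sd = 0.2, seed = 3)
  clean <- generate_phantom_pair(sp0)
  noisy <- generate_phantom_pair(spn)
  delta <- noisy$t1$vertices - clean$t1$vertices
  expect_equal(sd(as.vector(delta)), 0.2, tolerance = 0.02)

  spa <- phantom_spec(artifact_fraction = 0.1, seed = 3)
  art <- generate_phantom_pair(spa)
  moved <- which(rowSums(abs(art$t1$vertices - clean$t1$vertices)) > 0)
  expect_true(all(moved %in% art$truth$roi2$vertex_indices))
  shift <- sqrt(rowSums((art$t1$vertices[moved, ] -
                           clean$t1$vertices[moved, ])^2))
  expect_true(all(shift >= 2 & shift <= 5))
  expect_equal(length(moved),
               round(0.1 * length(art$truth$roi2$vertex_indices)))
})

test_that("translated-maxilla deviation is bounded by the translation", {
  t <- 1
  p <- generate_phantom_pair(
    phantom_spec(residual_transform = rigid_transform(diag(3), c(t, 0, 0))))
  ref2 <- extract_submesh(p$t0, p$truth$roi2)
  samples <- p$t1$vertices[p$truth$roi2$vertex_indices, ]
  dev <- surface_deviation(samples, ref2)
  expect_lte(max(dev$distances), t + 1e-12)
  expect_gt(dev$summary$rms, 0)
})

test_that("pipeline RMS grows monotonically with the residual magnitude", {
  rms <- vapply(c(0, 0.5, 1, 2), function(t) {
    p <- generate_phantom_pair(
      phantom_spec(residual_transform = rigid_transform(diag(3),
                                                        c(0, 0, -t)),
                   seed = 13))
    run_case(case_config(p$t0, p$t1, p$truth$roi1, p$truth$roi2,
                         case_id = paste0("t", t)))$case$rms_3d_error
  }, 0)
  expect_true(all(diff(rms) > 0))
  expect_lt(rms[1], 1e-6)
})

test_that("maxilla-only artifacts leave the reference registration intact", {
  pose <- rigid_transform(rotation_about_axis(c(1, 2, -1), 20), c(8, -6, 10))
  run_one <- function(af) {
    p <- generate_phantom_pair(phantom_spec(global_pose = pose,
                                            noise_sd = 0.05,
                                            artifact_fraction = af,
                                            seed = 19))
    out <- run_case(case_config(p$t0, p$t1, p$truth$roi1, p$truth$roi2))
    recovery_error(out$transform, pose)
  }
  clean <- run_one(0)
  dirty <- run_one(0.1)
  expect_lt(dirty$rot_deg, 0.3)
  expect_lt(dirty$trans_mm, 0.1)
  expect_lt(clean$rot_deg, 0.3)
})

test_that("cohorts are deterministic and calibrated to their targets", {
  m1 <- generate_cohort(n_per_group = 2, seed = 41,
                        spec_template = phantom_spec())
  m2 <- generate_cohort(n_per_group = 2, seed = 41,
                        spec_template = phantom_spec())
  expect_identical(m1$true_rms, m2$true_rms)
  expect_identical(m1$pair[[1]]$t1$vertices, m2$pair[[1]]$t1$vertices)
  # zero-noise single-case null cohort: measured RMS equals the drawn target
  null <- generate_cohort(n_per_group = 1, group_effects = c(a = 0, b = 0),
                          between_patient_sd = 0,
                          spec_template = phantom_spec(), seed = 43)
  p <- null$pair[[1]]
  out <- run_case(case_config(p$t0, p$t1, p$truth$roi1, p$truth$roi2))
  expect_lt(out$case$rms_3d_error, 1e-6)
  # drawn magnitudes standardise exactly to the requested moments
  m5 <- generate_cohort(n_per_group = 5, seed = 47,
                        spec_template = phantom_spec())
  for (g in unique(m5$group)) {
    tr <- m5$true_rms[m5$group == g]
    expect_equal(mean(tr), c(splintless = 1.22, splint = 1.63)[[g]],
                 tolerance = 1e-9)
    expect_equal(sd(tr), 0.4, tolerance = 1e-9)
  }
  expect_error(generate_cohort(n_per_group = 0), "n_per_group")
  expect_error(generate_cohort(group_effects = c(-1, 1)), "non-negative")
})

test_that("cohort files round-trip: written STL/ROI reproduce in-memory runs", {
  dir <- withr::local_tempdir()
  man <- generate_cohort(out_dir = dir, n_per_group = 2, seed = 53,
                         spec_template = phantom_spec(noise_sd = 0.05))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  row <- man[1, ]
  from_file <- run_case(case_config(row$t0_path, row$t1_path,
                                    row$roi1_path, row$roi2_path,
                                    case_id = row$case_id))
  expect_equal(from_file$case$rms_3d_error, row$true_rms, tolerance = 0.05)
})
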