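test_that("human reference lung matches the morphometric tables", {
  lung <- human_lung()
  expect_s3_class(lung, "lung_model")
  expect_identical(nrow(lung$airways), 18L)
  expect_identical(nrow(lung$segments), 19L)
  # trachea row as printed
  tr <- lung$airways[lung$airways$id == 1, ]
  expect_equal(tr$length_mm, 100)
  expect_equal(tr$diameter_mm, 16)
  expect_equal(tr$volume_ml, pi * 16^2 * 100 / 4 / 1000)
  # segment volume column is a percentage table summing to exactly 100.0
  expect_equal(sum(table3()$volume_pct), 100)
  expect_equal(sum(lung$segments$f), 1, tolerance = 1e-12)
  expect_true(all(lung$segments$height_pct >= 0 & lung$segments$height_pct <= 100))
  # reference whole-lung parameters
  expect_equal(lung$D_L_O2_ref, 40)
  expect_equal(lung$D_L_CO2, 800)
  expect_lt(lung$shunt_baseline, 0.05)
  expect_equal(lung$deadspace_total_ml, 150)
})

test_that("airway tree is a single-rooted acyclic tree feeding every segment", {
  lung <- human_lung()
  expect_identical(sum(is.na(lung$parent)), 1L)
  expect_identical(lung$airways$id[is.na(lung$parent)], 1L)
  depths <- pulmodpm:::airway_depths(lung)
  expect_true(all(depths <= nrow(lung$airways)))
  # every segment is fed by exactly one leaf compartment
  leaves <- lung$airways$id[lung$is_leaf]
  expect_true(all(lung$segments$feeding_airway_id %in% leaves))
  expect_identical(anyDuplicated(lung$segments$id), 0L)
  # left/right partition reproduces the documented right-lung volume share
  expect_equal(right_lung_fraction(lung), 0.525, tolerance = 1e-12)
})

test_that("sheep lung has six lobes with renormalized printed fractions", {
  sheep <- sheep_lung()
  expect_identical(nrow(sheep$airways), 6L)
  expect_identical(nrow(sheep$segments), 6L)
  expect_equal(sheep$airways$length_mm[sheep$airways$id == 1], 91.1)
  expect_equal(sheep$airways$volume_ml[sheep$airways$id == 1], 8.6)
  # printed alveolar percentages sum to 100.1; fractions renormalize
  lob <- read_anatomy_table("sheep_lobes.tsv")
  expect_equal(sum(lob$volume_pct), 100.1)
  expect_equal(sheep$segments$f[sheep$segments$id == 20], 31.1 / 100.1,
               tolerance = 1e-12)
  expect_equal(sum(sheep$segments$f), 1, tolerance = 1e-12)
  # lobar ids follow the human numbering convention
  expect_identical(sheep$segments$id, 19:24)
  # right lung has 4 lobes, left 2
  expect_identical(sum(sheep$segments$side == "right"), 4L)
})

test_that("goat uses sheep anatomy scaled to goat mass", {
  goat <- build_goat_lung(30)
  expect_identical(goat$species, "goat")
  expect_identical(nrow(goat$segments), 6L)
  sheep <- sheep_lung()
  expect_equal(goat$frc_ml / sheep$frc_ml, 30 / 40, tolerance = 1e-12)
})

test_that("allometric scaling follows the volume and surface-area power laws", {
  lung <- human_lung()
  expect_identical(scale_anatomy(lung, 70), lung)   # ratio 1 is the identity
  m2 <- scale_anatomy(lung, 140)
  expect_equal(m2$airways$volume_ml, lung$airways$volume_ml * 2)
  expect_equal(m2$frc_ml, lung$frc_ml * 2)
  expect_equal(m2$D_L_O2_ref, lung$D_L_O2_ref * 2^(2 / 3))
  expect_equal(m2$segments$f, lung$segments$f)       # fractions unchanged
  m8 <- scale_anatomy(lung, 70 * 8)
  expect_equal(m8$D_L_O2_ref, lung$D_L_O2_ref * 4)   # 8^(2/3) = 4 exactly
  # composition: scaling by a then b equals scaling by a*b once
  ma <- scale_anatomy(scale_anatomy(lung, 91), 55)
  mb <- scale_anatomy(lung, 55)
  expect_equal(ma$airways$volume_ml, mb$airways$volume_ml, tolerance = 1e-12)
  expect_equal(ma$D_L_O2_ref, mb$D_L_O2_ref, tolerance = 1e-12)
})

test_that("invalid masses are rejected", {
  expect_error(build_human_lung(0), "positive")
  expect_error(build_sheep_lung(-3), "positive")
  expect_error(scale_anatomy(human_lung(), 0), "positive")
})
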