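test_that("effective layer SLD is the volume-fraction weighted mean", {
  # half-hydrated headgroup in D2O
  expect_equal(effective_layer_sld(c(headgroup = 0.5), solvent_fraction = 0.5,
                                   contrast_sld = 6.35), 4.115,
               tolerance = 1e-12)
  # dry tail layer, 80/20 deuterated tails / drug
  expect_equal(effective_layer_sld(c(tails = 0.8, cpz = 0.2),
                                   solvent_fraction = 0,
                                   contrast_sld = 6.35), 2.796,
               tolerance = 1e-12)
  # a pure-solvent layer carries the contrast SLD exactly
  expect_equal(effective_layer_sld(c(tails = 0), solvent_fraction = 1,
                                   contrast_sld = 2.07), 2.07,
               tolerance = 1e-12)
  expect_error(effective_layer_sld(c(tails = 0.6), solvent_fraction = 0.2,
                                   contrast_sld = 0), "sum to 1")
})

test_that("stack compilation produces the five-layer bilayer geometry", {
  m <- blank_model()
  st <- compile_stack(m, mix_solvent_contrast(1))
  # oxide + 4 bilayer layers (five membrane slabs incl. oxide)
  expect_equal(length(st$layers$thickness), 5)
  expect_equal(st$layers$thickness, c(12, 8, 17.5, 17.5, 8))
  expect_equal(st$incident_sld, 2.07)
  # optional thin water layer adds one slab
  m2 <- blank_model(t_water_gap = 4)
  st2 <- compile_stack(m2, mix_solvent_contrast(1))
  expect_equal(length(st2$layers$thickness), 6)
  expect_equal(st2$layers$sld[2], mix_solvent_contrast(1)$sld)
  # disabling the optional slots reproduces the plain stack
  m3 <- blank_model(t_water_gap = 0)
  expect_equal(compile_stack(m3, mix_solvent_contrast(0.38)),
               compile_stack(m, mix_solvent_contrast(0.38)))
})

test_that("two contrasts share all structure and differ only in SLD", {
  m <- cpz_1ad_model()
  s1 <- compile_stack(m, mix_solvent_contrast(0))
  s2 <- compile_stack(m, mix_solvent_contrast(1))
  expect_identical(s1$layers$thickness, s2$layers$thickness)
  expect_identical(s1$layers$rough, s2$layers$rough)
  expect_true(all(abs(s1$layers$sld - s2$layers$sld) > 0))
})

test_that("variant / adsorbed-layer mismatches and bad inventories error", {
  expect_error(membrane_model("CPZ_TAILS_1AD"), "adsorbed")
  expect_error(membrane_model("BLANK",
                              adsorbed = list(list(thickness = 10, sld = 2,
                                                   solvent = 0.5))),
               "adsorbed")
  expect_error(blank_model(tail_in = list(cpz = 1.2, solvent = 0)),
               "\\[0, 1\\]")
  # headgroup drug requires the explicit flag
  expect_error(blank_model(head_in = list(cpz = 0.1, solvent = 0.5)),
               "allow_headgroup_cpz")
  m <- membrane_model("CPZ_TAILS",
                      head_in = list(cpz = 0.1, solvent = 0.5),
                      tail_in = list(cpz = 0.2, solvent = 0.05),
                      allow_headgroup_cpz = TRUE)
  expect_s3_class(m, "membrane_model")
})

test_that("volume-fraction profiles conserve component volume and sum to 1", {
  m <- cpz_1ad_model(cpz = 0.22)
  prof <- volume_fraction_profile(m, z_step = 0.1)
  expect_true(all(abs(rowSums(prof[, -1]) - 1) < 1e-9))
  expect_true(all(prof[, -1] >= 0 & prof[, -1] <= 1 + 1e-12))
  # integral of the drug profile equals sum(t * phi) over layers
  cpz_integral <- sum(prof$cpz) * 0.1
  cpz_expected <- 2 * 15 * 0.95 * 0.22
  expect_equal(cpz_integral, cpz_expected, tolerance = 0.005)
  # tails likewise
  t_int <- sum(prof$tails) * 0.1
  expect_equal(t_int, 2 * 15 * 0.95 * 0.78, tolerance = 0.005)
})

test_that("zero roughness gives an exact boxcar profile", {
  m <- blank_model(rough_substrate = 1e-6, rough_membrane = 1e-6)
  prof <- volume_fraction_profile(m, z_step = 0.05)
  mid_tail <- prof$tails[prof$z > 25 & prof$z < 30]
  expect_true(all(abs(mid_tail - 0.95) < 1e-9))
  blank_cpz <- volume_fraction_profile(blank_model(), z_step = 0.5)$cpz
  expect_true(all(blank_cpz == 0))
})

test_that("structural summary reports thickness, occupancy and coverage", {
  m <- blank_model()
  s <- summarize_structure(m)
  expect_equal(s$total_thickness, 2 * (8 + 17.5))
  expect_equal(s$total_thickness, 51)
  expect_equal(s$coverage, 0.95)
  # blank fits sit inside the reported experimental ranges
  expect_gte(m$t_head, 7); expect_lte(m$t_head, 9)
  expect_gte(m$t_tail, 17); expect_lte(m$t_tail, 18)
  mc <- cpz_1ad_model(cpz = 0.2)
  sc <- summarize_structure(mc)
  expect_true(all(sc$cpz_tail_fraction >= 0.15 & sc$cpz_tail_fraction <= 0.25))
  expect_equal(sc$adsorbed_extent, 119)
})

test_that("drug retention is the post/pre volume ratio in percent", {
  before <- summarize_structure(cpz_1ad_model(cpz = 0.38))
  after <- summarize_structure(cpz_1ad_model(cpz = 0.17))
  expect_equal(cpz_retention(before, after), 45)
  expect_equal(cpz_retention(before, before), 100)
  gone <- summarize_structure(cpz_1ad_model(cpz = 0))
  expect_equal(cpz_retention(before, gone), 0)
  expect_error(cpz_retention(gone, before), "undefined")
})
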