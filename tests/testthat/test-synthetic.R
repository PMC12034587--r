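test_that("slide generation is seed-deterministic and respects ground-truth containment", {
  cfg <- slide_gen_config(tissue_blob_count = 2L, hole_count = 1L,
                          anomaly_lesion_count = 1L, seed = 7L)
  s1 <- generate_slide(cfg)
  s2 <- generate_slide(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$tissue_truth, s2$tissue_truth)
  expect_identical(s1$anomaly_truth, s2$anomaly_truth)
  # every anomalous pixel is a tissue pixel
  expect_true(all(s1$tissue_truth[s1$anomaly_truth]))
  expect_equal(dim(s1$image)[1:2], dim(s1$tissue_truth))
})

test_that("a slide without lesions has an all-zero anomaly mask", {
  s <- generate_slide(slide_gen_config(anomaly_lesion_count = 0L, seed = 3L))
  expect_false(any(s$anomaly_truth))
})

test_that("a centered disc blob rasterizes to the closed-form disc area", {
  cfg <- slide_gen_config(width_px = 1024L, height_px = 1024L, seed = 5L,
                          blob_centers = matrix(c(512, 512), 1),
                          blob_radii = 200)
  s <- generate_slide(cfg)
  expect_lt(abs(sum(s$tissue_truth) - pi * 200^2) / (pi * 200^2), 0.02)
})

test_that("undersized slides are rejected", {
  expect_error(slide_gen_config(width_px = 256L), "512")
})

test_that("patch banks are labelled, deterministic, and show the configured contrast", {
  cfg <- slide_gen_config(seed = 13L)
  b <- generate_patch_bank(cfg, 10L, 0L, 64L)
  expect_length(b$label, 10L)
  expect_true(all(b$label == "normal"))
  b2 <- generate_patch_bank(cfg, 10L, 0L, 64L)
  expect_identical(b$pixels, b2$pixels)

  for (tex in c("hemorrhage_like", "infiltrate_like", "deposit_like")) {
    cfgT <- slide_gen_config(anomaly_texture = tex, seed = 17L)
    bank <- generate_patch_bank(cfgT, 30L, 30L, 64L)
    mn <- mean(bank$pixels[, , , bank$label == "normal"])
    ma <- mean(bank$pixels[, , , bank$label == "anomalous"])
    expect_gt(mn - ma, 0.5 * expected_bank_contrast(tex))
  }
})

test_that("clinical tables follow the 18-variable schema with controlled missingness", {
  tab <- generate_clinical_table(clinical_gen_config(30L, 10L, seed = 2L))
  expect_identical(setdiff(names(tab), c("patient_id", "outcome")),
                   clinical_schema()$name)
  expect_length(clinical_schema()$name, 18L)
  expect_false(anyNA(tab))
  expect_equal(sum(tab$outcome), 10L)

  big <- generate_clinical_table(clinical_gen_config(5000L, 5000L,
                                                     missing_rate = 0.1,
                                                     seed = 9L))
  cells <- as.matrix(big[, clinical_schema()$name])
  expect_lt(abs(mean(is.na(cells)) - 0.1), 0.01)
})

test_that("invalid missingness rates are rejected", {
  expect_error(clinical_gen_config(10L, 10L, missing_rate = 1), "missing_rate")
})

test_that("a configured class effect is recoverable with the configured sign", {
  tab <- generate_clinical_table(clinical_gen_config(
    1000L, 1000L, effect_sizes = list(nihss = 2), seed = 12L))
  d <- mean(tab$nihss[tab$outcome == 1]) - mean(tab$nihss[tab$outcome == 0])
  expect_gt(d, 0)
  tab2 <- generate_clinical_table(clinical_gen_config(
    1000L, 1000L, effect_sizes = list(age = -5), seed = 12L))
  d2 <- mean(tab2$age[tab2$outcome == 1]) - mean(tab2$age[tab2$outcome == 0])
  expect_lt(d2, 0)
})

test_that("cohort generation couples banks and clinical rows by patient id", {
  co <- generate_cohort(n_normal = 4L, n_abnormal = 3L,
                        patches_per_patient = 6L, patch_px = 32L, seed = 8L)
  expect_identical(names(co$banks), co$clinical$patient_id)
  anom_frac <- sapply(co$banks, function(b) mean(b$label == "anomalous"))
  expect_true(all(anom_frac[co$clinical$outcome == 0] == 0))
  expect_true(all(anom_frac[co$clinical$outcome == 1] > 0))
})
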