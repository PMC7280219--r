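# zero between-subject variability: site metadata equals the group defaults
exact_config <- function(...) {
  tiny_config(..., subject_sd = c(tau1_ns = 0, tau2_ns = 0,
                                  a2_fraction = 0, sg_depth_um = 0,
                                  sb_depth_um = 0, puncta_density = 0))
}

test_that("layer selection reads SG/SB depths from stack metadata", {
  cfg <- exact_config()
  site <- generateSubject("control", cfg, seed = 2)$sites[[1]]
  sel <- selectLayers(site)
  expect_equal(sel$sg_depth_um, 25)   # control truth
  expect_equal(sel$sb_depth_um, 55)
  expect_equal(depthFeatures(sel),
               c(depth_SG_um = 25, dist_SG_SB_um = 30))

  # explicit indices on the 5 um grid
  cfg_full <- tiny_config(render = "full", frame_size = 64L,
                          n_sections = 10L)
  site_full <- generateSubject("control", cfg_full, seed = 2)$sites[[1]]
  sel_ix <- selectLayers(site_full, indices = c(3, 9))
  expect_equal(sel_ix$sg_depth_um, 15)
  expect_equal(sel_ix$sb_depth_um, 45)

  # psoriasis defaults: SG 30, SB 90
  pso <- generateSubject("psoriasis", exact_config(), seed = 3)
  expect_equal(depthFeatures(selectLayers(pso$sites[[1]])),
               c(depth_SG_um = 30, dist_SG_SB_um = 60))

  # a single-frame stack cannot yield two distinct layers
  one <- site
  keep <- sel$sg_index
  one$frames[-keep] <- list(NULL)
  expect_error(selectLayers(one), class = "flim_inconsistent_layers")
})

test_that("condition feature vectors have the fixed 8-feature schema", {
  cfg <- exact_config()
  site <- generateSubject("control", cfg, seed = 4)$sites[[1]]
  sm <- siteSummary(site, cfg)
  v <- conditionFeatures(sm)
  expect_identical(names(v), CONDITION_FEATURES)
  expect_true(all(is.finite(v)))
  expect_equal(v[["dist_SG_SB_um"]], 30)

  sm_bad <- sm
  sm_bad$entropy_SG <- NA_real_
  expect_error(conditionFeatures(sm_bad), class = "flim_incomplete_subject")
})

test_that("PASI feature ratios compare inflamed to pseudo-control sites", {
  cfg <- exact_config()
  pso <- generateSubject("psoriasis", cfg, seed = 9)
  sms <- lapply(pso$sites, siteSummary, config = cfg)

  # identical sites: all ratios exactly 1
  v_same <- pasiFeatures(sms[[1]], sms[[1]])
  expect_identical(names(v_same), PASI_FEATURES)
  expect_equal(unname(v_same[2:4]), c(1, 1, 1))

  # generator defaults: inflamed epidermis twice as thick
  v <- pasiFeatures(sms[[1]], sms[[2]])
  expect_equal(v[["dist_SG_SB_inflamed_um"]], 60)
  expect_equal(v[["dist_ratio_inflamed_over_pseudo"]], 2.0)
  expect_gt(v[["p2_SG_ratio_inflamed_over_pseudo"]], 1)
  expect_true(v[["p1_SB_inflamed_percent"]] >= 0 &&
              v[["p1_SB_inflamed_percent"]] <= 100)

  expect_error(pasiFeatures(sms[[1]], NULL),
               class = "flim_incomplete_subject")
  broken <- sms[[2]]; broken$fourier_SB <- 0
  expect_error(pasiFeatures(sms[[1]], broken),
               class = "flim_degenerate_ratio")
})

test_that("cohort feature tables assemble, label and exclude correctly", {
  cfg <- tiny_config()
  coh <- generateCohort(c(control = 2, psoriasis = 2), cfg, seed = 33)
  ss <- cohortSiteSummaries(coh, cfg)

  tab <- cohortFeatureTable(coh, "condition", cfg, site_summaries = ss)
  expect_equal(nrow(tab), 6)  # 2 control sites + 2 x 2 psoriasis sites
  expect_setequal(unique(tab$group),
                  c("control", "psoriasis", "pseudo_control"))
  expect_true(all(CONDITION_FEATURES %in% colnames(tab)))
  expect_equal(nrow(attr(tab, "excluded")), 0)

  ptab <- cohortFeatureTable(coh, "pasi", cfg, site_summaries = ss)
  expect_equal(nrow(ptab), 2)
  expect_true(all(PASI_FEATURES %in% colnames(ptab)))

  # a control-only cohort has no PASI-mode rows
  ctrl <- generateCohort(c(control = 2), cfg, seed = 34)
  expect_error(cohortFeatureTable(ctrl, "pasi", cfg),
               class = "flim_incomplete_subject")
})

test_that("group-mean feature differences carry the constructed effect signs", {
  cfg <- tiny_config()
  coh <- generateCohort(c(control = 4, psoriasis = 4), cfg, seed = 55)
  tab <- cohortFeatureTable(coh, "condition", cfg)
  mu <- function(g, f) mean(tab[tab$group == g, f])
  expect_gt(mu("psoriasis", "tau2_mean_SB"), mu("control", "tau2_mean_SB"))
  expect_gt(mu("psoriasis", "tau1_mean_SB"), mu("control", "tau1_mean_SB"))
  expect_gt(mu("psoriasis", "dist_SG_SB_um"), mu("control", "dist_SG_SB_um"))
  expect_gt(mu("psoriasis", "depth_SG_um"), mu("control", "depth_SG_um"))
  expect_gt(mu("psoriasis", "tau2_std_SG"), mu("control", "tau2_std_SG"))
})
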