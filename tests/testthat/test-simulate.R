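test_that("parameter validation rejects impossible values", {
  expect_error(sim_params(k_uptake = -1), "rates")
  expect_error(sim_params(f_escape = 1.5), "fractions")
  expect_error(sim_params(dose_copies = 0), "positive")
})

test_that("no uptake means a constant medium pool and empty cells", {
  p <- sim_params(k_uptake = 0)
  s <- simulate_compartments(p, c(1, 5, 24))
  expect_equal(s$medium, rep(p$dose_copies, 3))
  expect_equal(s$cell_translatable, rep(0, 3))
  expect_equal(s$ev, rep(0, 3))
})

test_that("with no decay or egress, medium plus cells conserve the dose", {
  p <- sim_params(k_deg = 0, k_ev = 0, k_endo_deg = 0, k_translate = 0)
  s <- simulate_compartments(p, c(0.5, 2, 10))
  total <- s$medium + s$cell_internalized + s$cell_translatable
  expect_equal(total, rep(p$dose_copies, 3), tolerance = 1e-12)
})

test_that("mRNA copies are conserved at every step to 1e-9 relative", {
  s <- simulate_compartments(default_sim_params(), c(0.5, 1, 5, 24))
  expect_lt(attr(s, "conservation_error"), 1e-9)
  # also under a wash event
  sw <- simulate_compartments(default_sim_params(), c(0.5, 1, 5, 24),
                              wash_h = 1)
  expect_lt(attr(sw, "conservation_error"), 1e-9)
  expect_equal(sw$medium[sw$timepoint_h == 5], 0)
  expect_gt(sw$cell_translatable[sw$timepoint_h == 5], 0)
})

test_that("default calibration places the peaks at the observed times", {
  s <- simulate_compartments(default_sim_params(), c(0.5, 1, 5, 24))
  pc <- s$per_cell_copies
  expect_equal(s$timepoint_h[which.max(pc)], 1)
  expect_equal(pc[s$timepoint_h == 1], 1355, tolerance = 0.01)
  pe <- s$per_ev_copies
  expect_equal(s$timepoint_h[which.max(pe)], 5)
  expect_equal(pe[s$timepoint_h == 5], 31, tolerance = 0.01)
  expect_lte(s$medium_frac[s$timepoint_h == 5], 0.20)
})

test_that("identical seeds give identical datasets; seeds differ by noise only", {
  a <- simulate_dataset(default_sim_params(seed = 11))
  b <- simulate_dataset(default_sim_params(seed = 11))
  expect_identical(a, b)
  c <- simulate_dataset(default_sim_params(seed = 12))
  strip <- function(gt) as.data.frame(lapply(unclass(gt), identity))
  expect_identical(strip(a$ground_truth), strip(c$ground_truth))
  expect_false(identical(a$qpcr[[1]]$unknowns$cq,
                         c$qpcr[[1]]$unknowns$cq))
})

test_that("noiseless qPCR observation is an exact pipeline inverse", {
  set.seed(6)
  truth <- 5.4e8
  obs <- observe_qpcr(truth, cq_sd = 0)
  fit <- standard_curve(obs$standards$quantity_ng, obs$standards$cq)
  q <- quantify_unknowns(fit, obs$unknowns, mw = vegfa_mrna_mw(),
                         force = TRUE)
  expect_equal(mean(q$copies), truth, tolerance = 1e-6)
})

test_that("noisy qPCR recovery is nearly unbiased under the default noise", {
  set.seed(31)
  truth <- 5.4e8
  est <- replicate(200, {
    obs <- observe_qpcr(truth, cq_sd = 0.2)
    fit <- standard_curve(obs$standards$quantity_ng, obs$standards$cq)
    mean(quantify_unknowns(fit, obs$unknowns, mw = vegfa_mrna_mw(),
                           force = TRUE)$copies)
  })
  expect_lt(abs(mean(est) / truth - 1), 0.1)
})

test_that("ELISA observation inverts exactly without noise, closely with", {
  prot_mw <- 22313.64
  noiseless <- observe_elisa(1e12, prot_mw, volume_ml = 1, cv = 0, n = 3)
  # hand value: 1e12 / N_A * 22313.64 g -> pg in 1 mL
  expect_equal(attr(noiseless, "true_pg_ml"), 37052.7, tolerance = 1e-5)
  expect_equal(elisa_to_copies(as.numeric(noiseless), prot_mw),
               rep(1e12, 3), tolerance = 1e-12)

  set.seed(13)
  noisy <- observe_elisa(1e12, prot_mw, cv = 0.15, n = 6)
  rec <- mean(elisa_to_copies(as.numeric(noisy), prot_mw))
  expect_lt(abs(rec / 1e12 - 1), 0.15)
})

test_that("positivity scoring responds to threshold and mean", {
  set.seed(9)
  expect_equal(observe_positivity(50, threshold = 0), 100)
  expect_lt(observe_positivity(1, threshold = 1e6, n_cells = 1e4), 1)
  expect_equal(observe_positivity(0, threshold = 10), 0)
  p <- default_sim_params()
  s <- simulate_compartments(p, c(2))
  frac <- observe_positivity(s$per_cell_copies, p$positivity_threshold,
                             p$cell_sigma, p$n_cells)
  expect_gte(frac, 90)
})

test_that("the bundled dataset carries coherent tables", {
  ds <- simulate_dataset(default_sim_params(seed = 2),
                         timepoints_h = c(0.5, 1, 5, 24))
  expect_named(ds, c("ground_truth", "qpcr", "elisa", "nta",
                     "positivity_2h", "params"))
  expect_length(ds$qpcr, 8) # cell + EV at 4 timepoints
  expect_equal(nrow(ds$qpcr[[1]]$standards), 21) # 7 dilutions x 3 wells
  expect_length(ds$nta, 4)
  nta1 <- ds$nta[[1]]
  s <- summarize_nta(nta1$capture_sizes_nm, nta1$capture_conc_per_ml,
                     nta1$dilution_factor)
  expect_equal(s$n_captures, 3)
})
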