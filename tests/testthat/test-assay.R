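cfg <- neovax_config()
dilutions <- cfg$top_concentration / cfg$dilution_factor^(0:7)

test_that("noiseless 4PL stabilization curves are recovered within 1%", {
  for (true_ec50 in c(0.5, 3, 10, 40)) {
    mfi <- 150 + (1200 - 150) / (1 + true_ec50 / dilutions)
    res <- fit_ec50(dilutions, mfi, 150)
    expect_equal(res$fit_method, "logistic_fit")
    expect_lt(abs(res$ec50_um / true_ec50 - 1), 0.01)
  }
})

test_that("EC50 at the half-maximal point matches the generator definition", {
  # with zero noise the signal at c = EC50 is exactly the midpoint
  curves <- gen_binding_curves("p", c(p = 10), 0, seed = 1, cfg)
  sig_at_ec50 <- 150 + (1200 - 150) / (1 + 10 / 10)
  expect_equal(sig_at_ec50, (150 + 1200) / 2)
  res <- fit_binding_curves(curves, cfg)
  expect_lt(abs(res$ec50_um / 10 - 1), 0.01)
  expect_true(res$binder)
})

test_that("flat curves yield no EC50 and a non-binder call", {
  flat <- rep(150, 8)
  res <- fit_ec50(dilutions, flat, 150)
  expect_true(is.na(res$ec50_um))
  expect_equal(res$fit_method, "none")
  expect_false(call_binder(res, 150, cfg))
})

test_that("EC50 fitting needs at least 4 points and ignores row order", {
  expect_error(fit_ec50(dilutions[1:3], c(1000, 800, 400), 100),
               "insufficient data")
  mfi <- 150 + (1200 - 150) / (1 + 8 / dilutions)
  ord <- sample(seq_along(dilutions))
  a <- fit_ec50(dilutions, mfi, 150)
  b <- fit_ec50(dilutions[ord], mfi[ord], 150)
  expect_equal(a$ec50_um, b$ec50_um, tolerance = 1e-8)
})

test_that("interpolation crossing matches hand arithmetic", {
  # piecewise-linear curve crossing 600 between 3.70 and 11.11 uM with
  # signals 400 and 800: the log-linear crossing is the geometric mean
  conc <- c(100, 33.3333, 11.1111, 3.7037, 1.2346, 0.4115, 0.1372, 0.0457)
  sig <- c(1000, 900, 800, 400, 200, 150, 120, 110)
  cross <- neovax:::interpolate_crossing(conc, sig, 600)
  expect_equal(cross, sqrt(11.1111 * 3.7037), tolerance = 1e-4)
})

test_that("noisy EC50 recovery has small geometric-mean bias", {
  true_ec50 <- setNames(10^seq(0, 1.5, length.out = 100),
                        sprintf("pep%03d", 1:100))
  curves <- gen_binding_curves(names(true_ec50), true_ec50,
                               noise_cv = 0.05, seed = 11, cfg = cfg)
  fits <- fit_binding_curves(curves, cfg)
  m <- merge(fits, data.frame(peptide_id = names(true_ec50),
                              true = unname(true_ec50)))
  expect_false(any(is.na(m$ec50_um)))
  # geometric mean of fitted/true within 10%
  expect_lt(abs(mean(log(m$ec50_um) - log(m$true))), log(1.1))
})

test_that("IC50 is the 50%-inhibition concentration of the FITC reference", {
  # signal equals reference/2 exactly at the true IC50
  curves <- gen_binding_curves("comp", c(comp = 25), 0, seed = 2, cfg,
                               assay_type = "competition")
  ref <- curves$reference_no_competitor[1]
  at25 <- curves$signal[abs(curves$concentration_um - 25) < 12 &
                          curves$concentration_um > 0]
  res <- fit_ic50(curves$concentration_um, curves$signal, ref, "comp")
  expect_lt(abs(res$ic50_um / 25 - 1), 0.01)
  # no inhibition anywhere: absent IC50, non-binder
  flat <- gen_binding_curves("none", c(), 0, seed = 3, cfg,
                             assay_type = "competition")
  r0 <- fit_ic50(flat$concentration_um, flat$signal,
                 flat$reference_no_competitor[1], "none")
  expect_true(is.na(r0$ic50_um))
  expect_false(call_binder(r0, 0, cfg))
  expect_error(fit_ic50(dilutions, rep(1, 8), 0), "reference")
  # noiseless descending 4PL with IC50 5 uM recovered within 1%
  c5 <- gen_binding_curves("p5", c(p5 = 5), 0, seed = 4, cfg,
                           assay_type = "competition")
  r5 <- fit_ic50(c5$concentration_um, c5$signal,
                 c5$reference_no_competitor[1], "p5")
  expect_lt(abs(r5$ic50_um / 5 - 1), 0.01)
})

test_that("binder calls require both a determinate EC50 and a real plateau", {
  mk_res <- function(ec50, plateau) {
    structure(list(peptide_id = "p", assay_type = "stabilization",
                   ec50_um = ec50, baseline = 100, plateau = plateau,
                   fit_method = "logistic_fit"),
              class = "binding_result")
  }
  expect_true(call_binder(mk_res(8, 300), 100, cfg))     # plateau 3x
  expect_false(call_binder(mk_res(NA_real_, 300), 100, cfg))
  expect_false(call_binder(mk_res(8, 120), 100, cfg))    # plateau 1.2x
  expect_false(call_binder(mk_res(400, 300), 100, cfg))  # beyond range
})

test_that("responder calls implement the inclusive twice-background rule", {
  expect_true(call_responder(1.2, 0.5, cfg))
  expect_false(call_responder(0.9, 0.5, cfg))
  expect_true(call_responder(1.0, 0.5, cfg))   # boundary: twice or higher
  # zero background is floored so tiny signals do not auto-respond
  expect_false(call_responder(0.15, 0, cfg))
  expect_true(call_responder(0.2, 0, cfg))
})

test_that("responder calling recovers the planted responder set exactly", {
  peps <- sprintf("pep%02d", 1:6)
  subjects <- paste0("donor", 1:4)
  planted <- tibble::tibble(
    subject_id = c("donor1", "donor2", "donor2", "donor4"),
    peptide_id = c("pep01", "pep01", "pep03", "pep05")
  )
  for (bg in c(0.05, 0.4, 2)) {
    tc <- gen_tcell_assays(peps, subjects, planted, background_pct = bg,
                           seed = 13, cfg = cfg)
    calls <- call_responder(tc$stim_pct, tc$unstim_pct, cfg)
    got <- tc[calls, c("subject_id", "peptide_id")]
    expect_setequal(paste(got$subject_id, got$peptide_id),
                    paste(planted$subject_id, planted$peptide_id))
  }
  # empty responder set stays empty
  tc0 <- gen_tcell_assays(peps, subjects, planted[0, ], seed = 13,
                          cfg = cfg)
  expect_false(any(call_responder(tc0$stim_pct, tc0$unstim_pct, cfg)))
})
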