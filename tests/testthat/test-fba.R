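# FBA assembly and optimisation on core models.

test_that("ATP objective is the single hydrolysis column; biomass carries 12 precursors", {
  m <- fix_model("ecoli_like")
  med <- get_media(tmpl, "glc_o2")
  lp <- build_lp(m, med, "atp_hydrolysis")
  expect_identical(sum(lp$obj != 0), 1L)
  expect_identical(names(lp$obj)[lp$obj != 0], "ATPM")
  # the hydrolysis reaction is ATP + H2O -> ADP + Pi + H+
  expect_equal(tmpl$reactions$ATPM$stoich[c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c")],
               c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1))

  lpb <- build_lp(m, med, "biomass")
  bio <- lpb$S[, tmpl$biomass$id]
  prec <- vapply(tmpl$biomass$precursors, `[[`, "", "compound")
  expect_length(prec, 12)
  expect_true(all(bio[prec] < 0))

  lpd <- build_lp(m, med, drain("oaa_c"))
  expect_true("SINK_oaa_c" %in% colnames(lpd$S))
  expect_identical(ncol(lpd$S), ncol(lp$S) + 1L)
  expect_error(build_lp(m, med, drain("btcoa_c")), "absent from model")
})

test_that("no free lunch: all exchanges closed gives zero ATP and zero drains", {
  med <- closed_media()
  for (nm in c("ecoli_like", "clostridium_like")) {
    m <- fix_model(nm)
    r <- fba(m, med, "atp_hydrolysis")
    expect_equal(r$objective_value, 0, tolerance = 1e-7)
    expect_true(is.na(r$yield))
  }
  expect_false(any(precursor_producibility(fix_model("ecoli_like"), med)))
})

test_that("doubling the carbon uptake bound doubles the optimum but not the yield", {
  m <- fix_model("ecoli_like")
  med <- get_media(tmpl, "glc_o2")
  r1 <- fba(m, med, "atp_hydrolysis")
  med2 <- med
  med2$exchange_bounds[med$carbon_source, "uptake"] <- 20
  r2 <- fba(m, med2, "atp_hydrolysis")
  expect_equal(r2$objective_value, 2 * r1$objective_value, tolerance = 1e-6)
  expect_equal(r2$yield, r1$yield, tolerance = 1e-8)
})

test_that("opening an electron-acceptor exchange never decreases the ATP yield", {
  for (nm in c("ecoli_like", "bsubtilis_like", "bacteroides_like")) {
    m <- fix_model(nm)
    base <- fba(m, get_media(tmpl, "glc_none"), "atp_hydrolysis")$objective_value
    for (acc in c("glc_o2", "glc_no3", "glc_tmao")) {
      withacc <- fba(m, get_media(tmpl, acc), "atp_hydrolysis")$objective_value
      expect_gte(withacc, base - 1e-7)
    }
  }
})

test_that("yield matrix reproduces fixture manifests; empty input gives empty table", {
  m <- fix_model("clostridium_like")
  tab <- atp_yield_matrix(list(m), c("glc_none", "glc_no3", "glc_tmao"))
  expect_identical(nrow(tab), 3L)
  # fermentation-only organism: identical yield whatever the acceptor
  expect_equal(max(tab$atp_yield) - min(tab$atp_yield), 0, tolerance = 1e-7)
  man <- fixture_manifest("clostridium_like")
  expect_equal(tab$atp_yield[tab$media == "glc_none"],
               man$atp_yields$glc_none, tolerance = 1e-6)
  empty <- atp_yield_matrix(list(), list())
  expect_identical(nrow(empty), 0L)
})

test_that("glycerol yields less ATP per mol than glucose for the enterobacterial model", {
  m <- fix_model("ecoli_like")
  y_glc <- fba(m, get_media(tmpl, "glc_no3"), "atp_hydrolysis")$yield
  y_gly <- fba(m, get_media(tmpl, "glyc_no3"), "atp_hydrolysis")$yield
  expect_lt(y_gly, y_glc)
})

test_that("precursor producibility distinguishes complete and broken networks", {
  m <- fix_model("ecoli_like")
  med <- get_media(tmpl, "glc_o2")
  expect_true(all(precursor_producibility(m, med)))
  m2 <- m
  m2$reactions <- m2$reactions[setdiff(names(m2$reactions),
                                       c("CS", "ACONT", "ICDHyr", "ICL", "MALS"))]
  pp <- precursor_producibility(m2, med)
  expect_false(pp[["akg_c"]])
  expect_true(pp[["pyr_c"]])
})

test_that("an aerobic optimum can combine respiration with fermentation", {
  # anaerobe fixture carrying a (spurious) bd oxidase but no TCA cycle:
  # at the aerobic optimum the oxidase runs while acetate is secreted
  m <- fix_model("bacteroides_like")
  r <- fba(m, get_media(tmpl, "glc_o2"), "atp_hydrolysis")
  expect_gt(r$fluxes[["CYTBD"]], 1e-6)
  expect_gt(r$fluxes[["EX_ac_e"]], 1e-6)
  expect_gt(r$yield, fba(m, get_media(tmpl, "glc_none"), "atp_hydrolysis")$yield)
})

test_that("media bounds only override exchange reactions", {
  m <- fix_model("ecoli_like")
  lp <- build_lp(m, get_media(tmpl, "glc_o2"))
  internal <- setdiff(names(lp$lower), grep("^EX_", names(lp$lower), value = TRUE))
  tpl_lower <- vapply(tmpl$reactions[internal], `[[`, 0, "lower")
  expect_equal(lp$lower[internal], tpl_lower)
})
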