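# Boolean pathway rules, respiration classes, fermentation capability.

test_that("fixture pathway vectors and respiration classes match their manifests", {
  for (nm in list_fixtures()) {
    m <- fix_model(nm)
    p <- determine_pathways(m)
    man <- fixture_manifest(nm)
    expect_identical(as.list(p$presence), as.list(unlist(man$pathways_present)),
                     info = nm)
    expect_identical(p$respiration, man$respiration, info = nm)
  }
})

test_that("the enterobacterial fixture carries all four glucose-oxidation pathways", {
  p <- determine_pathways(fix_model("ecoli_like"))
  expect_true(all(p$presence[tmpl$pathway_meta$glucose_oxidation]))
  expect_identical(p$respiration, "facultative")
})

test_that("a single missing step breaks a pathway call (gluconolactonase case)", {
  p <- determine_pathways(fix_model("acinetobacter_like"))
  expect_false(p$presence[["entner_doudoroff"]])
  m <- fix_model("acinetobacter_like")
  expect_true(all(c("G6PDH2r", "EDD", "EDA") %in% names(m$reactions)))
  expect_false("PGL" %in% names(m$reactions))
})

test_that("presence calls agree with an independent step-by-step oracle on random subsets", {
  all_ids <- names(tmpl$reactions)
  set.seed(17)
  for (k in 1:100) {
    sub <- sample(all_ids, sample.int(length(all_ids), 1))
    fake <- fix_model("ecoli_like")
    fake$reactions <- stats::setNames(rep("gene_associated", length(sub)), sub)
    p <- determine_pathways(fake)
    expect_identical(unname(p$presence),
                     unname(rule_oracle(sub, tmpl$pathway_rules)))
  }
})

test_that("presence calls are monotone under reaction addition", {
  m <- fix_model("parasite_like")
  p0 <- determine_pathways(m)$presence
  m2 <- add_reactions(m, setdiff(names(tmpl$reactions), names(m$reactions)),
                      evidence = "gapfilled")
  p1 <- determine_pathways(m2)$presence
  expect_false(any(p0 & !p1))
  expect_true(all(p1))      # full template satisfies every rule
})

test_that("respiration classification follows the chain definitions", {
  mk <- function(ids) {
    m <- fix_model("ecoli_like")
    m$reactions <- stats::setNames(rep("gene_associated", length(ids)), ids)
    m
  }
  expect_identical(classify_respiration(mk(c("CYTBO3", "NAR", "NADH16", "ATPS4r"))),
                   "facultative")
  expect_identical(classify_respiration(mk(c("CYTBO3", "NADH16", "ATPS4r"))),
                   "aerobic")
  expect_identical(classify_respiration(mk(c("NAR", "NADH5", "ATPS4r"))),
                   "anaerobic")
  expect_identical(classify_respiration(mk(c("NADH16", "ATPS4r"))), "none")
  expect_identical(classify_respiration(mk(c("CYTBO3", "ATPS4r"))), "none")
  expect_identical(classify_respiration(fix_model("clostridium_like")), "none")
  # spurious oxidase on an anaerobe: classified aerobic, caught later by
  # the phylogenetic outlier screen
  expect_identical(classify_respiration(fix_model("bacteroides_like")), "aerobic")
})

test_that("fermentation capability by FBA matches the fixture manifests", {
  med <- get_media(tmpl, "glc_none")
  fc_e <- fermentation_capability(fix_model("ecoli_like"), med)
  expect_true(all(fc_e[c("acetate", "ethanol", "formate", "lactate")]))
  expect_false(any(fc_e[c("butanol", "butyrate", "acetone")]))
  fc_c <- fermentation_capability(fix_model("clostridium_like"), med)
  expect_true(fc_c[["butyrate"]])
  expect_true(fc_c[["butanol"]])
  expect_error(fermentation_capability(fix_model("ecoli_like"),
                                       get_media(tmpl, "glc_o2")),
               "acceptor-free")
  expect_false(any(fermentation_capability(fix_model("ecoli_like"),
                                           closed_media())))
})

test_that("Boolean presence with reachable substrate implies FBA capability, discrepancies surface", {
  med <- get_media(tmpl, "glc_none")
  for (nm in list_fixtures()) {
    m <- fix_model(nm)
    p <- determine_pathways(m)
    if (!(p$presence[["glycolysis"]] || p$presence[["entner_doudoroff"]])) next
    fc <- fermentation_capability(m, med)
    man <- fixture_manifest(nm)
    # capability never exceeds Boolean presence...
    ferm <- intersect(names(fc), names(p$presence))
    expect_true(all(!fc[ferm] | p$presence[ferm]), info = nm)
    # ...and any present-but-incapable pathway is a recorded discrepancy
    disc <- ferm[p$presence[ferm] & !fc[ferm]]
    expect_setequal(disc,
                    ferm[unlist(man$pathways_present[ferm]) &
                           !unlist(man$fermentation_capability[ferm])])
  }
})
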