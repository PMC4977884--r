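# Template parsing, integrity checks, and round-trip writing.

test_that("packaged template has 12 pathway rules, 7 media, and is fully balanced", {
  expect_length(tmpl$pathway_rules, 12)
  expect_length(tmpl$media, 7)
  expect_setequal(names(tmpl$pathway_rules),
                  c(tmpl$pathway_meta$glucose_oxidation,
                    tmpl$pathway_meta$fermentation))
  expect_length(tmpl$pathway_meta$glucose_oxidation, 4)
  expect_length(tmpl$pathway_meta$fermentation, 8)
  rep <- validate_template(tmpl)
  expect_identical(nrow(rep), 0L)
})

test_that("formula parser handles counts, multi-letter elements, and rejects junk", {
  expect_equal(parse_formula("C6H12O6")[["C"]], 6)
  expect_equal(parse_formula("Fe8S8")[["Fe"]], 8)
  expect_equal(parse_formula("HPO4")[["H"]], 1)
  expect_error(parse_formula("C6H12-"), "not parseable")
})

test_that("equation dialect round-trips including rational coefficients", {
  eq <- "co2_c + 1/3 h_c <=> co2_e + 1/3 h_e"
  st <- parse_equation(eq)
  expect_equal(st[["h_c"]], -1/3)
  expect_equal(st[["co2_e"]], 1)
  st2 <- parse_equation(format_equation(st))
  expect_equal(st2[sort(names(st2))], st[sort(names(st))])
  expect_error(parse_equation("a_c b_c"), "arrow")
})

test_that("GPR parser supports and/or/parentheses with quoted roles", {
  g <- parse_gpr('"role A" and ("role B" or "role C")')
  expect_true(eval_gpr(g, normalize_role(c("role A", "role C"))))
  expect_false(eval_gpr(g, normalize_role("role A")))
  expect_false(eval_gpr(g, normalize_role(c("role B", "role C"))))
  expect_setequal(gpr_roles(g), c("role A", "role B", "role C"))
  expect_true(eval_gpr(parse_gpr("spontaneous"), character(0)))
  expect_error(parse_gpr('role A'), "quoted")
})

test_that("constructed element imbalance is reported with reaction and element", {
  t2 <- tmpl
  # knock one H off the water product of ENO
  t2$reactions$ENO$stoich[["h2o_c"]] <- 0
  t2$reactions$ENO$stoich[["h_c"]] <- 1   # 2pg -> pep + H (O and H now off)
  rep <- validate_template(t2)
  expect_true(any(rep$reaction == "ENO" & rep$type == "element" & rep$what == "H"))
  expect_true(any(rep$reaction == "ENO" & rep$type == "element" & rep$what == "O"))
})

test_that("exchange and biomass reactions are exempt from balance checks", {
  rep <- validate_template(tmpl)
  expect_false(any(grepl("^EX_", rep$reaction)))
  expect_false(any(rep$reaction == tmpl$biomass$id))
})

test_that("loader rejects dangling references and degenerate inputs", {
  src <- system.file("extdata", "template", package = "coremetab")
  tmp <- file.path(tempdir(), "broken_template")
  unlink(tmp, recursive = TRUE)
  dir.create(file.path(tmp, "media"), recursive = TRUE)
  file.copy(list.files(src, full.names = TRUE), tmp, recursive = TRUE)

  rx <- readLines(file.path(tmp, "reactions.tsv"))
  rx[2] <- sub("glc__D_e", "nonexistent_cpd_e", rx[2])
  writeLines(rx, file.path(tmp, "reactions.tsv"))
  expect_error(load_template(tmp), "unknown compound")

  # empty reaction table: header only
  writeLines(readLines(file.path(src, "reactions.tsv"))[1],
             file.path(tmp, "reactions.tsv"))
  expect_error(load_template(tmp), "unknown reaction|empty reaction|unresolvable")
})

test_that("write/load round trip reproduces the template", {
  out <- file.path(tempdir(), "template_roundtrip")
  unlink(out, recursive = TRUE)
  write_template(tmpl, out)
  t2 <- load_template(out)
  expect_identical(names(t2$reactions), names(tmpl$reactions))
  for (id in names(tmpl$reactions)) {
    a <- tmpl$reactions[[id]]; b <- t2$reactions[[id]]
    expect_equal(b$stoich[sort(names(b$stoich))],
                 a$stoich[sort(names(a$stoich))], tolerance = 1e-12)
    expect_identical(c(b$lower, b$upper), c(a$lower, a$upper))
    expect_identical(b$gpr, a$gpr)
    expect_identical(b$etc_tag, a$etc_tag)
  }
  expect_identical(t2$pathway_rules, tmpl$pathway_rules)
  expect_identical(names(t2$media), names(tmpl$media))
  for (nm in names(tmpl$media))
    expect_equal(t2$media[[nm]]$exchange_bounds[rownames(tmpl$media[[nm]]$exchange_bounds), ],
                 tmpl$media[[nm]]$exchange_bounds)
})

test_that("media invariants hold: carbon uptake open, acceptors as declared", {
  for (nm in list_media(tmpl)) {
    med <- get_media(tmpl, nm)
    expect_gt(med$exchange_bounds[med$carbon_source, "uptake"], 0)
    if (!is.na(med$electron_acceptor))
      expect_gt(med$exchange_bounds[med$electron_acceptor, "uptake"], 0)
  }
  expect_error(get_media(tmpl, "marsian_brine"), "unknown medium")
})

test_that("SBML export carries every model reaction and species", {
  m <- fix_model("clostridium_like")
  f <- file.path(tempdir(), "model.xml")
  write_sbml(m, f)
  x <- xml2::read_xml(f)
  rx <- xml2::xml_find_all(x, ".//*[local-name()='reaction']")
  expect_length(rx, length(m$reactions))
  ids <- xml2::xml_attr(rx, "id")
  expect_true(all(paste0("R_", names(m$reactions)) %in% ids))
  expect_true(any(startsWith(ids, "R_EX_")))
  sp <- xml2::xml_find_all(x, ".//*[local-name()='species']")
  cpds <- unique(unlist(lapply(tmpl$reactions[names(m$reactions)],
                               function(r) names(r$stoich))))
  expect_length(sp, length(cpds))
})
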