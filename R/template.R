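# Core model template (CMT): loading, validation, round-trip writing.
#
# The packaged template lives in inst/extdata/template as plain text:
# compounds.tsv, reactions.tsv (equation dialect "2 a_c + 1/3 b_c => c_e"),
# biomass.json, pathway_rules.json and media/*.json.

#' Parse an elemental formula
#'
#' Turns a Hill-style formula string such as \code{"C6H12O6"} into a
#' named count vector.  Only element symbols followed by optional
#' integer counts are allowed.
#'
#' @param formula formula string.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula))
    stop("empty formula")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop(sprintf("formula '%s' is not parseable", formula))
  el <- sub("[0-9]+$", "", toks)
  ct <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

# coefficient token: integer, decimal, or rational "p/q"
.parse_coef <- function(tok) {
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    parts <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    return(parts[1] / parts[2])
  }
  x <- suppressWarnings(as.numeric(tok))
  if (is.na(x)) stop(sprintf("bad stoichiometric coefficient '%s'", tok))
  x
}

#' Parse a reaction equation string
#'
#' The dialect is \code{"2 a_c + 1/3 b_c <=> c_e"}: terms separated by
#' \code{" + "}, each an optional coefficient (integer, decimal or
#' rational) followed by a compound id carrying its compartment suffix.
#' \code{"=>"} and \code{"<=>"} only mark readability; flux bounds are
#' authoritative for reversibility.  An empty side denotes a boundary
#' (exchange) reaction.
#'
#' @param eq equation string.
#' @return named numeric vector of signed coefficients (reactants
#'   negative, products positive).
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("=>", eq, fixed = TRUE)) "=>" else
      stop(sprintf("equation '%s' has no arrow", eq))
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      bits <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(bits) == 1L) {
        coef <- 1; cpd <- bits
      } else if (length(bits) == 2L) {
        coef <- .parse_coef(bits[1]); cpd <- bits[2]
      } else stop(sprintf("cannot parse term '%s'", term))
      out[cpd] <- (if (cpd %in% names(out)) out[[cpd]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  res <- lhs
  for (cpd in names(rhs))
    res[cpd] <- (if (cpd %in% names(res)) res[[cpd]] else 0) + rhs[[cpd]]
  res[res != 0]
}

.format_coef <- function(x) {
  # prefer small rationals for readability/round-trip fidelity
  for (q in c(1L, 2L, 3L, 4L, 6L, 12L)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) {
      p <- round(p)
      return(if (q == 1L) as.character(p) else paste0(p, "/", q))
    }
  }
  format(x, digits = 15)
}

#' Format a stoichiometry vector back into the equation dialect
#' @param stoich named signed coefficient vector.
#' @param reversible logical; use \code{"<=>"} or \code{"=>"}.
#' @return equation string.
#' @export
format_equation <- function(stoich, reversible = TRUE) {
  fmt_side <- function(v) {
    if (!length(v)) return("")
    ids <- names(v)[order(names(v))]
    paste(vapply(ids, function(i) {
      cf <- abs(v[[i]])
      if (abs(cf - 1) < 1e-12) i else paste(.format_coef(cf), i)
    }, ""), collapse = " + ")
  }
  lhs <- fmt_side(stoich[stoich < 0])
  rhs <- fmt_side(stoich[stoich > 0])
  paste(lhs, if (reversible) "<=>" else "=>", rhs) |> trimws()
}

## ---- GPR boolean expressions ------------------------------------------

#' Parse a gene-protein-reaction (GPR) rule
#'
#' Rules are boolean expressions over double-quoted functional-role
#' strings combined with \code{and} / \code{or} and parentheses, e.g.
#' \code{'"role A" and ("role B" or "role C")'}.  The bare markers
#' \code{spontaneous} and \code{universal} denote reactions included in
#' every model irrespective of annotation.
#'
#' @param text rule text.
#' @return a GPR node: a list with \code{op} in
#'   \code{c("and","or","leaf","spontaneous","universal")}.
#' @export
parse_gpr <- function(text) {
  text <- trimws(text)
  if (identical(text, "spontaneous")) return(list(op = "spontaneous"))
  if (identical(text, "universal"))  return(list(op = "universal"))
  if (!nzchar(text)) stop("empty GPR rule (use 'spontaneous' or 'universal')")
  # tokenize
  toks <- list(); i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(text, j, j) != "\"") j <- j + 1L
      if (j > n) stop("unterminated quoted role in GPR")
      toks[[length(toks) + 1L]] <- list(t = "leaf", v = substr(text, i + 1L, j - 1L))
      i <- j + 1L
    } else if (ch == "(") { toks[[length(toks) + 1L]] <- list(t = "("); i <- i + 1L
    } else if (ch == ")") { toks[[length(toks) + 1L]] <- list(t = ")"); i <- i + 1L
    } else {
      j <- i
      while (j <= n && grepl("[A-Za-z]", substr(text, j, j))) j <- j + 1L
      word <- tolower(substr(text, i, j - 1L))
      if (!word %in% c("and", "or"))
        stop(sprintf("unexpected token '%s' in GPR (roles must be quoted)", word))
      toks[[length(toks) + 1L]] <- list(t = word)
      i <- j
    }
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]]$t else NA_character_
  parse_expr <- function() {
    node <- parse_term()
    args <- list(node)
    while (identical(peek(), "or")) {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) node else list(op = "or", args = args)
  }
  parse_term <- function() {
    node <- parse_factor()
    args <- list(node)
    while (identical(peek(), "and")) {
      pos <<- pos + 1L
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) node else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (identical(t, "(")) {
      pos <<- pos + 1L
      node <- parse_expr()
      if (!identical(peek(), ")")) stop("missing ')' in GPR")
      pos <<- pos + 1L
      return(node)
    }
    if (identical(t, "leaf")) {
      v <- toks[[pos]]$v; pos <<- pos + 1L
      return(list(op = "leaf", role = v))
    }
    stop("malformed GPR expression")
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR expression")
  out
}

#' All functional-role leaves of a GPR rule
#' @param gpr parsed GPR node.
#' @return character vector of role strings (empty for markers).
#' @export
gpr_roles <- function(gpr) {
  switch(gpr$op,
         leaf = gpr$role,
         spontaneous = , universal = character(0),
         unique(unlist(lapply(gpr$args, gpr_roles))))
}

#' Evaluate a GPR rule against a role set
#'
#' Role matching is exact string equality after whitespace squeezing and
#' case folding (see [normalize_role()]).
#'
#' @param gpr parsed GPR node.
#' @param roles character vector of normalized annotation roles.
#' @return logical.
#' @export
eval_gpr <- function(gpr, roles) {
  switch(gpr$op,
         spontaneous = TRUE,
         universal = TRUE,
         leaf = normalize_role(gpr$role) %in% roles,
         and = all(vapply(gpr$args, eval_gpr, TRUE, roles = roles)),
         or = any(vapply(gpr$args, eval_gpr, TRUE, roles = roles)))
}

#' Normalize a functional-role string
#'
#' Lower-cases and squeezes internal whitespace so that cosmetic
#' differences between annotation sources do not break exact matching.
#' No fuzzy matching is attempted.
#'
#' @param role character vector.
#' @return normalized character vector.
#' @export
normalize_role <- function(role) {
  tolower(gsub("[[:space:]]+", " ", trimws(role)))
}

## ---- loading ----------------------------------------------------------

.biomass_stoich <- function(bm) {
  st <- numeric(0)
  add <- function(cpd, x) st[cpd] <<- (if (cpd %in% names(st)) st[[cpd]] else 0) + x
  for (p in bm$precursors) add(p$compound, -p$coefficient)
  for (cpd in names(bm$coa_release)) {
    w <- -st[[cpd]]
    add(bm$coa_release[[cpd]], w)
  }
  cf <- bm$cofactors
  if (!is.null(cf$atp) && cf$atp != 0) {
    add("atp_c", -cf$atp); add("h2o_c", -cf$atp)
    add("adp_c", cf$atp); add("pi_c", cf$atp); add("h_c", cf$atp)
  }
  if (!is.null(cf$nadph) && cf$nadph != 0) {
    add("nadph_c", -cf$nadph); add("nadp_c", cf$nadph)
  }
  if (!is.null(cf$nadh) && cf$nadh != 0) {
    # negative consumption = net production during biosynthesis
    add("nadh_c", cf$nadh); add("nad_c", -cf$nadh); add("h_c", cf$nadh)
  }
  st[st != 0]
}

#' Load a core model template from disk
#'
#' Reads the documented plain-text dialect: \code{compounds.tsv},
#' \code{reactions.tsv}, \code{biomass.json}, \code{pathway_rules.json}
#' and \code{media/*.json} under one directory, cross-references all
#' records, and returns a \code{cmt_template}.
#'
#' @param path directory containing the template files.
#' @return an object of class \code{cmt_template} with fields
#'   \code{compounds} (data frame), \code{reactions} (named list of
#'   reaction records), \code{role_index}, \code{biomass},
#'   \code{pathway_rules}, and \code{media}.
#' @export
load_template <- function(path) {
  fp <- function(...) file.path(path, ...)
  for (f in c("compounds.tsv", "reactions.tsv", "biomass.json", "pathway_rules.json"))
    if (!file.exists(fp(f))) stop(sprintf("template file missing: %s", fp(f)))

  cpd <- utils::read.delim(fp("compounds.tsv"), quote = "", stringsAsFactors = FALSE)
  need <- c("id", "name", "formula", "charge", "compartment")
  if (!all(need %in% names(cpd)))
    stop("compounds.tsv: expected columns id, name, formula, charge, compartment")
  if (anyDuplicated(cpd$id))
    stop(sprintf("compounds.tsv: duplicate compound id '%s'",
                 cpd$id[duplicated(cpd$id)][1]))
  bad_cmp <- setdiff(unique(cpd$compartment), c("cytosol", "extracellular"))
  if (length(bad_cmp))
    stop(sprintf("compounds.tsv: unknown compartment '%s'", bad_cmp[1]))
  for (k in seq_len(nrow(cpd))) parse_formula(cpd$formula[k])  # must parse

  rx <- utils::read.delim(fp("reactions.tsv"), quote = "", stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (anyDuplicated(rx$id))
    stop(sprintf("reactions.tsv: duplicate reaction id '%s'",
                 rx$id[duplicated(rx$id)][1]))
  reactions <- vector("list", nrow(rx)); names(reactions) <- rx$id
  for (k in seq_len(nrow(rx))) {
    st <- tryCatch(parse_equation(rx$equation[k]),
                   error = function(e) stop(sprintf(
                     "reactions.tsv line %d (%s): %s", k + 1L, rx$id[k],
                     conditionMessage(e))))
    dangling <- setdiff(names(st), cpd$id)
    if (length(dangling))
      stop(sprintf("reaction '%s' references unknown compound '%s'",
                   rx$id[k], dangling[1]))
    if (rx$lower[k] > rx$upper[k])
      stop(sprintf("reaction '%s': lower bound exceeds upper bound", rx$id[k]))
    gpr <- tryCatch(parse_gpr(rx$gpr[k]),
                    error = function(e) stop(sprintf(
                      "reaction '%s': %s", rx$id[k], conditionMessage(e))))
    tags <- rx$pathways[k]
    tags <- if (nzchar(tags)) strsplit(tags, ";", fixed = TRUE)[[1]] else character(0)
    etc <- rx$etc_tag[k]
    reactions[[k]] <- list(
      id = rx$id[k], name = rx$name[k], stoich = st,
      lower = as.numeric(rx$lower[k]), upper = as.numeric(rx$upper[k]),
      gpr = gpr, gpr_text = rx$gpr[k],
      pathway_tags = tags,
      etc_tag = if (nzchar(etc)) etc else NA_character_,
      proton_translocation = as.numeric(rx$proton_translocation[k]),
      kind = if (startsWith(rx$id[k], "EX_")) "exchange" else "internal")
  }

  bm <- jsonlite::read_json(fp("biomass.json"))
  if (length(bm$precursors) != 12L)
    stop("biomass.json must declare exactly 12 precursors")
  bst <- .biomass_stoich(bm)
  dangling <- setdiff(names(bst), cpd$id)
  if (length(dangling))
    stop(sprintf("biomass references unknown compound '%s'", dangling[1]))
  if (!length(reactions))
    stop("integrity error: empty reaction table, biomass precursors unresolvable")
  reactions[[bm$id]] <- list(
    id = bm$id, name = bm$name, stoich = bst, lower = 0, upper = 1000,
    gpr = list(op = "universal"), gpr_text = "universal",
    pathway_tags = character(0), etc_tag = NA_character_,
    proton_translocation = 0, kind = "biomass")

  pr <- jsonlite::read_json(fp("pathway_rules.json"))
  rules <- lapply(pr$rules, function(steps) lapply(steps, function(s) unlist(s)))
  for (pw in names(rules))
    for (step in rules[[pw]]) {
      missing_rxn <- setdiff(step, names(reactions))
      if (length(missing_rxn))
        stop(sprintf("pathway rule '%s' references unknown reaction '%s'",
                     pw, missing_rxn[1]))
    }

  media <- list()
  mdir <- fp("media")
  if (dir.exists(mdir)) {
    for (f in sort(list.files(mdir, pattern = "\\.json$", full.names = TRUE))) {
      m <- jsonlite::read_json(f, simplifyVector = TRUE)
      m$electron_acceptor <- if (is.null(m$electron_acceptor)) NA_character_ else m$electron_acceptor
      eb <- m$exchange_bounds
      m$exchange_bounds <- do.call(rbind, lapply(eb, as.numeric))
      rownames(m$exchange_bounds) <- names(eb)
      colnames(m$exchange_bounds) <- c("uptake", "secretion")
      if (!m$carbon_source %in% cpd$id)
        stop(sprintf("medium '%s': unknown carbon source", m$name))
      if (m$exchange_bounds[m$carbon_source, "uptake"] <= 0)
        stop(sprintf("medium '%s': carbon source has no uptake", m$name))
      class(m) <- "cmt_media"
      media[[m$name]] <- m
    }
  }

  role_index <- list()
  for (r in reactions) {
    for (role in normalize_role(gpr_roles(r$gpr)))
      role_index[[role]] <- c(role_index[[role]], r$id)
  }

  t <- structure(list(
    compounds = cpd, reactions = reactions, role_index = role_index,
    biomass = bm, pathway_rules = rules,
    pathway_meta = list(glucose_oxidation = unlist(pr$glucose_oxidation),
                        fermentation = unlist(pr$fermentation),
                        transporter_exempt = unlist(pr$transporter_exempt)),
    media = media, path = path), class = "cmt_template")
  t
}

#' Write a template back to disk in the packaged dialect
#'
#' Inverse of [load_template()]: \code{load(write(load(x)))} reproduces
#' \code{load(x)}.
#'
#' @param template a \code{cmt_template}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_template <- function(template, path) {
  dir.create(file.path(path, "media"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(template$compounds, file.path(path, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rx <- template$reactions
  rx <- rx[vapply(rx, function(r) r$kind != "biomass", TRUE)]
  df <- data.frame(
    id = vapply(rx, `[[`, "", "id"),
    name = vapply(rx, `[[`, "", "name"),
    equation = vapply(rx, function(r)
      format_equation(r$stoich, reversible = r$lower < 0), ""),
    lower = vapply(rx, `[[`, 0, "lower"),
    upper = vapply(rx, `[[`, 0, "upper"),
    gpr = vapply(rx, `[[`, "", "gpr_text"),
    pathways = vapply(rx, function(r) paste(r$pathway_tags, collapse = ";"), ""),
    etc_tag = vapply(rx, function(r) if (is.na(r$etc_tag)) "" else r$etc_tag, ""),
    proton_translocation = vapply(rx, `[[`, 0, "proton_translocation"),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(path, "reactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(template$biomass, file.path(path, "biomass.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pr <- c(list(comment = "regenerated by write_template()"),
          template$pathway_meta[c("glucose_oxidation", "fermentation")],
          list(transporter_exempt = template$pathway_meta$transporter_exempt,
               rules = template$pathway_rules))
  jsonlite::write_json(pr, file.path(path, "pathway_rules.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (m in template$media) {
    eb <- m$exchange_bounds
    out <- list(name = m$name, description = m$description,
                carbon_source = m$carbon_source,
                electron_acceptor = if (is.na(m$electron_acceptor)) NULL else m$electron_acceptor,
                exchange_bounds = stats::setNames(
                  lapply(seq_len(nrow(eb)), function(i) as.numeric(eb[i, ])),
                  rownames(eb)))
    jsonlite::write_json(out, file.path(path, "media", paste0(m$name, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

.coremetab_env <- new.env(parent = emptyenv())

#' The packaged core model template
#'
#' Loads (and caches) the curated template shipped with the package:
#' central carbon metabolism, fermentation pathways, and electron
#' transport chain variants with calibrated proton-translocation
#' stoichiometry, plus 12 pathway rules and 7 minimal media.
#'
#' @param reload force re-reading from disk.
#' @return a \code{cmt_template}.
#' @export
core_template <- function(reload = FALSE) {
  if (reload || is.null(.coremetab_env$template)) {
    path <- system.file("extdata", "template", package = "coremetab")
    if (!nzchar(path)) stop("packaged template not found; is coremetab installed?")
    .coremetab_env$template <- load_template(path)
  }
  .coremetab_env$template
}

#' Validate element and charge balance of a template
#'
#' Checks every internal reaction for element and charge conservation
#' (translocated protons are counted in their destination compartment
#' because both proton species appear explicitly in the stoichiometry).
#' Exchange, sink and biomass reactions are exempt.  The packaged
#' template yields an empty report.
#'
#' @param template a \code{cmt_template}.
#' @param tol numeric tolerance on imbalance.
#' @return data frame with columns \code{reaction}, \code{type}
#'   (\code{"element"} or \code{"charge"}), \code{what}, and
#'   \code{imbalance}; zero rows if fully balanced.
#' @export
validate_template <- function(template, tol = 1e-6) {
  cpd <- template$compounds
  fmap <- lapply(stats::setNames(cpd$formula, cpd$id), parse_formula)
  qmap <- stats::setNames(cpd$charge, cpd$id)
  out <- list()
  for (r in template$reactions) {
    if (r$kind != "internal") next
    st <- r$stoich
    elements <- numeric(0)
    for (i in seq_along(st)) {
      f <- fmap[[names(st)[i]]]
      for (el in names(f)) {
        elements[el] <- (if (el %in% names(elements)) elements[[el]] else 0) +
          st[[i]] * f[[el]]
      }
    }
    for (el in names(elements))
      if (abs(elements[[el]]) > tol)
        out[[length(out) + 1L]] <- data.frame(
          reaction = r$id, type = "element", what = el,
          imbalance = elements[[el]])
    q <- sum(st * qmap[names(st)])
    if (abs(q) > tol)
      out[[length(out) + 1L]] <- data.frame(
        reaction = r$id, type = "charge", what = "charge", imbalance = q)
  }
  if (!length(out))
    return(data.frame(reaction = character(0), type = character(0),
                      what = character(0), imbalance = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.cmt_template <- function(x, ...) {
  cat("Core model template\n")
  cat(sprintf("  compounds: %d   reactions: %d (incl. %d exchanges, biomass)\n",
              nrow(x$compounds), length(x$reactions),
              sum(vapply(x$reactions, function(r) r$kind == "exchange", TRUE))))
  cat(sprintf("  pathway rules: %d   media: %d (%s)\n",
              length(x$pathway_rules), length(x$media),
              paste(names(x$media), collapse = ", ")))
  invisible(x)
}

#' Names of the packaged media
#' @param template a \code{cmt_template}.
#' @return character vector of media names.
#' @export
list_media <- function(template = core_template()) names(template$media)

#' Fetch one medium from a template
#' @param template a \code{cmt_template}.
#' @param name medium name, e.g. \code{"glc_o2"}.
#' @return a \code{cmt_media} object.
#' @export
get_media <- function(template, name) {
  if (!name %in% names(template$media))
    stop(sprintf("unknown medium '%s' (available: %s)", name,
                 paste(names(template$media), collapse = ", ")))
  template$media[[name]]
}
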