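# Synthetic annotation sets with known ground truth, and the packaged
# organism-style fixtures.
#
# The generator works backwards through the template: for every step
# of every requested pathway it takes the step's first alternative
# reaction and emits all functional roles of that reaction's GPR, so
# that at zero noise the requested pathway vector is recovered exactly
# by determine_pathways().  Noise is independent per-role dropout;
# decoy roles match no template GPR leaf and therefore never change
# any downstream result.

.etc_reaction_sets <- list(
  aerobic  = c("NADH16", "CYTBO3", "SUCDi", "ATPS4r"),
  nitrate  = c("NADH16", "NAR", "NO3t2", "ATPS4r"),
  tmao     = c("NADH16", "TMAOR", "ATPS4r"),
  fumarate = c("NADH16", "FRD7", "ATPS4r"))

#' Specification of a synthetic genome
#'
#' @param genome_id identifier.
#' @param pathways_present character vector drawn from the template's
#'   12 pathway names.
#' @param etc_profile subset of \code{c("aerobic","nitrate","tmao","fumarate")}.
#' @param role_dropout_prob probability in \eqn{[0,1]} of dropping each
#'   emitted role independently.
#' @param decoy_role_count number of non-template decoy roles to add.
#' @param seed integer seed; fully determines the output.
#' @return a \code{genome_spec}.
#' @export
genome_spec <- function(genome_id, pathways_present = character(0),
                        etc_profile = character(0),
                        role_dropout_prob = 0, decoy_role_count = 0,
                        seed = 1L) {
  stopifnot(role_dropout_prob >= 0, role_dropout_prob <= 1)
  bad <- setdiff(etc_profile, names(.etc_reaction_sets))
  if (length(bad)) stop(sprintf("unknown ETC profile '%s'", bad[1]))
  structure(list(genome_id = genome_id,
                 pathways_present = pathways_present,
                 etc_profile = etc_profile,
                 role_dropout_prob = role_dropout_prob,
                 decoy_role_count = as.integer(decoy_role_count),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic annotation set from a genome specification
#'
#' @param spec a [genome_spec()].
#' @param template a \code{cmt_template}.
#' @return list with \code{annotations} (an \code{annotation_set}) and
#'   \code{truth} (the intended 12-pathway presence vector and ETC
#'   profile).
#' @export
generate_annotation_set <- function(spec, template = core_template()) {
  stopifnot(inherits(spec, "genome_spec"))
  bad <- setdiff(spec$pathways_present, names(template$pathway_rules))
  if (length(bad)) stop(sprintf("unknown pathway '%s'", bad[1]))

  rxn_ids <- character(0)
  for (pw in spec$pathways_present)
    for (step in template$pathway_rules[[pw]])
      rxn_ids <- c(rxn_ids, step[[1]])            # first alternative
  for (p in spec$etc_profile)
    rxn_ids <- c(rxn_ids, .etc_reaction_sets[[p]])
  rxn_ids <- unique(rxn_ids)

  roles <- sort(unique(unlist(lapply(template$reactions[rxn_ids],
                                     function(r) gpr_roles(r$gpr)))))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  if (spec$role_dropout_prob > 0 && length(roles))
    roles <- roles[stats::runif(length(roles)) >= spec$role_dropout_prob]
  decoys <- if (spec$decoy_role_count > 0)
    sprintf("hypothetical protein cluster %06d",
            sample.int(999999L, spec$decoy_role_count)) else character(0)

  truth <- stats::setNames(names(template$pathway_rules) %in% spec$pathways_present,
                           names(template$pathway_rules))
  list(annotations = annotation_set(spec$genome_id, c(roles, decoys),
                                    allow_empty = TRUE),
       truth = list(genome_id = spec$genome_id,
                    pathways_present = truth,
                    etc_profile = spec$etc_profile))
}

#' Packaged fixture names
#' @return character vector.
#' @export
list_fixtures <- function() {
  dir <- system.file("extdata", "fixtures", package = "coremetab")
  sort(sub("\\.tsv$", "", list.files(dir, pattern = "\\.tsv$")))
}

#' Load a packaged organism-style fixture
#'
#' The seven fixtures are curated role lists emulating well-studied
#' organism types (a facultative enterobacterium, a Gram-positive
#' nitrate respirer, a strictly fermentative clostridium, an
#' ED-pathway pseudomonad, a genome-reduced parasite, a strict aerobe
#' missing its gluconolactonase annotation, and an anaerobe carrying a
#' spurious oxidase annotation).  Each carries a manifest of expected
#' reactions, pathway vector, respiration class and ATP yields.
#'
#' @param name fixture name, see [list_fixtures()].
#' @return an \code{annotation_set}; the manifest is attached as
#'   \code{attr(x, "manifest")}.
#' @export
load_fixture <- function(name) {
  dir <- system.file("extdata", "fixtures", package = "coremetab")
  f <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(f))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(list_fixtures(), collapse = ", ")))
  df <- utils::read.delim(f, quote = "", stringsAsFactors = FALSE)
  man <- fixture_manifest(name)
  a <- annotation_set(name, df$role)
  attr(a, "manifest") <- man
  a
}

#' Manifest of a packaged fixture
#' @param name fixture name.
#' @return named list: expected reactions, pathway vector, respiration
#'   class, ATP yields per medium, fermentation capabilities.
#' @export
fixture_manifest <- function(name) {
  dir <- system.file("extdata", "fixtures", package = "coremetab")
  mans <- jsonlite::read_json(file.path(dir, "manifests.json"),
                              simplifyVector = TRUE)
  if (!name %in% names(mans))
    stop(sprintf("no manifest for fixture '%s'", name))
  mans[[name]]
}

#' Build the core model of a packaged fixture
#' @param name fixture name.
#' @param template template (defaults to the packaged one).
#' @return a \code{core_model}.
#' @export
fixture_model <- function(name, template = core_template())
  build_core_model(template, load_fixture(name))

#' Write annotation sets to the two-column TSV dialect
#' @param annotations an \code{annotation_set} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "annotation_set"))
    annotations <- list(annotations)
  df <- do.call(rbind, lapply(annotations, function(a)
    data.frame(genome_id = a$genome_id,
               role = if (length(a$roles)) a$roles else character(0))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
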