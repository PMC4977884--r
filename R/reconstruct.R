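# Per-genome core model reconstruction: evaluate the template's GPR
# rules against a genome's functional-role annotation set.

#' Construct an annotation set
#'
#' @param genome_id genome identifier.
#' @param roles character vector of functional-role strings.
#' @param taxon_label optional taxon name.
#' @param seq_key optional 16S-identity key used by deduplication.
#' @param quality optional numeric quality score.
#' @param allow_empty set \code{TRUE} to permit an empty role set
#'   (an explicitly "empty genome").
#' @return an \code{annotation_set} object.
#' @export
annotation_set <- function(genome_id, roles, taxon_label = NA_character_,
                           seq_key = NA_character_, quality = NA_real_,
                           allow_empty = FALSE) {
  roles <- unique(normalize_role(roles[nzchar(roles)]))
  if (!length(roles) && !allow_empty)
    stop(sprintf("annotation set '%s' has no roles; pass allow_empty = TRUE for an empty genome",
                 genome_id))
  structure(list(genome_id = genome_id, roles = roles,
                 taxon_label = taxon_label, seq_key = seq_key,
                 quality = quality),
            class = "annotation_set")
}

#' Read annotation sets from TSV or JSON
#'
#' The TSV dialect is two columns (\code{genome_id}, \code{role}), one
#' role per line, optionally with \code{taxon_label}, \code{seq_key} and
#' \code{quality} columns (constant within a genome).  JSON files hold a
#' list of objects with the same fields.
#'
#' @param path file path.
#' @return a named list of \code{annotation_set} objects.
#' @export
read_annotations <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    out <- lapply(recs, function(r)
      annotation_set(r$genome_id, unlist(r$roles),
                     taxon_label = r$taxon_label %||% NA_character_,
                     seq_key = r$seq_key %||% NA_character_,
                     quality = r$quality %||% NA_real_))
  } else {
    df <- utils::read.delim(path, quote = "", stringsAsFactors = FALSE)
    if (!all(c("genome_id", "role") %in% names(df)))
      stop(sprintf("parse error in %s: need columns genome_id, role", path))
    out <- lapply(split(df, df$genome_id), function(d)
      annotation_set(d$genome_id[1], d$role,
                     taxon_label = if ("taxon_label" %in% names(d)) d$taxon_label[1] else NA_character_,
                     seq_key = if ("seq_key" %in% names(d)) d$seq_key[1] else NA_character_,
                     quality = if ("quality" %in% names(d)) d$quality[1] else NA_real_))
  }
  stats::setNames(out, vapply(out, `[[`, "", "genome_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a core metabolic model for one genome
#'
#' A template reaction is included iff its GPR rule evaluates true over
#' the genome's roles, or it is marked spontaneous or universal.  Roles
#' not known to the template are ignored (reported via
#' \code{unknown_roles}), never fatal.
#'
#' @param template a \code{cmt_template}.
#' @param annotations an \code{annotation_set}.
#' @return a \code{core_model}: list with \code{genome_id},
#'   \code{reactions} (named character vector mapping reaction id to
#'   evidence tag \code{gene_associated} / \code{spontaneous} /
#'   \code{universal} / \code{gapfilled}), \code{unknown_roles} and
#'   \code{template}.
#' @export
build_core_model <- function(template, annotations) {
  stopifnot(inherits(template, "cmt_template"),
            inherits(annotations, "annotation_set"))
  roles <- annotations$roles
  evidence <- character(0)
  for (r in template$reactions) {
    tag <- switch(r$gpr$op,
                  universal = "universal",
                  spontaneous = "spontaneous",
                  if (eval_gpr(r$gpr, roles)) "gene_associated" else NA_character_)
    if (!is.na(tag)) evidence[r$id] <- tag
  }
  unknown <- setdiff(roles, names(template$role_index))
  structure(list(genome_id = annotations$genome_id,
                 reactions = evidence,
                 unknown_roles = unknown,
                 seq_key = annotations$seq_key,
                 quality = annotations$quality,
                 taxon_label = annotations$taxon_label,
                 template = template),
            class = "core_model")
}

#' Reaction counts of a core model
#'
#' @param model a \code{core_model}.
#' @return named numeric vector: \code{total}, \code{gene_associated},
#'   \code{spontaneous}, \code{universal}, \code{gapfilled}.
#' @export
model_stats <- function(model) {
  ev <- model$reactions
  c(total = length(ev),
    gene_associated = sum(ev == "gene_associated"),
    spontaneous = sum(ev == "spontaneous"),
    universal = sum(ev == "universal"),
    gapfilled = sum(ev == "gapfilled"))
}

#' @export
print.core_model <- function(x, ...) {
  st <- model_stats(x)
  cat(sprintf("Core metabolic model of '%s'\n", x$genome_id))
  cat(sprintf("  reactions: %d (gene-associated %d, spontaneous %d, universal %d, gapfilled %d)\n",
              st["total"], st["gene_associated"], st["spontaneous"],
              st["universal"], st["gapfilled"]))
  if (length(x$unknown_roles))
    cat(sprintf("  %d annotation roles not in template (ignored)\n",
                length(x$unknown_roles)))
  invisible(x)
}

#' Add reactions to a model with a given evidence tag
#' @param model a \code{core_model}.
#' @param reaction_ids template reaction ids to add.
#' @param evidence evidence tag, default \code{"gapfilled"}.
#' @return the augmented \code{core_model}.
#' @export
add_reactions <- function(model, reaction_ids, evidence = "gapfilled") {
  unknown <- setdiff(reaction_ids, names(model$template$reactions))
  if (length(unknown))
    stop(sprintf("unknown template reaction '%s'", unknown[1]))
  new_ids <- setdiff(reaction_ids, names(model$reactions))
  model$reactions[new_ids] <- evidence
  model
}
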