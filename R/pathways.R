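# Boolean pathway-presence rules, respiration classification, and
# FBA-based fermentation-product capability.
#
# A pathway is called present iff every step of its rule lists at
# least one reaction present in the model; alternative reactions
# within a step are allowed, but no step may be skipped.

.pathway_names <- function(template)
  c(template$pathway_meta$glucose_oxidation, template$pathway_meta$fermentation)

#' Evaluate pathway-presence rules for a model
#'
#' @param model a \code{core_model}.
#' @param rules optional rule set (defaults to the model template's 12
#'   packaged rules).
#' @param exempt_transporters treat the template's diffusion-exemptible
#'   transporter steps as satisfied even when the transporter gene is
#'   absent (default \code{FALSE}).
#' @return a \code{pathway_profile}: list with \code{genome_id},
#'   \code{presence} (named logical over the 12 pathways),
#'   \code{respiration}, and \code{model_size}.
#' @export
determine_pathways <- function(model, rules = NULL, exempt_transporters = FALSE) {
  template <- model$template
  if (is.null(rules)) rules <- template$pathway_rules
  have <- names(model$reactions)
  if (exempt_transporters)
    have <- union(have, template$pathway_meta$transporter_exempt)
  presence <- vapply(rules, function(steps)
    all(vapply(steps, function(step) any(step %in% have), TRUE)), TRUE)
  structure(list(genome_id = model$genome_id,
                 presence = presence,
                 respiration = classify_respiration(model),
                 model_size = length(model$reactions),
                 seq_key = model$seq_key,
                 quality = model$quality),
            class = "pathway_profile")
}

#' Classify respiration type of a model
#'
#' An aerobic chain requires at least one aerobic terminal oxidase, at
#' least one respiratory dehydrogenase and the ATP synthase; an
#' anaerobic chain is analogous with an anaerobic terminal reductase.
#' Both chains together give \code{"facultative"}; neither gives
#' \code{"none"} (fermentation-only energy metabolism).
#'
#' @param model a \code{core_model}.
#' @return one of \code{"aerobic"}, \code{"anaerobic"},
#'   \code{"facultative"}, \code{"none"}.
#' @export
classify_respiration <- function(model) {
  template <- model$template
  tags <- vapply(template$reactions[names(model$reactions)],
                 function(r) if (is.na(r$etc_tag)) "" else r$etc_tag, "")
  has <- function(tag) any(tags == tag)
  dehydro <- has("dehydrogenase"); synthase <- has("atp_synthase")
  aer <- has("aerobic_terminal") && dehydro && synthase
  ana <- has("anaerobic_terminal") && dehydro && synthase
  if (aer && ana) "facultative" else if (aer) "aerobic" else
    if (ana) "anaerobic" else "none"
}

# fermentation product -> exchange reaction of the template
.fermentation_products <- c(
  lactate = "EX_lac__D_e", acetate = "EX_ac_e", formate = "EX_for_e",
  ethanol = "EX_etoh_e", butanediol = "EX_btd_RR_e", butyrate = "EX_but_e",
  butanol = "EX_btoh_e", acetone = "EX_act_e")

#' Fermentation-product capability by FBA
#'
#' Under an acceptor-free medium, maximises the secretion flux of each
#' of the eight fermentation end products in turn; a product is
#' "capable" iff its maximal secretion exceeds \code{eps} under full
#' redox balance.
#'
#' @param model a \code{core_model}.
#' @param media an acceptor-free \code{cmt_media} (e.g. \code{glc_none}).
#' @param eps capability threshold.
#' @return named logical vector over the eight products.
#' @export
fermentation_capability <- function(model, media, eps = 1e-6) {
  if (!is.na(media$electron_acceptor))
    stop("fermentation_capability() requires an acceptor-free medium")
  lp <- build_lp(model, media, "atp_hydrolysis")
  out <- stats::setNames(logical(length(.fermentation_products)),
                         names(.fermentation_products))
  for (p in names(.fermentation_products)) {
    ex <- .fermentation_products[[p]]
    if (!ex %in% lp$reaction_ids) { out[p] <- FALSE; next }
    obj <- stats::setNames(numeric(length(lp$obj)), lp$reaction_ids)
    obj[ex] <- 1
    sol <- solve_lp(obj, lp$S, rep(0, nrow(lp$S)), lp$lower, lp$upper)
    out[p] <- sol$status == "optimal" && sol$objval > eps
  }
  out
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat(sprintf("Pathway profile of '%s' (%d reactions, respiration: %s)\n",
              x$genome_id, x$model_size, x$respiration))
  on <- names(x$presence)[x$presence]
  cat("  present:", if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Tabulate pathway profiles of many models
#'
#' @param models list of \code{core_model}s.
#' @param ... passed to [determine_pathways()].
#' @return data frame with one row per genome: \code{genome_id}, one
#'   logical column per pathway, \code{respiration}, \code{model_size},
#'   \code{seq_key}, \code{quality}.
#' @export
pathway_profiles <- function(models, ...) {
  rows <- lapply(models, function(m) {
    p <- determine_pathways(m, ...)
    cbind(data.frame(genome_id = p$genome_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(p$presence)),
          data.frame(respiration = p$respiration,
                     model_size = p$model_size,
                     seq_key = if (is.null(p$seq_key)) NA_character_ else p$seq_key,
                     quality = if (is.null(p$quality)) NA_real_ else p$quality,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
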