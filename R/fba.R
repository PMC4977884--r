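# Flux balance analysis on core models: assemble the stoichiometric
# linear program for a model under a medium and maximise an objective
# (ATP hydrolysis, biomass, or a single-compound drain).
#
# Conventions: exchange reactions are written "x_e <=>" with positive
# flux = secretion, so a medium's maximum uptake u becomes a lower
# bound of -u.  Yields are reported per mol of carbon source taken up.

#' Assemble the FBA linear program
#'
#' Builds the steady-state system \eqn{S v = 0} over all compounds
#' touched by the model's reactions, with template flux bounds
#' overridden by the medium's exchange bounds (exchange reactions
#' only).
#'
#' @param model a \code{core_model}.
#' @param media a \code{cmt_media} (see [get_media()]).
#' @param objective \code{"atp_hydrolysis"}, \code{"biomass"}, or
#'   \code{drain("cpd_id")} for a single-compound sink objective.
#' @return an \code{lp_system}: list with \code{S}, \code{lower},
#'   \code{upper}, \code{obj}, \code{reaction_ids}, \code{compound_ids},
#'   \code{carbon_exchange}, \code{media_name}.
#' @export
build_lp <- function(model, media, objective = "atp_hydrolysis") {
  stopifnot(inherits(model, "core_model"))
  template <- model$template
  rxns <- template$reactions[names(model$reactions)]

  drain_cpd <- NULL
  if (inherits(objective, "fba_drain")) {
    drain_cpd <- objective$compound
    objective <- "drain"
  }

  # sparse-by-construction dense S
  cpds <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  if (!is.null(drain_cpd) && !drain_cpd %in% cpds)
    stop(sprintf("objective compound '%s' absent from model", drain_cpd))
  nr <- length(rxns) + as.integer(!is.null(drain_cpd))
  S <- matrix(0, length(cpds), nr,
              dimnames = list(cpds, c(names(rxns),
                                      if (!is.null(drain_cpd))
                                        paste0("SINK_", drain_cpd))))
  lower <- numeric(nr); upper <- numeric(nr)
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    S[names(r$stoich), i] <- r$stoich
    lower[i] <- r$lower; upper[i] <- r$upper
  }
  names(lower) <- names(upper) <- colnames(S)

  # media bounds override template bounds on exchange reactions only
  eb <- media$exchange_bounds
  for (i in seq_along(rxns)) {
    r <- rxns[[i]]
    if (r$kind != "exchange") next
    cpd <- names(r$stoich)[1]
    if (cpd %in% rownames(eb)) {
      lower[i] <- -eb[cpd, "uptake"]
      upper[i] <- eb[cpd, "secretion"]
    } else {
      lower[i] <- 0                   # secretion-only by default
    }
  }

  obj <- numeric(nr); names(obj) <- colnames(S)
  if (identical(objective, "atp_hydrolysis")) {
    if (!"ATPM" %in% colnames(S))
      stop("model lacks the ATP hydrolysis reaction 'ATPM'")
    obj["ATPM"] <- 1
  } else if (identical(objective, "biomass")) {
    bio <- model$template$biomass$id
    if (!bio %in% colnames(S))
      stop(sprintf("model lacks the biomass reaction '%s'", bio))
    obj[bio] <- 1
  } else if (identical(objective, "drain")) {
    j <- paste0("SINK_", drain_cpd)
    S[drain_cpd, j] <- -1
    # CoA-thioester precursors return the free carrier (as in the
    # biomass reaction); otherwise the drain would demand net CoA
    # synthesis, which the core network rightly cannot do
    carrier <- model$template$biomass$coa_release[[drain_cpd]]
    if (!is.null(carrier) && carrier %in% rownames(S))
      S[carrier, j] <- 1
    lower[j] <- 0; upper[j] <- 1000
    obj[j] <- 1
  } else stop("objective must be 'atp_hydrolysis', 'biomass', or drain(<compound>)")

  carbon_ex <- paste0("EX_", media$carbon_source)
  structure(list(S = S, lower = lower, upper = upper, obj = obj,
                 reaction_ids = colnames(S), compound_ids = cpds,
                 carbon_exchange = carbon_ex, media_name = media$name,
                 objective = objective,
                 genome_id = model$genome_id),
            class = "lp_system")
}

#' Drain objective marker
#'
#' Use as \code{build_lp(m, med, drain("oaa_c"))} to maximise a sink
#' flux for one compound (biomass-precursor producibility testing).
#'
#' @param compound compound id.
#' @return an \code{fba_drain} marker object.
#' @export
drain <- function(compound) structure(list(compound = compound), class = "fba_drain")

#' Maximise an assembled linear program
#'
#' Solves \eqn{\max c^T v} s.t. \eqn{S v = 0}, \eqn{l \le v \le u} and
#' normalises the optimum by the carbon-source uptake flux.
#'
#' @param lp an \code{lp_system} from [build_lp()].
#' @param tol LP tolerance.
#' @return an \code{fba_result}: \code{status}, \code{objective_value},
#'   \code{fluxes} (named), \code{yield} (objective per mol carbon
#'   taken up; \code{NA} when carbon uptake is below tolerance).
#' @export
maximize <- function(lp, tol = 1e-9) {
  stopifnot(inherits(lp, "lp_system"))
  sol <- solve_lp(lp$obj, lp$S, rep(0, nrow(lp$S)), lp$lower, lp$upper,
                  maximize = TRUE, tol = tol)
  fluxes <- stats::setNames(sol$x, lp$reaction_ids)
  yield <- NA_real_
  if (sol$status == "optimal") {
    uptake <- if (lp$carbon_exchange %in% names(fluxes))
      -fluxes[[lp$carbon_exchange]] else 0
    if (is.finite(uptake) && uptake > 1e-6)
      yield <- sol$objval / uptake
  }
  structure(list(status = sol$status,
                 objective_value = sol$objval,
                 fluxes = fluxes, yield = yield,
                 media_name = lp$media_name,
                 objective = lp$objective,
                 genome_id = lp$genome_id),
            class = "fba_result")
}

#' One-call FBA
#'
#' Convenience wrapper: \code{maximize(build_lp(model, media, objective))}.
#'
#' @inheritParams build_lp
#' @return an \code{fba_result}.
#' @export
fba <- function(model, media, objective = "atp_hydrolysis")
  maximize(build_lp(model, media, objective))

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("FBA result (%s, medium %s): %s\n",
              if (is.character(x$objective)) x$objective else "drain",
              x$media_name, x$status))
  if (x$status == "optimal")
    cat(sprintf("  objective = %.6g   yield = %s mol/mol carbon\n",
                x$objective_value,
                ifelse(is.na(x$yield), "NA", sprintf("%.6g", x$yield))))
  invisible(x)
}

#' ATP yield matrix over models and media
#'
#' Runs max-ATP-hydrolysis FBA for every (model, medium) pair.  Failed
#' or carbon-free solves are reported as yield 0 and flagged.
#'
#' @param models list of \code{core_model}s.
#' @param media list of \code{cmt_media} (or names resolved against the
#'   first model's template).
#' @return data frame with columns \code{genome_id}, \code{media},
#'   \code{status}, \code{atp_yield}, \code{flagged}.
#' @export
atp_yield_matrix <- function(models, media) {
  if (!length(models))
    return(data.frame(genome_id = character(0), media = character(0),
                      status = character(0), atp_yield = numeric(0),
                      flagged = logical(0)))
  if (is.character(media))
    media <- lapply(media, get_media, template = models[[1]]$template)
  rows <- list()
  for (m in models) for (med in media) {
    res <- fba(m, med, "atp_hydrolysis")
    ok <- res$status == "optimal" && !is.na(res$yield)
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = m$genome_id, media = med$name, status = res$status,
      atp_yield = if (ok) res$yield else 0,
      flagged = !ok)
  }
  do.call(rbind, rows)
}

#' Biomass-precursor producibility
#'
#' For each of the 12 biomass precursors, tests whether a sink (drain)
#' flux above the producibility threshold can be carried under the
#' medium.
#'
#' @param model a \code{core_model}.
#' @param media a \code{cmt_media}.
#' @param eps producibility threshold (default \code{1e-6}).
#' @return named logical vector over the 12 precursor compounds.
#' @export
precursor_producibility <- function(model, media, eps = 1e-6) {
  prec <- vapply(model$template$biomass$precursors, `[[`, "", "compound")
  out <- stats::setNames(logical(length(prec)), prec)
  for (p in prec) {
    res <- tryCatch(fba(model, media, drain(p)),
                    error = function(e) NULL)
    out[p] <- !is.null(res) && res$status == "optimal" &&
      res$objective_value > eps
  }
  out
}
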