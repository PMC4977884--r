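# Gapfilling: find a cardinality-minimal set of template reactions
# whose addition lets a model carry objective (biomass) flux on a
# medium.
#
# Strategy: (1) prune the candidate universe to reactions that can
# carry flux at all when every candidate is open and the objective is
# forced (a sound reduction: a reaction blocked in the fully augmented
# network can never help any subset); (2) prove the minimum cardinality
# with a branch-and-bound search over the 0/1 indicator relaxation;
# (3) canonicalise ties by exhaustive lexicographic enumeration at the
# proven cardinality when that enumeration is affordable.

.lp_for_reactions <- function(template, rxn_ids, media, objective = "biomass") {
  fake <- structure(list(genome_id = "gapfill", template = template,
                         reactions = stats::setNames(
                           rep("gene_associated", length(rxn_ids)), rxn_ids)),
                    class = "core_model")
  build_lp(fake, media, objective)
}

.objective_feasible <- function(template, rxn_ids, media, objective, eps) {
  lp <- .lp_for_reactions(template, rxn_ids, media, objective)
  sol <- solve_lp(lp$obj, lp$S, rep(0, nrow(lp$S)), lp$lower, lp$upper)
  sol$status == "optimal" && sol$objval >= eps
}

# max / min achievable flux of column `j` with objective flux forced >= eps
.flux_range <- function(lp, j, eps) {
  lower <- lp$lower; obj_ix <- which(lp$obj != 0)
  lower[obj_ix] <- pmax(lower[obj_ix], eps)
  probe <- stats::setNames(numeric(length(lp$obj)), lp$reaction_ids)
  probe[j] <- 1
  up <- solve_lp(probe, lp$S, rep(0, nrow(lp$S)), lower, lp$upper)
  dn <- solve_lp(probe, lp$S, rep(0, nrow(lp$S)), lower, lp$upper, maximize = FALSE)
  c(if (up$status == "optimal") up$objval else 0,
    if (dn$status == "optimal") dn$objval else 0)
}

# branch and bound on the indicator MILP; returns list(size, sets_found)
.gapfill_bnb <- function(template, model_ids, cand, media, objective, eps) {
  rxn_ids <- c(model_ids, cand)
  lp <- .lp_for_reactions(template, rxn_ids, media, objective)
  nrx <- length(lp$reaction_ids); nc <- length(cand)
  cand_ix <- match(cand, lp$reaction_ids)
  m0 <- nrow(lp$S)
  # columns: v (nrx), y (nc), s_up (nc), s_lo (nc)
  ncol_tot <- nrx + 3L * nc
  A <- matrix(0, m0 + 2L * nc, ncol_tot)
  A[seq_len(m0), seq_len(nrx)] <- lp$S
  lb <- c(lp$lower, rep(0, 3L * nc))
  ub <- c(lp$upper, rep(1, nc), rep(2001, 2L * nc))
  obj_ix <- which(lp$obj != 0)
  lb[obj_ix] <- pmax(lb[obj_ix], eps)       # force objective flux
  for (k in seq_len(nc)) {
    j <- cand_ix[k]
    # v_j - u_j y_k + s_up = 0  (v_j <= u_j y_k)
    A[m0 + 2L * k - 1L, j] <- 1
    A[m0 + 2L * k - 1L, nrx + k] <- -lp$upper[j]
    A[m0 + 2L * k - 1L, nrx + nc + k] <- 1
    # v_j - l_j y_k - s_lo = 0  (v_j >= l_j y_k)
    A[m0 + 2L * k, j] <- 1
    A[m0 + 2L * k, nrx + k] <- -lp$lower[j]
    A[m0 + 2L * k, nrx + 2L * nc + k] <- -1
    # candidate itself must be allowed its full template range
    lb[j] <- min(lp$lower[j], 0); ub[j] <- max(lp$upper[j], 0)
  }
  cost <- c(rep(0, nrx), rep(1, nc), rep(0, 2L * nc))
  b <- rep(0, nrow(A))
  yix <- nrx + seq_len(nc)
  int_tol <- 1e-5

  best <- nc + 1L; best_y <- NULL
  nodes <- list(list(fix = rep(NA, nc)))
  while (length(nodes)) {
    node <- nodes[[length(nodes)]]; nodes[[length(nodes)]] <- NULL
    l2 <- lb; u2 <- ub
    l2[yix[!is.na(node$fix) & node$fix == 1]] <- 1
    u2[yix[!is.na(node$fix) & node$fix == 0]] <- 0
    sol <- solve_lp(cost, A, b, l2, u2, maximize = FALSE)
    if (sol$status != "optimal") next
    lbound <- ceiling(sol$objval - 1e-6)
    if (lbound >= best) next
    yv <- sol$x[yix]
    frac <- abs(yv - round(yv)) > int_tol
    if (!any(frac)) {
      size <- as.integer(round(sum(yv)))
      if (size < best) { best <- size; best_y <- round(yv) }
      next
    }
    bvar <- which(frac)[which.max(pmin(yv[frac], 1 - yv[frac]))]
    n0 <- node; n0$fix[bvar] <- 0
    n1 <- node; n1$fix[bvar] <- 1
    nodes <- c(nodes, list(n0), list(n1))   # y=1 explored first (LIFO)
  }
  if (is.null(best_y)) return(NULL)
  list(size = best, set = cand[best_y > 0.5])
}

#' Gapfill a core model
#'
#' Finds a cardinality-minimal set of template reactions absent from
#' the model whose addition permits objective flux of at least
#' \code{eps} under the medium.  Ties between minimal sets are broken
#' lexicographically by reaction id.  If the model already carries the
#' flux, the empty solution is returned; if no addition set can help,
#' a structured "unfillable" result is returned rather than an error.
#'
#' @param model a \code{core_model}.
#' @param media a \code{cmt_media}; the classical setting is glucose +
#'   oxygen (\code{glc_o2}).
#' @param objective \code{"biomass"} (default) or
#'   \code{"atp_hydrolysis"}.
#' @param eps minimum objective flux regarded as growth.
#' @param max_size largest addition-set size searched.
#' @param verify_budget maximum number of subset LPs spent on the
#'   exhaustive lexicographic enumeration.
#' @return a \code{gapfill_solution}: list with \code{added_reaction_ids},
#'   \code{objective_flux_after}, \code{minimal} (\code{TRUE} when
#'   verified by exhaustive subset check, otherwise \code{NA} with the
#'   branch-and-bound optimum), \code{fillable}, \code{candidates},
#'   and \code{model} (the augmented model, additions tagged
#'   \code{gapfilled}).
#' @export
gapfill <- function(model, media, objective = "biomass", eps = 1e-6,
                    max_size = 6, verify_budget = 20000) {
  template <- model$template
  model_ids <- names(model$reactions)
  test_ids <- function(extra)
    .objective_feasible(template, c(model_ids, extra), media, objective, eps)

  if (test_ids(character(0)))
    return(structure(list(added_reaction_ids = character(0),
                          objective_flux_after = .objective_value(
                            template, model_ids, media, objective),
                          minimal = TRUE, fillable = TRUE,
                          candidates = character(0), model = model),
                     class = "gapfill_solution"))

  cand_all <- sort(setdiff(names(template$reactions), model_ids))
  cand_all <- cand_all[vapply(template$reactions[cand_all],
                              function(r) r$kind != "biomass", TRUE)]
  if (!test_ids(cand_all))
    return(structure(list(added_reaction_ids = character(0),
                          objective_flux_after = 0,
                          minimal = NA, fillable = FALSE,
                          candidates = cand_all, model = model),
                     class = "gapfill_solution"))

  # prune: keep candidates that can carry flux in the fully augmented
  # network under forced objective flux (skipped when the universe is
  # already small enough to enumerate directly)
  if (length(cand_all) > 25L) {
    lp_full <- .lp_for_reactions(template, c(model_ids, cand_all), media, objective)
    keep <- vapply(cand_all, function(cid) {
      rng <- .flux_range(lp_full, cid, eps)
      max(abs(rng)) > 1e-9
    }, TRUE)
    pool <- cand_all[keep]
  } else pool <- cand_all

  # exact search: iterative deepening over lexicographic subsets.
  # Exhaustive by construction, so the result is cardinality-minimal at
  # threshold eps with lexicographic tie-breaks.
  chosen <- NULL; minimal <- NA; spent <- 0
  for (k in seq_len(min(length(pool), max_size))) {
    ncomb <- choose(length(pool), k)
    if (spent + ncomb > verify_budget) break
    spent <- spent + ncomb
    for (sub in utils::combn(pool, k, simplify = FALSE)) {
      if (test_ids(sub)) { chosen <- sub; break }
    }
    if (!is.null(chosen)) { minimal <- TRUE; break }
  }

  if (is.null(chosen)) {
    # large solution: prove the minimum with branch-and-bound on the
    # indicator MILP.  The growth-forcing level is scaled up from eps
    # (weak eps-level forcing makes the relaxation degenerate); the
    # minimality flag stays NA because the exhaustive check is beyond
    # budget here.
    max_full <- .objective_value(template, c(model_ids, cand_all), media, objective)
    force_level <- max(eps, 0.01 * max_full)
    bnb <- .gapfill_bnb(template, model_ids, pool, media, objective, force_level)
    if (is.null(bnb))
      stop("internal error: augmented network feasible but search failed")
    chosen <- sort(bnb$set)
    # canonical lexicographic solution at the proven cardinality
    k <- bnb$size
    if (k >= 1 && choose(length(pool), k) <= verify_budget) {
      for (sub in utils::combn(pool, k, simplify = FALSE)) {
        if (test_ids(sub)) { chosen <- sub; break }
      }
    }
  }

  aug <- add_reactions(model, chosen, evidence = "gapfilled")
  structure(list(added_reaction_ids = chosen,
                 objective_flux_after = .objective_value(
                   template, c(model_ids, chosen), media, objective),
                 minimal = minimal, fillable = TRUE,
                 candidates = pool, model = aug),
            class = "gapfill_solution")
}

.objective_value <- function(template, rxn_ids, media, objective) {
  lp <- .lp_for_reactions(template, rxn_ids, media, objective)
  sol <- solve_lp(lp$obj, lp$S, rep(0, nrow(lp$S)), lp$lower, lp$upper)
  if (sol$status == "optimal") sol$objval else 0
}

#' @export
print.gapfill_solution <- function(x, ...) {
  if (!x$fillable) {
    cat("Gapfill: unfillable (no template addition restores the objective)\n")
  } else if (!length(x$added_reaction_ids)) {
    cat("Gapfill: model already feasible, nothing added\n")
  } else {
    cat(sprintf("Gapfill: %d reaction(s) added [%s], objective flux %.4g, minimal: %s\n",
                length(x$added_reaction_ids),
                paste(x$added_reaction_ids, collapse = ", "),
                x$objective_flux_after, format(x$minimal)))
  }
  invisible(x)
}

#' Brute-force minimum gapfill size (test oracle)
#'
#' Exhaustively enumerates addition subsets by increasing size over the
#' full (unpruned) candidate universe and returns the first feasible
#' subset in lexicographic order.  Exponential; intended as an
#' independent oracle on small instances only.
#'
#' @inheritParams gapfill
#' @param max_size largest subset size to try.
#' @return list with \code{size} and \code{set}, or \code{NULL} if no
#'   subset within \code{max_size} works.
#' @export
gapfill_bruteforce <- function(model, media, objective = "biomass",
                               eps = 1e-6, max_size = 3) {
  template <- model$template
  model_ids <- names(model$reactions)
  cand <- sort(setdiff(names(template$reactions), model_ids))
  cand <- cand[vapply(template$reactions[cand],
                      function(r) r$kind != "biomass", TRUE)]
  if (.objective_feasible(template, model_ids, media, objective, eps))
    return(list(size = 0L, set = character(0)))
  for (k in seq_len(max_size)) {
    for (sub in utils::combn(cand, k, simplify = FALSE))
      if (.objective_feasible(template, c(model_ids, sub), media, objective, eps))
        return(list(size = k, set = sub))
  }
  NULL
}

#' Alternate-carbon-source rescue of glucose-negative models
#'
#' For a model that fails to produce biomass on glucose, tests (without
#' gapfilling) whether swapping the carbon source for glycerol,
#' lactate, succinate or ribose restores biomass flux.
#'
#' @param model a \code{core_model}.
#' @param template its template (defaults to \code{model$template}).
#' @param base_media medium whose acceptor/mineral composition is kept
#'   (default the glucose+oxygen medium).
#' @param eps growth threshold.
#' @return named logical vector over the four alternate sources.
#' @export
alternate_carbon_rescue <- function(model, template = model$template,
                                    base_media = get_media(template, "glc_o2"),
                                    eps = 1e-6) {
  res0 <- fba(model, base_media, "biomass")
  if (res0$status == "optimal" && res0$objective_value > eps)
    stop("model grows on glucose; alternate-carbon rescue is only defined for glucose-negative models")
  sources <- c(glycerol = "glyc_e", lactate = "lac__D_e",
               succinate = "succ_e", ribose = "rib__D_e")
  out <- stats::setNames(logical(length(sources)), names(sources))
  for (s in names(sources)) {
    med <- swap_carbon_source(base_media, sources[[s]])
    r <- tryCatch(fba(model, med, "biomass"), error = function(e) NULL)
    out[s] <- !is.null(r) && r$status == "optimal" && r$objective_value > eps
  }
  out
}

#' Derive a medium with a different carbon source
#'
#' Copies a medium, closes the old carbon source's uptake and opens the
#' new one at the same maximum uptake rate.
#'
#' @param media a \code{cmt_media}.
#' @param carbon_source new carbon source compound id (extracellular).
#' @param uptake maximum uptake; defaults to the old carbon uptake.
#' @return a \code{cmt_media}.
#' @export
swap_carbon_source <- function(media, carbon_source, uptake = NULL) {
  eb <- media$exchange_bounds
  old <- media$carbon_source
  if (is.null(uptake)) uptake <- eb[old, "uptake"]
  eb <- eb[rownames(eb) != old, , drop = FALSE]
  eb <- rbind(eb, matrix(c(uptake, 0), 1, 2,
                         dimnames = list(carbon_source, colnames(eb))))
  media$exchange_bounds <- eb
  media$carbon_source <- carbon_source
  media$name <- paste0(media$name, "_as_", sub("_e$", "", carbon_source))
  media
}
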