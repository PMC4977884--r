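# Pairwise co-occurrence of pathway presence/absence across genome
# collections: 16S-key deduplication, model-size stratification, and
# the phi (= Pearson on binaries) correlation with t-based p-values.

.presence_columns <- function(profiles) {
  names(profiles)[vapply(profiles, is.logical, TRUE)]
}

#' Deduplicate profiles by 16S sequence key
#'
#' Keeps one representative per distinct \code{seq_key}: the profile
#' with the highest \code{quality}, ties broken by \code{genome_id}
#' order.  Profiles without a key are retained untouched.
#'
#' @param profiles data frame from [pathway_profiles()].
#' @return filtered data frame.
#' @export
deduplicate <- function(profiles) {
  if (!nrow(profiles)) return(profiles)
  has_key <- !is.na(profiles$seq_key) & nzchar(profiles$seq_key)
  keyed <- profiles[has_key, , drop = FALSE]
  if (nrow(keyed)) {
    q <- keyed$quality; q[is.na(q)] <- -Inf
    ord <- order(keyed$seq_key, -q, keyed$genome_id)
    keyed <- keyed[ord, , drop = FALSE]
    keyed <- keyed[!duplicated(keyed$seq_key), , drop = FALSE]
  }
  out <- rbind(profiles[!has_key, , drop = FALSE], keyed)
  out[order(match(out$genome_id, profiles$genome_id)), , drop = FALSE]
}

#' Assign model-size classes
#'
#' Thresholds follow the corpus stratification: small (< 93 reactions),
#' medium (93 to 133 inclusive), large (> 133).
#'
#' @param profiles data frame with a \code{model_size} column (or a
#'   numeric vector of sizes).
#' @return factor with levels \code{small}, \code{medium}, \code{large}.
#' @export
assign_size_classes <- function(profiles) {
  sizes <- if (is.data.frame(profiles)) profiles$model_size else profiles
  cut(sizes, breaks = c(-Inf, 92.5, 133.5, Inf),
      labels = c("small", "medium", "large"))
}

#' Pairwise pathway co-occurrence
#'
#' Computes, for every ordered pathway pair, the Pearson correlation of
#' the 0/1 presence vectors (identical to the phi coefficient of the
#' 2x2 contingency table) with the t-statistic p-value
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' Pairs involving a zero-variance column are flagged undefined rather
#' than propagating NaN.
#'
#' @param profiles data frame of profiles (logical pathway columns).
#' @param size_class \code{"all"} or one of \code{"small"},
#'   \code{"medium"}, \code{"large"} (filters on \code{model_size}).
#' @param alpha significance level (default 0.05).
#' @param holm apply Holm correction to the p-values (default
#'   \code{FALSE}, matching raw-p reporting).
#' @return a \code{cooccurrence_result}: list with \code{pairs} (long
#'   data frame: pathway_a, pathway_b, r, p, n, significant,
#'   undefined), \code{r_matrix}, \code{size_class}, \code{n}.
#' @export
pairwise_cooccurrence <- function(profiles, size_class = "all",
                                  alpha = 0.05, holm = FALSE) {
  if (size_class != "all") {
    cls <- assign_size_classes(profiles)
    profiles <- profiles[!is.na(cls) & cls == size_class, , drop = FALSE]
  }
  pcols <- .presence_columns(profiles)
  n <- nrow(profiles)
  if (n < 3) stop("need at least 3 profiles for co-occurrence analysis")
  X <- as.matrix(as.data.frame(lapply(profiles[pcols], as.numeric)))
  npw <- length(pcols)
  R <- matrix(NA_real_, npw, npw, dimnames = list(pcols, pcols))
  diag(R) <- 1
  rows <- list()
  for (i in seq_len(npw - 1L)) for (j in (i + 1L):npw) {
    xi <- X[, i]; xj <- X[, j]
    undef <- stats::var(xi) == 0 || stats::var(xj) == 0
    r <- if (undef) NA_real_ else stats::cor(xi, xj)
    p <- NA_real_
    if (!undef) {
      if (abs(r) >= 1 - 1e-12) {
        p <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
    R[i, j] <- R[j, i] <- r
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_a = pcols[i], pathway_b = pcols[j],
      r = r, p = p, n = n, undefined = undef)
  }
  pairs <- do.call(rbind, rows)
  if (holm) pairs$p <- stats::p.adjust(pairs$p, method = "holm")
  pairs$significant <- !pairs$undefined & !is.na(pairs$p) & pairs$p < alpha
  structure(list(pairs = pairs, r_matrix = R,
                 size_class = size_class, n = n, alpha = alpha),
            class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  cat(sprintf("Pathway co-occurrence (%s class, n = %d genomes): %d pairs, %d significant at alpha = %g\n",
              x$size_class, x$n, nrow(x$pairs), sum(x$pairs$significant),
              x$alpha))
  invisible(x)
}

#' Fraction of significant co-occurrences that are positive
#'
#' @param results a \code{cooccurrence_result} or list of them (e.g.
#'   one per size class).
#' @return data frame with columns \code{size_class},
#'   \code{n_significant}, \code{fraction_positive}.
#' @export
summarize_cooccurrence <- function(results) {
  if (inherits(results, "cooccurrence_result")) results <- list(results)
  do.call(rbind, lapply(results, function(res) {
    sig <- res$pairs[res$pairs$significant, , drop = FALSE]
    data.frame(size_class = res$size_class,
               n_significant = nrow(sig),
               fraction_positive = if (nrow(sig)) mean(sig$r > 0) else NA_real_)
  }))
}

#' Consistency of a pair across size classes
#'
#' A pair is "consistent" when its sign and significance are identical
#' in the small, medium and large classes.
#'
#' @param profiles profile data frame.
#' @param ... passed to [pairwise_cooccurrence()].
#' @return data frame of pairs with a \code{consistent} flag.
#' @export
cooccurrence_consistency <- function(profiles, ...) {
  classes <- c("small", "medium", "large")
  res <- lapply(classes, function(cl)
    pairwise_cooccurrence(profiles, size_class = cl, ...)$pairs)
  base <- res[[1]][, c("pathway_a", "pathway_b")]
  sgn <- sapply(res, function(d) sign(d$r))
  sig <- sapply(res, function(d) d$significant)
  base$consistent <- apply(sgn, 1, function(z) length(unique(z)) == 1) &
    apply(sig, 1, function(z) length(unique(z)) == 1)
  base
}
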