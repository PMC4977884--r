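# Shared objects and independent oracles for the suite.

tmpl <- core_template()

fix_model <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) cache[[name]] <<- fixture_model(name, tmpl)
    cache[[name]]
  }
})

# Brute-force LP oracle: enumerate all candidate vertices (n - m
# variables pinned at a bound, square solve for the rest).  Exponential
# and only for toy systems.
brute_lp <- function(obj, A, b, lower, upper) {
  A <- as.matrix(A); n <- ncol(A); m <- nrow(A)
  stopifnot(n >= m)
  best <- -Inf
  for (fixset in utils::combn(seq_len(n), n - m, simplify = FALSE)) {
    free <- setdiff(seq_len(n), fixset)
    Af <- A[, free, drop = FALSE]
    if (abs(det(Af)) < 1e-10) next
    k <- length(fixset)
    for (mask in seq_len(2^k) - 1L) {
      at_up <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      xf <- ifelse(at_up, upper[fixset], lower[fixset])
      rhs <- b - A[, fixset, drop = FALSE] %*% xf
      xr <- solve(Af, rhs)
      x <- numeric(n); x[fixset] <- xf; x[free] <- xr
      if (all(x >= lower - 1e-8) && all(x <= upper + 1e-8))
        best <- max(best, sum(obj * x))
    }
  }
  best
}

# Independent re-evaluation of pathway rules (step-by-step)
rule_oracle <- function(rxn_ids, rules) {
  vapply(rules, function(steps) {
    for (step in steps) if (!any(step %in% rxn_ids)) return(FALSE)
    TRUE
  }, TRUE)
}

# random model built from a random synthetic spec
random_synth_model <- function(i, template = tmpl, dropout = 0) {
  pw <- names(template$pathway_rules)
  set.seed(7000 + i)
  req <- sample(pw, sample.int(8L, 1L))
  etc <- sample(c("aerobic", "nitrate", "tmao", "fumarate"),
                sample.int(3L, 1L) - 1L)
  g <- generate_annotation_set(
    genome_spec(sprintf("synth%03d", i), req, etc,
                role_dropout_prob = dropout, seed = 7000 + i), template)
  list(model = build_core_model(template, g$annotations), truth = g$truth)
}

# a medium with every exchange closed
closed_media <- function(template = tmpl) {
  med <- get_media(template, "glc_none")
  med$exchange_bounds[, "uptake"] <- 0
  med$exchange_bounds[, "secretion"] <- 0
  # close every other exchange too by overriding defaults
  ex <- names(template$reactions)[vapply(template$reactions,
                                         function(r) r$kind == "exchange", TRUE)]
  cpds <- vapply(template$reactions[ex], function(r) names(r$stoich)[1], "")
  med$exchange_bounds <- matrix(0, length(cpds), 2,
                                dimnames = list(cpds, c("uptake", "secretion")))
  med$name <- "closed"
  med
}
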