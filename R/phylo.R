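# Phylogenetic tree collapse and pathway-annotation export.
#
# Trees are consumed (newick via ape), never inferred.  Collapse
# replaces every maximal clade whose leaf-pairwise (patristic)
# diameter is strictly below a threshold with its best-quality leaf,
# mirroring OTU-style clustering of near-identical 16S sequences.

#' Collapse a tree at an evolutionary-distance threshold
#'
#' For each maximal rooted clade in which all pairwise leaf distances
#' are strictly below \code{threshold}, only the leaf with the highest
#' quality score is kept (ties, or missing scores, fall back to
#' lexicographic leaf label).  Unrooted trees are midpoint-rooted
#' first.
#'
#' @param tree an \code{ape} \code{phylo} object with branch lengths.
#' @param threshold collapse diameter (default 0.01).
#' @param quality optional named numeric vector of per-genome quality
#'   scores (names = leaf labels).
#' @return the collapsed \code{phylo} tree; kept representatives carry
#'   the labels of their original leaves.  The mapping from each
#'   removed leaf to the representative it was merged into is attached
#'   as \code{attr(x, "representative_of")}; every such pair was within
#'   the threshold at the time of its merge.
#' @export
collapse_tree <- function(tree, threshold = 0.01, quality = NULL) {
  stopifnot(inherits(tree, "phylo"), threshold > 0)
  if (is.null(tree$edge.length))
    stop("collapse_tree() requires branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("leaf labels must be unique")
  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
    message("unrooted input tree was midpoint-rooted before collapse")
  }
  # collapsing representatives can itself create clades below the
  # diameter threshold (single-linkage chaining), so iterate the
  # one-pass collapse to its fixed point; the result is idempotent
  rep_all <- character(0)
  out <- tree
  repeat {
    out2 <- .collapse_once(out, threshold, quality)
    rep_new <- attr(out2, "representative_of")
    if (!length(rep_new)) break
    rep_all <- c(rep_all, rep_new)
    out <- out2
  }
  attr(out, "representative_of") <- rep_all
  out
}

.collapse_once <- function(tree, threshold, quality) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) {
    attr(tree, "representative_of") <- character(0)
    return(tree)
  }
  D <- ape::cophenetic.phylo(tree)

  # clade tip sets for every internal node
  node_ids <- (ntip + 1L):(ntip + tree$Nnode)
  tipsets <- lapply(node_ids, function(nd) {
    unlist(phangorn::Descendants(tree, nd, type = "tips"))
  })
  diam <- vapply(tipsets, function(tp)
    if (length(tp) < 2) 0 else max(D[tree$tip.label[tp], tree$tip.label[tp]]),
    0)
  names(diam) <- node_ids

  parent_of <- function(nd) {
    e <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(e)) e else NA_integer_
  }
  # maximal collapsible clades: diameter < threshold, parent's >= threshold
  collapsible <- node_ids[diam < threshold]
  maximal <- collapsible[vapply(collapsible, function(nd) {
    p <- parent_of(nd)
    is.na(p) || diam[as.character(p)] >= threshold
  }, TRUE)]

  pick_rep <- function(labels) {
    if (!is.null(quality)) {
      q <- quality[labels]
      if (all(!is.na(q))) {
        best <- max(q)
        return(sort(labels[q == best])[1])
      }
      message("quality score missing for some leaves; falling back to lexicographic label")
    }
    sort(labels)[1]
  }

  drop <- character(0); rep_of <- character(0)
  for (nd in maximal) {
    labs <- tree$tip.label[tipsets[[match(nd, node_ids)]]]
    if (length(labs) < 2) next
    rep <- pick_rep(labs)
    gone <- setdiff(labs, rep)
    drop <- c(drop, gone)
    rep_of[gone] <- rep
  }
  out <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  attr(out, "representative_of") <- rep_of
  out
}

#' Export pathway/respiration annotations for tree viewers
#'
#' Produces one record per leaf: the Boolean pathway vector, the
#' respiration class, and a colour code shared by identical vectors
#' (iTOL-style dataset semantics).  Leaves without a profile get an
#' explicit \code{"missing"} state.
#'
#' @param tree a \code{phylo} tree.
#' @param profiles profile data frame from [pathway_profiles()]
#'   (matched on \code{genome_id}).
#' @param file optional path; when given, the dataset is written as TSV.
#' @return data frame with columns \code{leaf}, one column per pathway,
#'   \code{respiration}, \code{vector_key}, \code{color},
#'   \code{missing}.
#' @export
export_tree_annotations <- function(tree, profiles, file = NULL) {
  pcols <- names(profiles)[vapply(profiles, is.logical, TRUE)]
  ix <- match(tree$tip.label, profiles$genome_id)
  vecs <- vapply(seq_along(tree$tip.label), function(i) {
    if (is.na(ix[i])) "missing"
    else paste(as.integer(unlist(profiles[ix[i], pcols])), collapse = "")
  }, "")
  keys <- sort(unique(vecs[vecs != "missing"]))
  pal <- if (length(keys)) grDevices::hcl.colors(max(length(keys), 2L), "Dark 3")[seq_along(keys)] else character(0)
  color <- ifelse(vecs == "missing", "#BBBBBB", pal[match(vecs, keys)])
  out <- data.frame(leaf = tree$tip.label, stringsAsFactors = FALSE)
  for (p in pcols)
    out[[p]] <- ifelse(is.na(ix), NA, as.logical(profiles[[p]][ix]))
  out$respiration <- ifelse(is.na(ix), NA_character_, profiles$respiration[ix])
  out$vector_key <- vecs
  out$color <- color
  out$missing <- is.na(ix)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Flag metabolic-profile outliers on a tree
#'
#' A leaf is flagged when its Boolean pathway vector differs from the
#' vectors of all leaves within a patristic radius (default 5 times the
#' collapse threshold) -- the annotation-error screening rule.  Leaves
#' with no neighbour inside the radius are not flagged.
#'
#' @param tree a \code{phylo} tree.
#' @param profiles profile data frame.
#' @param radius patristic distance radius (default 0.05).
#' @return data frame: \code{leaf}, \code{n_neighbors}, \code{outlier}.
#' @export
flag_profile_outliers <- function(tree, profiles, radius = 0.05) {
  ann <- export_tree_annotations(tree, profiles)
  D <- ape::cophenetic.phylo(tree)
  out <- data.frame(leaf = ann$leaf, n_neighbors = 0L, outlier = FALSE)
  for (i in seq_len(nrow(ann))) {
    if (ann$missing[i]) next
    nb <- which(D[ann$leaf[i], ann$leaf] > 0 & D[ann$leaf[i], ann$leaf] <= radius &
                  !ann$missing)
    out$n_neighbors[i] <- length(nb)
    if (length(nb))
      out$outlier[i] <- all(ann$vector_key[nb] != ann$vector_key[i])
  }
  out
}
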