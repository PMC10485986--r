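#' Intersect landmark, ecology, and tree taxa into one matched dataset
#'
#' Names are compared after a configurable normalization (case-folding and
#' space/underscore unification); original spellings are kept. The tree is
#' pruned to the common taxon set with branch lengths preserved, and all
#' three components are returned in one shared taxon order (the landmark
#' set's order restricted to the intersection).
#'
#' @param lm a [landmark_set()].
#' @param eco an [ecology_table()].
#' @param tree an `ape::phylo` with unique tip labels and branch lengths.
#' @param normalize compare names after case-folding and replacing spaces
#'   with underscores (default TRUE).
#' @return An object of class `matched_dataset`: list with `landmarks`,
#'   `ecology`, `tree`, `taxa` (shared order) and `dropped` (a list of taxa
#'   dropped from each source).
#' @export
match_and_prune <- function(lm, eco, tree, normalize = TRUE) {
  if (!inherits(tree, "phylo")) stop_validation("tree must be an ape phylo")
  if (anyDuplicated(tree$tip.label)) stop_validation("duplicate tree tips")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_validation("negative branch lengths")
  key <- if (normalize) normalize_taxon else identity
  k_lm <- key(lm$taxa); k_eco <- key(eco$taxon); k_tr <- key(tree$tip.label)
  common <- intersect(intersect(k_lm, k_eco), k_tr)
  if (length(common) < 4)
    stop_validation("only %d taxa common to landmarks, ecology and tree; models unidentifiable",
                    length(common))
  # shared order: landmark-set order restricted to the intersection
  ord <- k_lm[k_lm %in% common]
  dropped <- list(landmarks = lm$taxa[!k_lm %in% common],
                  ecology   = eco$taxon[!k_eco %in% common],
                  tree      = tree$tip.label[!k_tr %in% common])
  lm2 <- taxon_subset(lm, lm$taxa[match(ord, k_lm)])
  eco2 <- eco[match(ord, k_eco), , drop = FALSE]
  rownames(eco2) <- NULL
  tree2 <- ape::keep.tip(tree, tree$tip.label[match(ord, k_tr)])
  # rename tree tips to the landmark-set spelling so labels agree everywhere
  tree2$tip.label <- lm2$taxa[match(key(tree2$tip.label), key(lm2$taxa))]
  structure(list(landmarks = lm2, ecology = eco2, tree = tree2,
                 taxa = lm2$taxa, dropped = dropped),
            class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  nd <- vapply(x$dropped, length, 1L)
  cat(sprintf("<matched_dataset> %d taxa (dropped: %d landmark, %d ecology, %d tree)\n",
              length(x$taxa), nd[["landmarks"]], nd[["ecology"]], nd[["tree"]]))
  invisible(x)
}
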