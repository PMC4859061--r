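#' Serialise a simulation genealogy to Newick
#'
#' The recorded genealogy is a tree over lineage segments: parapatric
#' splits close the parent and attach its daughters as a (possibly
#' multifurcating) internal node labelled with the parent id; sympatric
#' births insert an unlabelled degree-three node on the parent's branch at
#' the birth age. Branch lengths are in Myr (ages decrease toward the
#' present); extant tips have branches reaching the end age of the run.
#'
#' @param result a `sim_result`.
#' @return a single Newick string (terminated by `;`). Tips are named
#'   `s<id>`.
#' @export
genealogy_newick <- function(result) {
  sp <- result$species
  end_age <- result$end_age
  kids <- split(sp$id, factor(sp$parent, levels = sp$id))
  term <- ifelse(is.na(sp$death), end_age, sp$death)
  # children processed oldest-first; equal ages ordered by id
  build <- function(sid, from_age, kidlist) {
    if (length(kidlist) == 0)
      return(sprintf("s%d:%g", sid, from_age - term[sid]))
    a <- sp$birth[kidlist[1]]
    here <- kidlist[sp$birth[kidlist] == a]
    rest <- kidlist[sp$birth[kidlist] < a]
    sub <- vapply(here, function(cid) {
      ck <- kids[[as.character(cid)]]
      ck <- ck[order(-sp$birth[ck], ck)]
      build(cid, a, ck)
    }, character(1))
    if (sp$closed[sid] && !is.na(sp$death[sid]) && sp$death[sid] == a &&
        length(rest) == 0) {
      # parapatric closure: parent becomes the labelled internal node
      sprintf("(%s)s%d:%g", paste(sub, collapse = ","), sid, from_age - a)
    } else {
      # sympatric branching: the parent lineage continues past the node
      cont <- build(sid, a, rest)
      sprintf("(%s):%g", paste(c(sub, cont), collapse = ","), from_age - a)
    }
  }
  roots <- sp$id[is.na(sp$parent)]
  stopifnot(length(roots) == 1)
  rk <- kids[[as.character(roots)]]
  rk <- rk[order(-sp$birth[rk], rk)]
  paste0(build(roots, sp$birth[roots], rk), ";")
}

#' Genealogy as an ape tree, optionally pruned to extant species
#'
#' @param result a `sim_result` with at least two tip lineages.
#' @param extant_only drop lineages extinct before the end age (default
#'   `FALSE`).
#' @return an [ape::read.tree()] `phylo` object, or `NULL` when pruning
#'   leaves fewer than two tips.
#' @export
genealogy_tree <- function(result, extant_only = FALSE) {
  tr <- ape::read.tree(text = genealogy_newick(result))
  if (!extant_only) return(tr)
  sp <- result$species
  extinct <- sprintf("s%d", sp$id[!is.na(sp$death) & !sp$closed])
  drop <- intersect(tr$tip.label, extinct)
  if (length(setdiff(tr$tip.label, drop)) < 2) return(NULL)
  ape::drop.tip(tr, drop)
}
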