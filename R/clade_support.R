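# Monospecific-clade support: how many of the focal species' family members
# sit together in a single clade of the family tree. A large largest
# monospecific clade is the signature of recent, lineage-specific duplication.

#' Parse a Newick tree
#'
#' Thin validation wrapper over [ape::read.tree()]: requires a well-formed
#' string ending in `";"`, unique tip labels, and at least one tip. Branch
#' lengths and internal node (support) labels are retained.
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path optional path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) abort("supply a Newick string or a path")
    text <- paste(readLines(path), collapse = "")
  }
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) abort("Newick string must end in ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(paste0("unbalanced parentheses in Newick string (", n_open,
                 " '(' vs ", n_close, " ')')"))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) abort(paste0("Newick parse error: ",
                                                    conditionMessage(e))))
  if (is.null(tree)) abort("Newick parse error: unreadable string")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip label: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  tree
}

as_focal_predicate <- function(is_focal) {
  if (is.function(is_focal)) return(is_focal)
  if (is.character(is_focal) && length(is_focal) == 1) {
    prefix <- is_focal
    return(function(label) startsWith(label, prefix))
  }
  abort("is_focal must be a predicate function or a tip-label prefix")
}

#' Largest monospecific clade of the focal species
#'
#' Scans every clade of the (rooted) tree — each tip and each subtree rooted
#' at an internal node — keeps those whose tips all satisfy `is_focal`, and
#' returns the largest one, as a fraction of all focal tips in the tree. Ties
#' are broken by the first clade encountered in post-order. With
#' `all_rootings = TRUE` every edge is tried as the root (for consensus trees
#' whose published rooting is implicit) and the maximum fraction over rootings
#' is reported.
#'
#' @param tree an [ape::phylo] tree or a Newick string.
#' @param is_focal predicate on tip labels, or a label prefix such as
#'   `"RPR"`.
#' @param all_rootings evaluate every rooting of an unrooted topology.
#' @return one-row tibble: `clade_size`, `focal_total`, `fraction`,
#'   `rounded_percent`, and `clade_tips` (list-column of tip labels).
#' @export
#' @examples
#' tr <- parse_newick("(((RPR1,RPR2),RPR3),(X1,(RPR4,X2)));")
#' max_monospecific_clade(tr, "RPR")   # 3 of 4 focal tips -> 75%
max_monospecific_clade <- function(tree, is_focal, all_rootings = FALSE) {
  if (is.character(tree)) tree <- parse_newick(tree)
  pred <- as_focal_predicate(is_focal)
  focal_tip <- map_lgl(tree$tip.label, pred)
  if (!any(focal_tip)) abort("no tip satisfies the focal predicate")
  best_of <- function(tr) {
    ft <- map_lgl(tr$tip.label, pred)
    n_tip <- length(tr$tip.label)
    edges <- tr$edge
    # post-order accumulation: all-focal flag and tip set per node
    nodes <- n_tip + seq_len(tr$Nnode)
    all_focal <- c(ft, rep(NA, tr$Nnode))
    members <- c(as.list(seq_len(n_tip)), vector("list", tr$Nnode))
    ord <- ape::postorder(tr)               # edge indices, children first
    for (e in ord) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      if (is.na(all_focal[parent])) {
        all_focal[parent] <- TRUE
        members[[parent]] <- integer(0)
      }
      all_focal[parent] <- all_focal[parent] && all_focal[child]
      members[[parent]] <- c(members[[parent]], members[[child]])
    }
    best_size <- 0L; best_tips <- integer(0)
    # tips first, then internal nodes in post-order of first completion
    for (v in c(seq_len(n_tip), unique(edges[ord, 1]))) {
      if (isTRUE(all_focal[v]) && length(members[[v]]) > best_size) {
        best_size <- length(members[[v]])
        best_tips <- members[[v]]
      }
    }
    list(size = best_size, tips = tr$tip.label[best_tips])
  }
  if (all_rootings) {
    utree <- ape::unroot(tree)
    n_tip <- length(utree$tip.label)
    res <- list(size = -1L, tips = character(0))
    for (child in unique(utree$edge[, 2])) {
      rt <- tryCatch({
        if (child <= n_tip) {
          ape::root(utree, outgroup = utree$tip.label[child],
                    resolve.root = TRUE)
        } else {
          ape::root(utree, node = child, resolve.root = TRUE)
        }
      }, error = function(e) NULL)
      if (is.null(rt)) next
      cand <- best_of(rt)
      if (cand$size > res$size) res <- cand
    }
  } else {
    res <- best_of(tree)
  }
  n_focal <- sum(focal_tip)
  frac <- res$size / n_focal
  tibble(
    clade_size = res$size,
    focal_total = n_focal,
    fraction = frac,
    rounded_percent = rounded_percent(frac),
    clade_tips = list(res$tips)
  )
}

#' Round a fraction to an integer percentage, halves up
#'
#' `round()` in R rounds halves to even; clade-support percentages are
#' conventionally reported with halves rounded up (11/18 -> 61%, 0.5 -> 50%).
#'
#' @param fraction value in `[0, 1]`.
#' @return integer percent.
#' @export
rounded_percent <- function(fraction) {
  if (any(is.na(fraction)) || any(fraction < 0) || any(fraction > 1)) {
    abort("fraction must lie in [0, 1]")
  }
  as.integer(floor(100 * fraction + 0.5))
}
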