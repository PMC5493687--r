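#' Fitch parsimony reconstruction of one discrete character
#'
#' Bottom-up pass of unordered (Fitch) parsimony on a rooted binary tree.
#' Each tip starts with the singleton set of its observed state; MISSING tips
#' (`NA` or `"?"`) start with the full alphabet and act as wildcards. At each
#' internal node the child sets are intersected; an empty intersection is
#' replaced by the union and counts one state change. The returned score is
#' the minimum number of changes over all full labelings of the tree.
#'
#' @param tree Rooted binary `phylo` tree.
#' @param states Character (or coercible) vector of tip states named by tip
#'   label; `NA` or `"?"` = MISSING.
#' @param alphabet Optional character vector of admissible states; defaults
#'   to the distinct observed states.
#' @return A `FitchReconstruction`: list with `tree`, `node_sets` (state set
#'   per node, tips first in `ape` numbering), `score`, `alphabet`,
#'   `tip_states`.
#' @export
fitch <- function(tree, states, alphabet = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree has polytomies; resolve them or use a binary tree")
  states <- states[tree$tip.label]
  if (length(states) != length(tree$tip.label) || is.null(names(states)))
    stop("states must be named by tip label and cover every tip")
  st <- as.character(states)
  st[st %in% "?"] <- NA_character_
  if (all(is.na(st))) stop("all tips MISSING; nothing to reconstruct")
  if (is.null(alphabet)) alphabet <- sort(unique(st[!is.na(st)]))
  if (any(!is.na(st) & !(st %in% alphabet)))
    stop("tip state outside the declared alphabet")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  node_sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip))
    node_sets[[i]] <- if (is.na(st[i])) alphabet else st[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  score <- 0L
  # children of each internal node, in postorder
  for (node in unique(edges[, 1L])) {
    kids <- edges[edges[, 1L] == node, 2L]
    s <- node_sets[[kids[1L]]]
    for (k in kids[-1L]) {
      inter <- intersect(s, node_sets[[k]])
      if (length(inter) > 0L) {
        s <- inter
      } else {
        s <- union(s, node_sets[[k]])
        score <- score + 1L
      }
    }
    node_sets[[node]] <- s
  }
  structure(list(tree = tree, node_sets = node_sets, score = score,
                 alphabet = alphabet,
                 tip_states = stats::setNames(st, tree$tip.label)),
            class = "FitchReconstruction")
}

#' @export
print.FitchReconstruction <- function(x, ...) {
  cat(sprintf("Fitch reconstruction: %d tips, score %d, root set {%s}\n",
              length(x$tree$tip.label), x$score,
              paste(x$node_sets[[length(x$tree$tip.label) + 1L]], collapse = ",")))
  invisible(x)
}

# All most-parsimonious full labelings (MPRs) of the character on the tree.
# Free nodes are the internal nodes plus MISSING tips; assignments over the
# alphabet are enumerated and filtered to minimum cost (optionally with the
# root state fixed). Returns list(states = matrix MPR x node, cost).
enumerate_mprs <- function(recon, root_state = NULL) {
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  nnode_tot <- ntip + tree$Nnode
  free <- c(which(is.na(recon$tip_states)), (ntip + 1L):nnode_tot)
  a <- recon$alphabet
  grid <- as.matrix(expand.grid(rep(list(a), length(free)),
                                stringsAsFactors = FALSE))
  full <- matrix(NA_character_, nrow(grid), nnode_tot)
  fixed <- setdiff(seq_len(ntip), free)
  for (i in fixed) full[, i] <- recon$tip_states[i]
  full[, free] <- grid
  cost <- integer(nrow(full))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (full[, tree$edge[e, 1L]] != full[, tree$edge[e, 2L]])
  if (!is.null(root_state)) {
    keep <- full[, ntip + 1L] == root_state
    if (!any(keep)) stop("no labeling with the requested root state")
    full <- full[keep, , drop = FALSE]
    cost <- cost[keep]
  }
  best <- cost == min(cost)
  list(states = full[best, , drop = FALSE], cost = min(cost))
}

node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- integer(ntip + tree$Nnode)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # root is ntip+1 in ape; walk edges in preorder
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre)))
    depth[pre[e, 2L]] <- depth[pre[e, 1L]] + 1L
  depth
}

# Branch label: tip name for terminal branches, "stem:<tip+tip+...>" for the
# branch subtending an internal clade.
node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  vapply(node, function(n) {
    if (n <= ntip) return(tree$tip.label[n])
    tips <- ape::extract.clade(tree, n)$tip.label
    paste0("stem:", paste(sort(tips), collapse = "+"))
  }, character(1))
}

#' Map parsimony state changes onto branches
#'
#' Enumerates every most-parsimonious labeling (MPR) of the character and
#' reports where changes fall. The default `REPORT_AMBIGUOUS` policy does not
#' force a placement: each branch that changes in at least one MPR is listed
#' with the fraction of MPRs placing a change there, and a change whose
#' placement varies across MPRs is flagged ambiguous rather than resolved.
#' `ACCTRAN` (`DELTRAN`) instead picks the single MPR that places changes as
#' close to (far from) the root as possible, measured by the summed depth of
#' changed branches, with a deterministic lexicographic tie-break.
#'
#' @param recon A [fitch()] reconstruction.
#' @param tie_policy `"REPORT_AMBIGUOUS"`, `"ACCTRAN"` or `"DELTRAN"`.
#' @param root_state Optional state imposed at the root, e.g. the
#'   ancestral-absence polarization when an outgroup lacks the character
#'   state of interest. The minimum is then taken over root-compatible
#'   labelings only.
#' @return Data frame of branches (identified by their child node) with
#'   columns `parent`, `child`, `branch` (label), `prop_mprs` (fraction of
#'   MPRs with a change there), `ambiguous`, and for ACCTRAN/DELTRAN
#'   `from_state`/`to_state`. The total score is attached as attribute
#'   `score`; for REPORT_AMBIGUOUS, attribute `admissible` holds, per
#'   ambiguous change set, the branches over which it can move.
#' @export
map_changes <- function(recon,
                        tie_policy = c("REPORT_AMBIGUOUS", "ACCTRAN", "DELTRAN"),
                        root_state = NULL) {
  stopifnot(inherits(recon, "FitchReconstruction"))
  tie_policy <- match.arg(tie_policy)
  tree <- recon$tree
  mprs <- enumerate_mprs(recon, root_state)
  ne <- nrow(tree$edge)
  chg <- matrix(FALSE, nrow(mprs$states), ne)
  for (e in seq_len(ne))
    chg[, e] <- mprs$states[, tree$edge[e, 1L]] != mprs$states[, tree$edge[e, 2L]]
  if (tie_policy == "REPORT_AMBIGUOUS") {
    prop <- colMeans(chg)
    keep <- which(prop > 0)
    out <- data.frame(parent = tree$edge[keep, 1L], child = tree$edge[keep, 2L],
                      branch = node_label(tree, tree$edge[keep, 2L]),
                      prop_mprs = prop[keep],
                      ambiguous = prop[keep] < 1,
                      stringsAsFactors = FALSE)
    attr(out, "score") <- mprs$cost
    attr(out, "admissible") <- out$branch[out$ambiguous]
    return(out)
  }
  depth <- node_depths(tree)
  edge_depth <- depth[tree$edge[, 2L]]
  placement <- as.vector(chg %*% edge_depth)
  cand <- if (tie_policy == "ACCTRAN") which(placement == min(placement))
          else which(placement == max(placement))
  if (length(cand) > 1L) {  # deterministic tie-break on the labeling itself
    keys <- apply(mprs$states[cand, , drop = FALSE], 1L, paste, collapse = "")
    cand <- cand[order(keys)[1L]]
  }
  pick <- mprs$states[cand, ]
  keep <- which(chg[cand, ])
  out <- data.frame(parent = tree$edge[keep, 1L], child = tree$edge[keep, 2L],
                    branch = node_label(tree, tree$edge[keep, 2L]),
                    from_state = pick[tree$edge[keep, 1L]],
                    to_state = pick[tree$edge[keep, 2L]],
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  attr(out, "score") <- mprs$cost
  out
}

#' Fitch reconstruction for every character of a character matrix
#'
#' @param tree Rooted binary `phylo` species tree.
#' @param characters Data frame: column `character` plus one state column per
#'   species (`"?"` or `NA` = MISSING).
#' @param tie_policy Passed to [map_changes()].
#' @return Data frame with one row per character: `character`, `score`,
#'   `root_states`, `n_ambiguous_branches`.
#' @export
reconstruct_characters <- function(tree, characters,
                                   tie_policy = "REPORT_AMBIGUOUS") {
  sp <- intersect(names(characters), tree$tip.label)
  if (length(sp) != length(tree$tip.label))
    stop("character matrix lacks species column(s): ",
         paste(setdiff(tree$tip.label, names(characters)), collapse = ", "))
  res <- lapply(seq_len(nrow(characters)), function(i) {
    st <- stats::setNames(as.character(unlist(characters[i, sp])), sp)
    rec <- fitch(tree, st)
    ch <- map_changes(rec, tie_policy = tie_policy)
    data.frame(character = characters$character[i], score = rec$score,
               root_states = paste(rec$node_sets[[length(tree$tip.label) + 1L]],
                                   collapse = ","),
               n_ambiguous_branches = sum(ch$ambiguous),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
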