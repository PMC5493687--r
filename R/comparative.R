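#' Join per-species direction calls by orthogroup
#'
#' Every orthogroup of the map appears exactly once. A species' entry is
#' `MISSING` when the orthogroup has no gene in that species' annotation;
#' otherwise the direction comes from the species' DE table (an orthogroup
#' gene without a DE entry is a universe mismatch and an error).
#'
#' @param de_results Named list (by species) of `DEResult` tables computed on
#'   the ortholog-restricted universe.
#' @param orthomap `OrthologMap`.
#' @return Data frame with `orthogroup` and one `dir_<species>` column per
#'   species, values in UP/DOWN/UNCHANGED/UNTESTABLE/MISSING.
#' @export
concordance_table <- function(de_results, orthomap) {
  species <- map_species(orthomap)
  miss_sp <- setdiff(species, names(de_results))
  if (length(miss_sp)) stop("no DE results for species: ",
                            paste(miss_sp, collapse = ", "))
  out <- data.frame(orthogroup = orthomap$orthogroup, stringsAsFactors = FALSE)
  for (sp in species) {
    de <- de_results[[sp]]
    idx <- match(orthomap[[sp]], de$gene)
    bad <- which(!is.na(orthomap[[sp]]) & is.na(idx))
    if (length(bad))
      stop("universe mismatch: ", sp, " gene(s) without DE entry: ",
           paste(utils::head(orthomap[[sp]][bad], 5), collapse = ", "))
    dir <- de$direction[idx]
    dir[is.na(orthomap[[sp]])] <- "MISSING"
    out[[paste0("dir_", sp)]] <- dir
  }
  out
}

#' Check that a named species set is a clade of the tree
#' @noRd
assert_clades <- function(clades, tree) {
  for (nm in names(clades)) {
    cl <- clades[[nm]]
    if (length(cl) < 2L) stop("named clade '", nm, "' must contain >= 2 species")
    bad <- setdiff(cl, tree$tip.label)
    if (length(bad)) stop("clade '", nm, "' references unknown species: ",
                          paste(bad, collapse = ", "))
    if (length(cl) < length(tree$tip.label)) {
      mrca <- ape::getMRCA(tree, cl)
      desc <- ape::extract.clade(tree, mrca)$tip.label
      if (!setequal(desc, cl))
        stop("'", nm, "' is not monophyletic on the species tree")
    }
  }
  invisible(TRUE)
}

#' Label the phylogenetic conservation pattern of one orthogroup
#'
#' A named clade is *consistent* with the direction pattern when (i) every
#' non-MISSING member shares one modulated direction (all UP or all DOWN),
#' with at least one member observed, and (ii) every non-member is UNCHANGED
#' or MISSING. The labeling:
#' \itemize{
#'   \item exactly one consistent clade: `CONSERVED_<clade>`;
#'   \item several (necessarily nested, with the distinguishing species
#'     MISSING): `AMBIGUOUS:<most-inclusive>..<least-inclusive>` — one
#'     origin somewhere between the two stems explains the data equally
#'     parsimoniously;
#'   \item no consistent clade and exactly one modulated species:
#'     `SPECIES_SPECIFIC:<species>`;
#'   \item no modulated species: `NOT_MODULATED`;
#'   \item otherwise (modulated species fitting no named clade, or mixed
#'     signs): `NOT_CONCORDANT`.
#' }
#' UNTESTABLE entries are treated as MISSING by default (conservative:
#' an untested species can neither support nor contradict a clade), or as
#' UNCHANGED via `untestable_as`.
#'
#' @param directions Named character vector (species -> direction).
#' @param species_tree `phylo` species tree.
#' @param clades Named list of species vectors; each must be monophyletic.
#' @param untestable_as `"MISSING"` or `"UNCHANGED"`.
#' @return Single conservation label string.
#' @export
classify_conservation <- function(directions, species_tree, clades,
                                  untestable_as = c("MISSING", "UNCHANGED")) {
  untestable_as <- match.arg(untestable_as)
  assert_clades(clades, species_tree)
  species <- species_tree$tip.label
  stopifnot(all(species %in% names(directions)))
  d <- directions[species]
  d[d == "UNTESTABLE"] <- untestable_as
  modulated <- names(d)[d %in% c("UP", "DOWN")]

  consistent <- function(members) {
    inside <- d[members]
    outside <- d[setdiff(species, members)]
    obs <- inside[inside != "MISSING"]
    length(obs) > 0L && all(obs %in% c("UP", "DOWN")) &&
      length(unique(obs)) == 1L && all(outside %in% c("UNCHANGED", "MISSING"))
  }
  ok <- names(clades)[vapply(clades, consistent, logical(1))]
  if (length(ok) == 1L) return(paste0("CONSERVED_", ok))
  if (length(ok) > 1L) {
    sizes <- vapply(clades[ok], length, integer(1))
    ord <- ok[order(-sizes)]
    return(paste0("AMBIGUOUS:", ord[1L], "..", ord[length(ord)]))
  }
  if (length(modulated) == 0L) return("NOT_MODULATED")
  if (length(modulated) == 1L) return(paste0("SPECIES_SPECIFIC:", modulated))
  "NOT_CONCORDANT"
}

#' Conservation labels for a whole concordance table
#'
#' @param conc Output of [concordance_table()].
#' @param species_tree,clades,untestable_as See [classify_conservation()].
#' @return `conc` with a `conservation` column appended.
#' @export
classify_concordance_table <- function(conc, species_tree, clades,
                                       untestable_as = "MISSING") {
  species <- sub("^dir_", "", grep("^dir_", names(conc), value = TRUE))
  conc$conservation <- vapply(seq_len(nrow(conc)), function(i) {
    d <- stats::setNames(as.character(conc[i, paste0("dir_", species)]), species)
    classify_conservation(d, species_tree, clades, untestable_as)
  }, character(1))
  conc
}

#' Profile a gene family's paralogs against its gene tree
#'
#' The gene tree is pruned to the selected family clade and to the leaves of
#' retained species. For every retained paralog the profile reports its
#' maximum TPM over samples, an expressed flag (strictly above `expressed_tpm`
#' in at least one sample, recomputed from the expression matrix rather than
#' cached), and the configured stage-contrast fold change with its direction
#' call. Per species the family is summarized by whether any expressed
#' paralog is called UP, and species with no expressed paralog are
#' family-silent.
#'
#' @param gene_tree `phylo` gene tree whose tip labels are gene ids.
#' @param membership Data frame (species, gene_id) mapping leaves to species.
#' @param expr_list Named list of full-universe TPM `ExpressionMatrix` per
#'   species.
#' @param de_list Named list of `DEResult` tables on the full universe.
#' @param family_clade Optional clade selector: internal node label or a
#'   character vector of leaf labels whose MRCA defines the clade; `NULL`
#'   keeps the whole tree.
#' @param species_keep Species to retain; default all in `membership`.
#' @param expressed_tpm Presence threshold (TPM, strict).
#' @return List of class `FamilyProfile`: `tree` (pruned), `paralogs` (one
#'   row per retained leaf), `species_summary` (per-species any-paralog-up
#'   and family-silent flags).
#' @export
family_profile <- function(gene_tree, membership, expr_list, de_list,
                           family_clade = NULL, species_keep = NULL,
                           expressed_tpm = 3) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (is.null(species_keep)) species_keep <- unique(membership$species)
  tr <- gene_tree
  if (!is.null(family_clade)) {
    node <- if (length(family_clade) == 1L && !family_clade %in% tr$tip.label) {
      if (is.null(tr$node.label) || !family_clade %in% tr$node.label)
        stop("internal node label not found: ", family_clade)
      length(tr$tip.label) + match(family_clade, tr$node.label)
    } else ape::getMRCA(tr, family_clade)
    tr <- ape::extract.clade(tr, node)
  }
  keep_genes <- membership$gene_id[membership$species %in% species_keep]
  keep <- intersect(tr$tip.label, keep_genes)
  if (length(keep) < 2L) stop("fewer than 2 family leaves retained")
  tr <- ape::keep.tip(tr, keep)

  rows <- lapply(tr$tip.label, function(g) {
    sp <- membership$species[membership$gene_id == g]
    if (length(sp) != 1L) stop("leaf not mapped to exactly one species: ", g)
    ex <- expr_list[[sp]]
    if (is.null(ex) || !g %in% rownames(ex$values))
      stop("gene ", g, " absent from the ", sp, " expression matrix")
    de <- de_list[[sp]]
    i <- match(g, de$gene)
    if (is.na(i)) stop("gene ", g, " absent from the ", sp, " DE table")
    data.frame(species = sp, gene_id = g,
               max_tpm = max(ex$values[g, ]),
               expressed = max(ex$values[g, ]) > expressed_tpm,
               fold_change = de$fold_change[i], p_value = de$p_value[i],
               direction = de$direction[i], stringsAsFactors = FALSE)
  })
  paralogs <- do.call(rbind, rows)
  species_summary <- do.call(rbind, lapply(
    intersect(species_keep, unique(paralogs$species)), function(sp) {
      p <- paralogs[paralogs$species == sp, , drop = FALSE]
      data.frame(species = sp, n_paralogs = nrow(p),
                 n_expressed = sum(p$expressed),
                 any_paralog_up = any(p$expressed & p$direction == "UP"),
                 family_silent = !any(p$expressed), stringsAsFactors = FALSE)
    }))
  structure(list(tree = tr, paralogs = paralogs,
                 species_summary = species_summary),
            class = "FamilyProfile")
}

#' @export
print.FamilyProfile <- function(x, ...) {
  cat(sprintf("FamilyProfile: %d paralogs in %d species (%d expressed)\n",
              nrow(x$paralogs), length(unique(x$paralogs$species)),
              sum(x$paralogs$expressed)))
  invisible(x)
}
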