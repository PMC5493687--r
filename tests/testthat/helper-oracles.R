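# Independent oracles used by the property and acceptance tests. These are
# deliberately written as brute-force enumerations, not as alternative
# implementations of the algorithms under test.

# All rooted binary tree shapes with n tips, as Newick strings with tips
# labeled t1..tn in left-to-right order.
enumerate_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1L) return("L")
    out <- character(0)
    for (i in seq_len(k %/% 2)) {
      sa <- shapes(i); sb <- shapes(k - i)
      for (ai in seq_along(sa)) {
        # unordered pair of subtree shapes: avoid mirrored duplicates
        for (bi in (if (i == k - i) ai else 1L):length(sb))
          out <- c(out, paste0("(", sa[ai], ",", sb[bi], ")"))
      }
    }
    out
  }
  vapply(shapes(n), function(s) {
    i <- 0L
    while (grepl("L", s, fixed = TRUE)) {
      i <- i + 1L
      s <- sub("L", paste0("t", i), s, fixed = TRUE)
    }
    paste0(s, ";")
  }, character(1), USE.NAMES = FALSE)
}

# Minimum number of state changes over ALL full labelings of the tree
# (internal nodes and MISSING tips free), by exhaustive vectorized
# enumeration over the alphabet.
brute_force_parsimony <- function(tree, states, alphabet) {
  ntip <- length(tree$tip.label)
  st <- as.character(states[tree$tip.label])
  st[st %in% "?"] <- NA_character_
  free <- c(which(is.na(st)), (ntip + 1L):(ntip + tree$Nnode))
  grid <- as.matrix(expand.grid(rep(list(alphabet), length(free)),
                                stringsAsFactors = FALSE))
  full <- matrix(NA_character_, nrow(grid), ntip + tree$Nnode)
  for (i in setdiff(seq_len(ntip), free)) full[, i] <- st[i]
  full[, free] <- grid
  cost <- integer(nrow(full))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (full[, tree$edge[e, 1L]] != full[, tree$edge[e, 2L]])
  min(cost)
}

# Literal restatement of the conservation-labeling rules, evaluated over
# clades derived afresh from the tree topology (not the caller's clade list).
oracle_conservation <- function(directions, tree, clade_names) {
  species <- tree$tip.label
  d <- directions[species]
  d[d == "UNTESTABLE"] <- "MISSING"
  clades <- list()
  for (node in (length(species) + 1L):(length(species) + tree$Nnode)) {
    tips <- ape::extract.clade(tree, node)$tip.label
    nm <- names(clade_names)[vapply(clade_names, setequal, logical(1), y = tips)]
    if (length(nm) == 1L) clades[[nm]] <- tips
  }
  fits <- character(0)
  for (nm in names(clades)) {
    inside <- d[clades[[nm]]]
    outside <- d[setdiff(species, clades[[nm]])]
    seen <- inside[inside != "MISSING"]
    if (length(seen) == 0L) next
    if (any(!seen %in% c("UP", "DOWN"))) next
    if (length(unique(seen)) != 1L) next
    if (any(!outside %in% c("UNCHANGED", "MISSING"))) next
    fits <- c(fits, nm)
  }
  n_mod <- sum(d %in% c("UP", "DOWN"))
  if (length(fits) == 1L) return(paste0("CONSERVED_", fits))
  if (length(fits) > 1L) {
    sz <- vapply(clades[fits], length, integer(1))
    fits <- fits[order(-sz)]
    return(paste0("AMBIGUOUS:", fits[1L], "..", fits[length(fits)]))
  }
  if (n_mod == 0L) return("NOT_MODULATED")
  if (n_mod == 1L) return(paste0("SPECIES_SPECIFIC:", names(d)[d %in% c("UP", "DOWN")]))
  "NOT_CONCORDANT"
}

# Two-gene, two-sample CountMatrix written to temp TSVs; returns the paths.
write_tiny_count_files <- function(dir = tempfile()) {
  dir.create(dir)
  counts <- file.path(dir, "counts.tsv")
  lengths <- file.path(dir, "lengths.tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t10\t20", "g2\t30\t40"), counts)
  writeLines(c("gene_id\tlength_bp", "g1\t1000", "g2\t2000"), lengths)
  list(counts = counts, lengths = lengths, dir = dir)
}

# A reduced study bundle (same structure as default_study_fixture, fewer
# genes) so orchestration tests stay fast.
make_small_bundle <- function(seed = 5) {
  tree <- parse_newick(STUDY_TREE)
  reps <- expand.grid(species = tree$tip.label, stage = STAGES, n = 3,
                      stringsAsFactors = FALSE)
  reps$n[reps$species == "armadillo" & reps$stage == "LG"] <- 1
  glires <- c("rabbit", "guinea_pig", "mouse")
  eff <- list(
    planted_effect("sp_up", "OG00001", "mouse", "LG", 2),
    planted_effect("clade_down", "OG00002", glires, "LG", -2))
  fam <- simulate_gene_family(tree, c(mouse = 1), family = "akr")
  extra <- lapply(split(fam$genes, fam$genes$species), function(df)
    data.frame(gene_id = df$gene_id, baseline = 30, length = 1200))
  b <- simulate_counts(sim_config(
    replicates = reps, n_orthogroups = 150, private_frac = 0.1,
    effects = eff, missing = list(armadillo = "OG00003"),
    extra_genes = extra, seed = seed))
  b$family <- fam
  b$clades <- list(Glires = glires, Eutheria = c("armadillo", glires),
                   Theria = tree$tip.label)
  b$species_tree <- tree
  b
}

study_clades <- function() {
  list(Glires = c("rabbit", "guinea_pig", "mouse"),
       Eutheria = c("armadillo", "rabbit", "guinea_pig", "mouse"),
       Theria = c("opossum", "armadillo", "rabbit", "guinea_pig", "mouse"))
}
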