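species5 <- c("opossum", "armadillo", "rabbit", "guinea_pig", "mouse")

fake_de <- function(sp, genes, directions) {
  data.frame(species = sp, gene = genes, fold_change = 1,
             p_value = 0.5, direction = directions,
             stringsAsFactors = FALSE)
}

test_that("concordance joining is lossless and respects MISSING", {
  om <- ortholog_map(c("OG1", "OG2", "OG3"),
                     data.frame(a = c("a1", "a2", "a3"),
                                b = c("b1", NA, "b3"),
                                c = c("c1", "c2", "c3")))
  de <- list(a = fake_de("a", c("a1", "a2", "a3"), c("DOWN", "UP", "UNCHANGED")),
             b = fake_de("b", c("b1", "b3"), c("DOWN", "UNCHANGED")),
             c = fake_de("c", c("c1", "c2", "c3"),
                         c("DOWN", "UNCHANGED", "UNCHANGED")))
  conc <- concordance_table(de, om)
  expect_equal(conc$orthogroup, c("OG1", "OG2", "OG3"))  # exactly once each
  expect_equal(conc$dir_b, c("DOWN", "MISSING", "UNCHANGED"))
  expect_equal(conc$dir_a[2], "UP")

  de$b <- fake_de("b", "b1", "DOWN")  # b3 lost: universe mismatch
  expect_error(concordance_table(de, om), "universe mismatch")
})

test_that("conservation labeling matches the spec'd examples", {
  sp <- parse_newick(STUDY_TREE)
  cl <- study_clades()
  lab <- function(op, arm, rab, gp, mou)
    classify_conservation(c(opossum = op, armadillo = arm, rabbit = rab,
                            guinea_pig = gp, mouse = mou), sp, cl)
  # Glires down, armadillo missing: origin anywhere from the eutherian stem
  # to the Glires stem
  expect_equal(lab("UNCHANGED", "MISSING", "DOWN", "DOWN", "DOWN"),
               "AMBIGUOUS:Eutheria..Glires")
  expect_equal(lab("UNCHANGED", "UNCHANGED", "DOWN", "DOWN", "DOWN"),
               "CONSERVED_Glires")
  expect_equal(lab("UNCHANGED", "UNCHANGED", "UNCHANGED", "UNCHANGED", "UP"),
               "SPECIES_SPECIFIC:mouse")
  # all therians down: the most inclusive consistent clade wins
  expect_equal(lab("DOWN", "DOWN", "DOWN", "DOWN", "DOWN"), "CONSERVED_Theria")
  expect_equal(lab("DOWN", "MISSING", "DOWN", "DOWN", "DOWN"), "CONSERVED_Theria")
  expect_equal(lab("UNCHANGED", "UNCHANGED", "UNCHANGED", "UNCHANGED",
                   "UNCHANGED"), "NOT_MODULATED")
  # same-sign but polyphyletic, and mixed signs: neither is conserved
  expect_equal(lab("DOWN", "UNCHANGED", "DOWN", "DOWN", "DOWN"), "NOT_CONCORDANT")
  expect_equal(lab("UNCHANGED", "UNCHANGED", "UP", "DOWN", "DOWN"), "NOT_CONCORDANT")
  # UNTESTABLE treated as MISSING by default, as UNCHANGED on request
  expect_equal(lab("UNCHANGED", "UNTESTABLE", "DOWN", "DOWN", "DOWN"),
               "AMBIGUOUS:Eutheria..Glires")
  expect_equal(classify_conservation(
    c(opossum = "UNCHANGED", armadillo = "UNTESTABLE", rabbit = "DOWN",
      guinea_pig = "DOWN", mouse = "DOWN"), sp, cl,
    untestable_as = "UNCHANGED"), "CONSERVED_Glires")
})

test_that("conservation labeling agrees with the brute-force oracle", {
  sp <- parse_newick(STUDY_TREE)
  cl <- study_clades()
  dirs <- c("UP", "DOWN", "UNCHANGED")
  grid <- expand.grid(rep(list(dirs), 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    d <- setNames(as.character(grid[i, ]), species5)
    expect_equal(classify_conservation(d, sp, cl),
                 oracle_conservation(d, sp, cl),
                 info = paste(d, collapse = ","))
  }
  # with MISSING entries sprinkled in
  set.seed(14)
  for (i in 1:300) {
    d <- setNames(sample(c(dirs, "MISSING"), 5, replace = TRUE), species5)
    expect_equal(classify_conservation(d, sp, cl),
                 oracle_conservation(d, sp, cl),
                 info = paste(d, collapse = ","))
  }
})

test_that("clade definitions must be monophyletic", {
  sp <- parse_newick(STUDY_TREE)
  d <- setNames(rep("UNCHANGED", 5), species5)
  expect_error(classify_conservation(d, sp, list(Bad = c("opossum", "mouse"))),
               "monophyletic")
  expect_error(classify_conservation(d, sp, list(One = "mouse")), ">= 2")
})

test_that("family profiling prunes the tree and recomputes presence", {
  sp_tree <- parse_newick(STUDY_TREE)
  fam <- simulate_gene_family(sp_tree, c(mouse = 2, rabbit = 1), family = "akr")
  genes <- fam$genes
  expr <- list(); de <- list()
  for (s in species5) {
    g <- genes$gene_id[genes$species == s]
    v <- matrix(50, length(g), 4,
                dimnames = list(g, paste0(s, "_", 1:4)))
    if (s == "opossum") v[1, ] <- c(10, 10, 10, 10)
    if (s == "mouse") v["mouse_akr2", ] <- c(2, 2, 2, 2.5)  # below 3 in all
    expr[[s]] <- expression_matrix(s, v, "TPM")
    de[[s]] <- fake_de(s, g, rep("UNCHANGED", length(g)))
    de[[s]]$fold_change <- 1
  }
  de$mouse$direction[de$mouse$gene == "mouse_akr1"] <- "UP"
  de$mouse$fold_change[de$mouse$gene == "mouse_akr1"] <- 3

  fp <- family_profile(fam$tree, genes, expr, de)
  expect_setequal(fp$tree$tip.label, fp$paralogs$gene_id)  # 1 row per leaf
  expect_false(fp$paralogs$expressed[fp$paralogs$gene_id == "mouse_akr2"])
  ss <- fp$species_summary
  expect_true(ss$any_paralog_up[ss$species == "mouse"])
  expect_false(ss$any_paralog_up[ss$species == "opossum"])  # fc ~ 1: unmodulated
  expect_false(any(ss$family_silent))

  # pruning to retained species drops the others' leaves
  fp2 <- family_profile(fam$tree, genes, expr, de,
                        species_keep = c("mouse", "opossum", "rabbit"))
  expect_setequal(unique(fp2$paralogs$species), c("mouse", "opossum", "rabbit"))
  renamed <- fp2$tree
  expect_true(ape::is.monophyletic(fp2$tree,
                                   genes$gene_id[genes$species == "mouse"]))

  # a leaf absent from the expression matrix is an error
  expr$mouse$values <- expr$mouse$values[-1, , drop = FALSE]
  expect_error(family_profile(fam$tree, genes, expr, de), "absent from")
})
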