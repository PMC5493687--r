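test_that("simulated counts match Poisson and NB moments", {
  # phi = 0 degenerates to Poisson: sample mean within 3 SE of the target
  cfg <- sim_config(species_tree = "(a,b);",
                    replicates = data.frame(species = rep(c("a", "b"), each = 3),
                                            stage = rep(STAGES, 2), n = 2),
                    n_orthogroups = 5000, private_frac = 0,
                    baseline_sdlog = 0, dispersion = 0, length_sdlog = 0,
                    depth_range = c(5e5, 5e5), seed = 3)
  b <- simulate_counts(cfg)
  x <- b$counts$a$counts[, 1]  # 5000 iid Poisson(mu = depth/n_genes = 100)
  mu <- 5e5 / 5000
  expect_lt(abs(mean(x) - mu), 3 * sqrt(mu / length(x)))
  expect_lt(abs(var(x) - mu), 4 * mu * sqrt(2 / length(x)))

  # NB: variance mu + phi mu^2
  cfg_nb <- sim_config(species_tree = "(a,b);",
                       replicates = data.frame(species = rep(c("a", "b"), each = 3),
                                               stage = rep(STAGES, 2), n = 2),
                       n_orthogroups = 5000, private_frac = 0,
                       baseline_sdlog = 0, dispersion = 0.2, length_sdlog = 0,
                       depth_range = c(5e5, 5e5), seed = 3)
  y <- simulate_counts(cfg_nb)$counts$a$counts[, 1]
  v_target <- mu + 0.2 * mu^2
  expect_lt(abs(mean(y) - mu), 3 * sqrt(v_target / length(y)))
  expect_lt(abs(var(y) / v_target - 1), 0.15)
})

test_that("planted log2 fold changes are realized in expectation", {
  eff <- lapply(1:200, function(i)
    planted_effect(paste0("e", i), sprintf("OG%05d", i), "a", "LG", 2))
  b <- simulate_counts(sim_config(species_tree = "(a,b);",
                    replicates = data.frame(species = rep(c("a", "b"), each = 3),
                                            stage = rep(STAGES, 2), n = 10),
                    n_orthogroups = 2000, private_frac = 0, baseline_sdlog = 0.3,
                    dispersion = 0.05, depth_range = c(1e6, 1e6),
                    effects = eff, seed = 4))
  des <- b$design[b$design$species == "a", ]
  mg <- as.character(des$sample[des$stage == "MG"])
  lg <- as.character(des$sample[des$stage == "LG"])
  tpm <- compute_tpm(b$counts$a)$values
  genes <- paste0("a_", sprintf("OG%05d", 1:200))
  ratio <- rowMeans(tpm[genes, lg]) / rowMeans(tpm[genes, mg])
  null_genes <- paste0("a_", sprintf("OG%05d", 1001:2000))
  null_ratio <- rowMeans(tpm[null_genes, lg]) / rowMeans(tpm[null_genes, mg])
  # TPM is compositional: planting 200 genes up 4x inflates the LG
  # denominator for every gene, so the planted-to-null ratio of realized
  # LG/MG ratios is the quantity that equals 2^log2fc in expectation
  rel <- mean(log(ratio)) - mean(log(null_ratio))
  se_rel <- sqrt(var(log(ratio)) / length(ratio) +
                 var(log(null_ratio)) / length(null_ratio))
  expect_lt(abs(rel - log(4)), 3 * se_rel)
  # and the null genes all see the same denominator inflation
  expect_lt(mean(null_ratio), 1)
  expect_lt(abs(mean(null_ratio) - 2000 / (1800 + 200 * 4)), 0.05)
})

test_that("identical seeds give bit-identical bundles", {
  cfg <- function() sim_config(n_orthogroups = 100, seed = 42)
  b1 <- simulate_counts(cfg())
  b2 <- simulate_counts(cfg())
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$orthomap, b2$orthomap)
  b3 <- simulate_counts(sim_config(n_orthogroups = 100, seed = 43))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("effects referencing unknown species or stages are config errors", {
  expect_error(planted_effect("e", "OG00001", "mouse", "XX", 1), "stage")
  eff <- list(planted_effect("e", "OG00001", "dragon", "LG", 1))
  expect_error(simulate_counts(sim_config(n_orthogroups = 10, effects = eff)),
               "unknown species")
  eff2 <- list(planted_effect("e", "OG99999", "mouse", "LG", 1))
  expect_error(simulate_counts(sim_config(n_orthogroups = 10, effects = eff2)),
               "unknown orthogroup")
})

test_that("gene family simulation respects the duplication spec", {
  sp_tree <- parse_newick(STUDY_TREE)
  f0 <- simulate_gene_family(sp_tree, integer(0))
  expect_equal(length(f0$tree$tip.label), 5L)
  expect_equal(nrow(f0$genes), 5L)
  # isomorphic to the species tree after renaming genes back to species
  renamed <- f0$tree
  renamed$tip.label <- f0$genes$species[match(renamed$tip.label, f0$genes$gene_id)]
  expect_equal(ape::dist.topo(ape::unroot(renamed), ape::unroot(sp_tree)), 0,
               ignore_attr = TRUE)

  f1 <- simulate_gene_family(sp_tree, c(mouse = 1))
  mg <- f1$genes$gene_id[f1$genes$species == "mouse"]
  expect_length(mg, 2L)
  expect_setequal(ape::extract.clade(f1$tree, ape::getMRCA(f1$tree, mg))$tip.label, mg)

  f2 <- simulate_gene_family(sp_tree, c(armadillo = 1, rabbit = 2,
                                        guinea_pig = 1, mouse = 2))
  n_per <- table(f2$genes$species)
  expect_equal(unname(n_per["opossum"]), 1L)  # outgroup stays single-copy
  expect_true(all(n_per[c("armadillo", "rabbit", "guinea_pig", "mouse")] >= 2L))

  expect_error(simulate_gene_family(sp_tree, c(dragon = 1)), "unknown lineage")
  expect_error(simulate_gene_family(sp_tree, c(mouse = -1)), ">= 0")
})

test_that("the default study fixture has the documented structure", {
  b <- default_study_fixture(seed = 1)
  tab <- table(b$design$species, b$design$stage)
  expect_equal(sum(tab == 1L), 1L)  # exactly one single-replicate cell
  expect_equal(tab["armadillo", "LG"], 1L, ignore_attr = TRUE)
  expect_true(all(tab[tab != 1L] == 3L))

  # every planted effect is enumerated in the ground truth
  expect_true(all(c("srd5a1_like", "pgr_like") %in% b$truth$effect_id))
  clade <- b$truth[b$truth$class == "clade_down", ]
  expect_equal(sort(unique(clade$species)), c("guinea_pig", "mouse", "rabbit"))
  expect_true(all(table(clade$target) == 3L))  # present in exactly 3 species

  # bundle passes the datamodel validations by construction
  expect_s3_class(b$orthomap, "OrthologMap")
  for (cm in b$counts) expect_s3_class(cm, "CountMatrix")
  # armadillo MISSING entries for half the clade orthogroups
  expect_equal(sum(is.na(b$orthomap$armadillo)), 10L)
})
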