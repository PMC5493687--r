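#' Simulation configuration for the multi-species count generator
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `mu_gs = depth_s * a_g(stage) * l_g / sum_j a_j(stage) * l_j` and variance
#' `mu + phi * mu^2`, where `a_g` is the gene's relative abundance on the TPM
#' scale (log-normal baseline times any planted effect multiplier) and `l_g`
#' its length. `phi = 0` degenerates to Poisson. Planted effects are
#' multiplicative on the TPM scale before count sampling, so ground-truth
#' fold changes are exact in expectation. Library depths are drawn
#' log-uniformly over a 2x range so that TPM normalization genuinely matters.
#'
#' @param species_tree Newick string for the species phylogeny.
#' @param replicates Data frame (species, stage, n) of replicate counts; all
#'   n >= 1.
#' @param n_orthogroups Number of background one-to-one orthologous genes.
#' @param private_frac Fraction (of `n_orthogroups`) of additional
#'   species-private genes per species, which exercise ortholog restriction.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   relative abundance (TPM scale).
#' @param dispersion Negative-binomial dispersion `phi >= 0`.
#' @param depth_range Library-size range (log-uniform draw).
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   (bp); lengths are shared across orthologs of a group.
#' @param effects List of effects from [planted_effect()].
#' @param baseline_override Named numeric vector (orthogroup id -> baseline
#'   TPM) pinning specific genes to known expression levels instead of a
#'   log-normal draw (used for analogue genes whose abundance the study
#'   system specifies).
#' @param dispersion_override Named numeric vector (orthogroup id -> phi)
#'   giving specific genes their own dispersion (used for analogue genes
#'   whose reported test statistics imply lower biological noise than the
#'   generic default).
#' @param missing Named list: species -> orthogroup ids absent from that
#'   species' annotation (the gene is dropped and the map entry is MISSING).
#' @param extra_genes Named list: species -> data frame (gene_id, baseline,
#'   length) of extra private genes (used for simulated gene families).
#' @param seed Integer seed governing every draw.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(species_tree = STUDY_TREE,
                       replicates = NULL,
                       n_orthogroups = 2000, private_frac = 0.2,
                       baseline_meanlog = log(50), baseline_sdlog = 1.2,
                       dispersion = 0.1, depth_range = c(1e6, 2e6),
                       length_meanlog = log(1500), length_sdlog = 0.4,
                       effects = list(), missing = list(),
                       extra_genes = list(), baseline_override = numeric(0),
                       dispersion_override = numeric(0), seed = 1) {
  tree <- parse_newick(species_tree)
  species <- tree$tip.label
  if (is.null(replicates))
    replicates <- expand.grid(species = species, stage = STAGES, n = 3,
                              stringsAsFactors = FALSE)
  stopifnot(all(replicates$n >= 1), dispersion >= 0,
            all(is.finite(c(baseline_meanlog, baseline_sdlog, depth_range,
                            length_meanlog, length_sdlog))),
            length(depth_range) == 2L, depth_range[1L] > 0)
  bad_sp <- setdiff(unique(replicates$species), species)
  if (length(bad_sp)) stop("replicates reference unknown species: ",
                           paste(bad_sp, collapse = ", "))
  structure(list(species_tree = species_tree, species = species,
                 replicates = replicates, n_orthogroups = n_orthogroups,
                 private_frac = private_frac,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 depth_range = depth_range, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, effects = effects,
                 missing = missing, extra_genes = extra_genes,
                 baseline_override = baseline_override,
                 dispersion_override = dispersion_override,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Default species tree of the study system
#'
#' Opossum (marsupial outgroup), armadillo, and the Glires clade
#' (rabbit, guinea pig, mouse).
#' @export
STUDY_TREE <- "(opossum,(armadillo,(rabbit,(guinea_pig,mouse))));"

#' Declare a planted expression effect
#'
#' The multiplier `2^log2fc` is applied to the gene's relative abundance in
#' the given stage (all other stages keep baseline), in every listed species.
#'
#' @param id Effect identifier.
#' @param target Orthogroup id (e.g. `"OG0001"`) or, with
#'   `target_type = "gene"`, a species-level gene id.
#' @param species Character vector of species carrying the effect.
#' @param stage Stage whose abundance is multiplied (one of NP, MG, LG).
#' @param log2fc Log2 fold change.
#' @param class Free-text effect class used in the ground-truth table.
#' @param target_type `"orthogroup"` or `"gene"`.
#' @export
planted_effect <- function(id, target, species, stage, log2fc,
                           class = "effect",
                           target_type = c("orthogroup", "gene")) {
  target_type <- match.arg(target_type)
  if (!stage %in% STAGES) stop("effect ", id, ": unknown stage ", stage)
  list(id = id, target = target, species = species, stage = stage,
       log2fc = log2fc, class = class, target_type = target_type)
}

#' Simulate multi-species stage-structured RNA-seq counts
#'
#' @param config A [sim_config()].
#' @return List with `counts` (named list of [count_matrix()] per species),
#'   `design` (`StageDesign`), `orthomap` (`OrthologMap` over the background
#'   orthogroups), `truth` (data frame of planted species-level effects),
#'   `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  for (e in config$effects) {
    bad <- setdiff(e$species, config$species)
    if (length(bad)) stop("effect ", e$id, " references unknown species: ",
                          paste(bad, collapse = ", "))
  }
  set.seed(config$seed)
  species <- config$species
  n_og <- config$n_orthogroups
  og_ids <- sprintf("OG%05d", seq_len(n_og))
  baseline_og <- stats::rlnorm(n_og, config$baseline_meanlog, config$baseline_sdlog)
  length_og <- pmax(200, round(stats::rlnorm(n_og, config$length_meanlog,
                                             config$length_sdlog)))
  names(baseline_og) <- names(length_og) <- og_ids
  if (length(config$baseline_override)) {
    bad <- setdiff(names(config$baseline_override), og_ids)
    if (length(bad)) stop("baseline override for unknown orthogroup: ",
                          paste(bad, collapse = ", "))
    baseline_og[names(config$baseline_override)] <- config$baseline_override
  }
  if (length(config$dispersion_override)) {
    bad <- setdiff(names(config$dispersion_override), og_ids)
    if (length(bad)) stop("dispersion override for unknown orthogroup: ",
                          paste(bad, collapse = ", "))
    if (any(config$dispersion_override < 0)) stop("dispersion must be >= 0")
  }

  # ortholog map: one gene per species per orthogroup, minus declared missing
  genes <- as.data.frame(stats::setNames(
    lapply(species, function(sp) paste0(sp, "_", og_ids)), species),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (sp in names(config$missing)) {
    bad <- setdiff(config$missing[[sp]], og_ids)
    if (length(bad)) stop("missing spec references unknown orthogroup: ",
                          paste(bad, collapse = ", "))
    genes[[sp]][og_ids %in% config$missing[[sp]]] <- NA_character_
  }
  orthomap <- ortholog_map(og_ids, genes)

  n_priv <- round(config$private_frac * n_og)
  design <- do.call(rbind, lapply(species, function(sp) {
    reps <- config$replicates[config$replicates$species == sp, , drop = FALSE]
    do.call(rbind, lapply(STAGES, function(st) {
      n <- reps$n[reps$stage == st]
      if (length(n) == 0L) return(NULL)
      data.frame(species = sp, sample = paste0(sp, "_", st, seq_len(n)),
                 stage = st, replicate = seq_len(n), stringsAsFactors = FALSE)
    }))
  }))
  design <- stage_design(design)

  # per-(gene, species, stage) log2 multipliers from the effect list
  counts <- list()
  truth_rows <- list()
  for (sp in species) {
    gene_ids <- paste0(sp, "_", og_ids)[!is.na(genes[[sp]])]
    baseline <- baseline_og[sub(paste0("^", sp, "_"), "", gene_ids)]
    lens <- length_og[sub(paste0("^", sp, "_"), "", gene_ids)]
    names(baseline) <- names(lens) <- gene_ids
    if (n_priv > 0L) {
      priv_ids <- sprintf("%s_p%04d", sp, seq_len(n_priv))
      baseline <- c(baseline, stats::setNames(
        stats::rlnorm(n_priv, config$baseline_meanlog, config$baseline_sdlog),
        priv_ids))
      lens <- c(lens, stats::setNames(
        pmax(200, round(stats::rlnorm(n_priv, config$length_meanlog,
                                      config$length_sdlog))), priv_ids))
    }
    xg <- config$extra_genes[[sp]]
    if (!is.null(xg)) {
      baseline <- c(baseline, stats::setNames(xg$baseline, xg$gene_id))
      lens <- c(lens, stats::setNames(xg$length, xg$gene_id))
    }
    lfc <- matrix(0, length(baseline), length(STAGES),
                  dimnames = list(names(baseline), STAGES))
    for (e in config$effects) {
      if (!sp %in% e$species) next
      gid <- if (e$target_type == "orthogroup") {
        if (!e$target %in% og_ids) stop("effect ", e$id,
                                        ": unknown orthogroup ", e$target)
        genes[[sp]][og_ids == e$target]
      } else e$target
      if (is.na(gid) || !gid %in% rownames(lfc)) next  # gene absent here
      lfc[gid, e$stage] <- lfc[gid, e$stage] + e$log2fc
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        effect_id = e$id, class = e$class, target = e$target, gene = gid,
        species = sp, stage = e$stage, log2fc = e$log2fc,
        stringsAsFactors = FALSE)
    }
    sdes <- design[design$species == sp, , drop = FALSE]
    depth <- exp(stats::runif(nrow(sdes), log(config$depth_range[1L]),
                              log(config$depth_range[2L])))
    phi <- stats::setNames(rep(config$dispersion, length(baseline)),
                           names(baseline))
    if (length(config$dispersion_override)) {
      ov_gid <- paste0(sp, "_", names(config$dispersion_override))
      hit <- ov_gid %in% names(phi)
      phi[ov_gid[hit]] <- config$dispersion_override[hit]
    }
    pois <- phi == 0
    m <- matrix(0, length(baseline), nrow(sdes),
                dimnames = list(names(baseline), sdes$sample))
    for (j in seq_len(nrow(sdes))) {
      a <- baseline * 2^lfc[, as.character(sdes$stage[j])]
      w <- a * lens
      mu <- depth[j] * w / sum(w)
      if (any(pois)) m[pois, j] <- stats::rpois(sum(pois), mu[pois])
      if (any(!pois)) m[!pois, j] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                                    size = 1 / phi[!pois])
    }
    counts[[sp]] <- count_matrix(sp, m, lens)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(effect_id = character(0))
  list(counts = counts, design = design, orthomap = orthomap,
       truth = truth, config = config)
}

#' Simulate a gene family tree by lineage-specific duplications
#'
#' Each species' single ancestral family gene is expanded by the requested
#' number of duplications on that terminal branch, yielding a within-species
#' paralog clade (a cherry for one duplication, a caterpillar for more). A
#' lineage with zero duplications keeps exactly one gene, so the gene tree of
#' a zero-duplication family is isomorphic to the species tree.
#'
#' @param species_tree `phylo` species tree.
#' @param duplications Named integer vector: species -> number of terminal
#'   duplications (>= 0). Species omitted get 0.
#' @param family Family name used in gene ids (`<species>_<family><k>`).
#' @return List with `tree` (gene `phylo`) and `genes` (data frame species,
#'   gene_id).
#' @export
simulate_gene_family <- function(species_tree, duplications = integer(0),
                                 family = "fam") {
  stopifnot(inherits(species_tree, "phylo"))
  bad <- setdiff(names(duplications), species_tree$tip.label)
  if (length(bad)) stop("duplication on unknown lineage: ",
                        paste(bad, collapse = ", "))
  if (any(duplications < 0)) stop("duplication counts must be >= 0")
  nwk <- ape::write.tree(species_tree)
  rows <- list()
  for (sp in species_tree$tip.label) {
    k <- if (sp %in% names(duplications)) duplications[[sp]] else 0L
    ids <- paste0(sp, "_", family, seq_len(k + 1L))
    sub <- ids[length(ids)]
    if (k > 0L) for (i in rev(seq_len(k)))
      sub <- paste0("(", ids[i], ",", sub, ")")
    nwk <- gsub(paste0("(?<![A-Za-z0-9_.])", sp, "(?![A-Za-z0-9_.])"),
                sub, nwk, perl = TRUE)
    rows[[sp]] <- data.frame(species = sp, gene_id = ids,
                             stringsAsFactors = FALSE)
  }
  list(tree = parse_newick(nwk), genes = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Default synthetic study bundle
#'
#' Five species (opossum outgroup, armadillo, rabbit, guinea pig, mouse),
#' three stages (NP/MG/LG) with three replicates each except a single
#' late-gestation armadillo sample, ~2,000 background orthologous genes plus
#' ~20% species-private genes, and planted effects mirroring the study
#' system's qualitative findings:
#' \itemize{
#'   \item a mouse-private late-gestation up-regulation (steroid-reductase
#'     analogue, log2FC +2);
#'   \item a guinea-pig-only 50\% mid-to-late decline (progesterone-receptor
#'     analogue, log2FC -1);
#'   \item 20 Glires-conserved late declines (coactivator analogues,
#'     log2FC -2), half of them unmapped (MISSING) in armadillo;
#'   \item 50 generic single-species |log2FC| = 2 effects (25 up in mouse,
#'     25 down in rabbit) for power assessment;
#'   \item 300 shared NP-vs-pregnant shifts (|log2FC| = 1.5 at NP in all
#'     species) driving the pronounced non-pregnant/pregnant
#'     sample-correlation split, with mid- and late-gestation samples
#'     remaining highly similar;
#'   \item an aldo-keto-reductase-like gene family with a single opossum
#'     gene, lineage-specific eutherian duplications, and one paralog
#'     up-regulated toward term in mouse, rabbit and armadillo (none in
#'     guinea pig, none in opossum).
#' }
#'
#' @param seed Integer seed.
#' @return The [simulate_counts()] bundle plus `family` (gene tree and
#'   membership from [simulate_gene_family()]) and `clades` (named species
#'   sets: Glires, Eutheria, Theria).
#' @export
default_study_fixture <- function(seed = 1) {
  tree <- parse_newick(STUDY_TREE)
  reps <- expand.grid(species = tree$tip.label, stage = STAGES, n = 3,
                      stringsAsFactors = FALSE)
  reps$n[reps$species == "armadillo" & reps$stage == "LG"] <- 1
  glires <- c("rabbit", "guinea_pig", "mouse")

  ncoa_og <- sprintf("OG%05d", 101:120)
  power_up_og <- sprintf("OG%05d", 201:225)
  power_dn_og <- sprintf("OG%05d", 251:275)
  np_og <- sprintf("OG%05d", 301:600)
  effects <- c(
    list(planted_effect("srd5a1_like", "OG00001", "mouse", "LG", 2,
                        class = "species_specific_up"),
         planted_effect("pgr_like", "OG00002", "guinea_pig", "LG", -1,
                        class = "species_specific_down")),
    lapply(seq_along(ncoa_og), function(i)
      planted_effect(paste0("ncoa_like_", i), ncoa_og[i], glires, "LG", -2,
                     class = "clade_down")),
    lapply(seq_along(power_up_og), function(i)
      planted_effect(paste0("power_up_", i), power_up_og[i], "mouse", "LG", 2,
                     class = "power_up")),
    lapply(seq_along(power_dn_og), function(i)
      planted_effect(paste0("power_down_", i), power_dn_og[i], "rabbit", "LG", -2,
                     class = "power_down")),
    lapply(seq_along(np_og), function(i)
      planted_effect(paste0("np_shift_", i), np_og[i], tree$tip.label, "NP",
                     if (i %% 2 == 0) 1.5 else -1.5, class = "np_shift"))
  )

  fam <- simulate_gene_family(
    tree, c(armadillo = 1, rabbit = 2, guinea_pig = 1, mouse = 2),
    family = "akr")
  extra <- lapply(split(fam$genes, fam$genes$species), function(df)
    data.frame(gene_id = df$gene_id, baseline = 30,
               length = 1200, stringsAsFactors = FALSE))
  fam_up <- c(mouse = "mouse_akr1", rabbit = "rabbit_akr1",
              armadillo = "armadillo_akr1")
  effects <- c(effects, lapply(names(fam_up), function(sp)
    planted_effect(paste0("family_up_", sp), fam_up[[sp]], sp, "LG", 2,
                   class = "family_up", target_type = "gene")))

  cfg <- sim_config(
    species_tree = STUDY_TREE, replicates = reps, n_orthogroups = 2000,
    private_frac = 0.2, dispersion = 0.1, effects = effects,
    missing = list(armadillo = ncoa_og[1:10]),
    extra_genes = extra,
    # analogue genes sit at the expression levels the study system reports:
    # the reductase analogue reaches ~200 TPM in late-gestation mouse
    # (baseline 50 x 2^2), the receptor analogue is highly expressed
    # (~400 TPM) in every species
    baseline_override = c(OG00001 = 50, OG00002 = 400),
    # their reported stage profiles are clean (strongly significant tests at
    # n = 3), implying much lower biological noise than the generic default
    dispersion_override = c(OG00001 = 0.01, OG00002 = 0.01),
    seed = seed)
  bundle <- simulate_counts(cfg)
  bundle$family <- fam
  bundle$clades <- list(Glires = glires,
                        Eutheria = c("armadillo", glires),
                        Theria = tree$tip.label)
  bundle$species_tree <- tree
  bundle
}
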