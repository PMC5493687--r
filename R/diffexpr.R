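#' Per-gene, per-stage mean expression
#'
#' @param expr TPM-scale `ExpressionMatrix`.
#' @param design `StageDesign` covering the matrix's samples.
#' @param stages Stages to average; every requested stage must have >= 1
#'   sample for this species.
#' @return Numeric matrix, genes x stages, of arithmetic mean TPM.
#' @export
stage_means <- function(expr, design, stages = STAGES) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  design <- design[design$sample %in% colnames(expr$values), , drop = FALSE]
  out <- matrix(NA_real_, nrow(expr$values), length(stages),
                dimnames = list(rownames(expr$values), stages))
  for (st in stages) {
    ids <- as.character(design$sample[design$stage == st])
    if (length(ids) == 0L) stop("stage with 0 samples: ", st)
    out[, st] <- rowMeans(expr$values[, ids, drop = FALSE])
  }
  out
}

#' Fold change between two stage means
#'
#' `(mean_num + pseudocount) / (mean_den + pseudocount)`; the default
#' pseudocount of 1 TPM keeps the ratio finite and positive for silent genes.
#'
#' @param means Stage-mean matrix from [stage_means()], or a named vector for
#'   one gene.
#' @param numerator_stage,denominator_stage Stage names; default LG over MG,
#'   the central late-over-mid-gestation contrast.
#' @param pseudocount Non-negative TPM offset added to both means.
#' @return Positive fold changes (NA where both means and the pseudocount are
#'   zero).
#' @export
fold_change <- function(means, numerator_stage = "LG", denominator_stage = "MG",
                        pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  if (is.null(dim(means))) means <- matrix(means, 1L, dimnames = list(NULL, names(means)))
  if (!all(c(numerator_stage, denominator_stage) %in% colnames(means)))
    stop("stage not present in means: need ", numerator_stage, " and ", denominator_stage)
  num <- means[, numerator_stage] + pseudocount
  den <- means[, denominator_stage] + pseudocount
  fc <- num / den
  fc[num == 0 & den == 0] <- NA_real_
  fc
}

#' Classical one-way fixed-effects ANOVA on a single gene
#'
#' Run on square-root transformed TPM. Degenerate cases follow documented
#' conventions: all observations identical gives an undefined p (`NA`); zero
#' within-group variance with non-zero between-group variance gives
#' `F = Inf, p = 0` (perfect separation).
#'
#' @param values Numeric vector (one gene's sqrt-TPM across samples).
#' @param groups Factor of group labels, >= 2 levels.
#' @return List with `statistic` (F), `p_value`, `df` (c(k-1, n-k)).
#' @export
anova_oneway <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups")
  n <- length(values)
  stopifnot(length(groups) == n)
  df1 <- k - 1L; df2 <- n - k
  if (df2 < 1L) stop("need total n >= k + 1")
  if (stats::var(values) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, df = c(df1, df2)))
  within_ss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0)
    return(list(statistic = Inf, p_value = 0, df = c(df1, df2)))
  a <- stats::anova(stats::lm(values ~ groups))
  list(statistic = a[["F value"]][1L], p_value = a[["Pr(>F)"]][1L],
       df = c(df1, df2))
}

#' Student (pooled-variance) t-test between two groups
#'
#' One-tailed p-values halve the two-tailed p when the observed effect sign
#' matches the stated alternative. Welch's unequal-variance variant is
#' available via `welch = TRUE`.
#'
#' @param x,y Numeric vectors (sqrt-TPM), each with >= 2 observations for a
#'   defined p-value.
#' @param tails 1 or 2.
#' @param alternative For `tails = 1`: `"greater"` (mean(x) > mean(y)) or
#'   `"less"`.
#' @param welch Use Welch's unequal-variance test instead of pooled variance.
#' @return List with `statistic` (t), `p_value` (`NA` when a group has < 2
#'   observations), `df`.
#' @export
t_test <- function(x, y, tails = 2, alternative = c("greater", "less"),
                   welch = FALSE) {
  stopifnot(tails %in% c(1, 2))
  if (length(x) < 2L || length(y) < 2L)
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_real_))
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(statistic = 0, p_value = if (tails == 2) 1 else 0.5,
                df = length(x) + length(y) - 2))
  alt <- if (tails == 2) "two.sided" else match.arg(alternative)
  ht <- stats::t.test(x, y, alternative = alt, var.equal = !welch)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Kruskal-Wallis rank test on a single gene
#'
#' Ties handled by midranks with the standard tie correction; p from the
#' chi-square approximation with k-1 degrees of freedom. As a rank statistic
#' it is invariant under strictly monotone transforms, so TPM and sqrt-TPM
#' give identical results.
#'
#' @param values Numeric vector.
#' @param groups Factor of group labels.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1, df = nlevels(groups) - 1L))
  ht <- stats::kruskal.test(values, groups)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Expression-presence calls
#'
#' `ANY_SAMPLE`: a gene is called expressed when its maximum TPM over samples
#' is strictly above the threshold (the "above 3 TPM in at least one sample"
#' convention). `ALL_SAMPLES`: the minimum must be strictly above.
#'
#' @param expr TPM-scale `ExpressionMatrix`.
#' @param threshold Non-negative TPM threshold.
#' @param rule `"ANY_SAMPLE"` or `"ALL_SAMPLES"`.
#' @return Named logical vector per gene.
#' @export
call_expressed <- function(expr, threshold = 3,
                           rule = c("ANY_SAMPLE", "ALL_SAMPLES")) {
  stopifnot(inherits(expr, "ExpressionMatrix"), threshold >= 0)
  rule <- match.arg(rule)
  if (expr$scale != "TPM") stop("presence calls are defined on the TPM scale")
  stat <- if (rule == "ANY_SAMPLE") apply(expr$values, 1L, max)
          else apply(expr$values, 1L, min)
  stat > threshold
}

#' Discrete direction call from fold change and p-value
#'
#' UP when `fc >= fc_min` and `p < alpha` (raw, uncorrected p — the pipeline
#' applies no multiple-testing correction anywhere); DOWN symmetrically at
#' `fc <= 1/fc_min`; otherwise UNCHANGED. When p is undefined (single
#' replicate stage) and the fold-change-only fallback is enabled, the call is
#' made from fc alone and flagged `unsupported_by_test`; with the fallback
#' off, such genes are UNTESTABLE.
#'
#' @param fc Positive fold change(s).
#' @param p P-value(s), `NA` = undefined.
#' @param fc_min Fold-change cutoff > 1 (default 1.5).
#' @param alpha Significance level in (0, 1).
#' @param fc_only_fallback Enable the fold-change-only fallback.
#' @return Data frame with columns `direction` (UP/DOWN/UNCHANGED/UNTESTABLE)
#'   and `unsupported_by_test` (logical).
#' @export
call_direction <- function(fc, p, fc_min = 1.5, alpha = 0.05,
                           fc_only_fallback = FALSE) {
  if (fc_min <= 1) stop("fc_min must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(length(fc) == length(p))
  if (any(!is.na(fc) & fc <= 0)) stop("fold changes must be positive")
  dir <- rep("UNCHANGED", length(fc))
  flag <- rep(FALSE, length(fc))
  tested <- !is.na(p)
  dir[tested & fc >= fc_min & p < alpha] <- "UP"
  dir[tested & fc <= 1 / fc_min & p < alpha] <- "DOWN"
  if (fc_only_fallback) {
    dir[!tested & !is.na(fc) & fc >= fc_min] <- "UP"
    dir[!tested & !is.na(fc) & fc <= 1 / fc_min] <- "DOWN"
    flag[!tested] <- TRUE
  } else {
    dir[!tested] <- "UNTESTABLE"
  }
  dir[is.na(fc) & is.na(p)] <- "UNTESTABLE"
  data.frame(direction = dir, unsupported_by_test = flag,
             stringsAsFactors = FALSE)
}

#' Per-gene stage-contrast differential expression table
#'
#' Statistical tests run on square-root transformed TPM (the
#' variance-stabilized scale); stage means, fold changes and presence calls
#' stay on the TPM scale. A gene's p-value is undefined when any tested group
#' has fewer than two replicates; the armadillo-style single-replicate stage
#' is then handled by the fold-change-only fallback if enabled.
#'
#' @param expr TPM-scale `ExpressionMatrix` for one species.
#' @param design `StageDesign`.
#' @param test `"anova"` (all stages), `"t_two_tailed"`, `"t_one_tailed"`
#'   (contrast stages only) or `"kruskal_wallis"`.
#' @param contrast Character pair `c(denominator, numerator)` for the fold
#'   change; default MG -> LG.
#' @param fc_min,alpha,pseudocount,fc_only_fallback See [call_direction()]
#'   and [fold_change()].
#' @param one_tailed_alternative Direction of the one-tailed alternative for
#'   the numerator stage relative to the denominator stage.
#' @return `DEResult` data frame: species, gene, per-stage means, fold
#'   change, test, statistic, p_value, direction, unsupported_by_test.
#' @export
de_table <- function(expr, design,
                     test = c("anova", "t_two_tailed", "t_one_tailed",
                              "kruskal_wallis"),
                     contrast = c("MG", "LG"), fc_min = 1.5, alpha = 0.05,
                     pseudocount = 1, fc_only_fallback = TRUE,
                     one_tailed_alternative = c("greater", "less")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "TPM") stop("de_table expects TPM input (it transforms internally)")
  test <- match.arg(test)
  one_tailed_alternative <- match.arg(one_tailed_alternative)
  design <- design[design$sample %in% colnames(expr$values), , drop = FALSE]
  design <- design[as.character(design$species) == expr$species_id, , drop = FALSE]
  stages_here <- intersect(STAGES, as.character(unique(design$stage)))
  means <- stage_means(expr, design, stages = stages_here)
  fc <- fold_change(means, numerator_stage = contrast[2L],
                    denominator_stage = contrast[1L], pseudocount = pseudocount)
  sq <- sqrt(expr$values)
  if (test == "anova" || test == "kruskal_wallis") {
    grp_stages <- stages_here
  } else {
    grp_stages <- contrast
  }
  samp <- as.character(design$sample[as.character(design$stage) %in% grp_stages])
  grp <- factor(as.character(design$stage)[match(samp, design$sample)],
                levels = grp_stages)
  tab <- table(grp)
  # a test's p is defined whenever the test itself can run: the k-group tests
  # tolerate singleton groups (one group with >=2 replicates suffices), the
  # two-group t-tests need both groups at n >= 2
  p_defined <- if (test %in% c("anova", "kruskal_wallis"))
    length(tab) >= 2L && any(tab >= 2L) && sum(tab) - length(tab) >= 1L
  else all(tab >= 2L)
  stat <- p <- rep(NA_real_, nrow(sq))
  if (p_defined) {
    den_ids <- samp[grp == contrast[1L]]
    num_ids <- samp[grp == contrast[2L]]
    for (i in seq_len(nrow(sq))) {
      v <- sq[i, samp]
      res <- switch(test,
        anova = anova_oneway(v, grp),
        kruskal_wallis = kruskal_wallis(expr$values[i, samp], grp),
        t_two_tailed = t_test(sq[i, num_ids], sq[i, den_ids], tails = 2),
        t_one_tailed = t_test(sq[i, num_ids], sq[i, den_ids], tails = 1,
                              alternative = one_tailed_alternative))
      stat[i] <- res$statistic
      p[i] <- res$p_value
    }
  }
  calls <- call_direction(fc, p, fc_min = fc_min, alpha = alpha,
                          fc_only_fallback = fc_only_fallback)
  out <- data.frame(species = expr$species_id, gene = rownames(expr$values),
                    stringsAsFactors = FALSE)
  for (st in stages_here) out[[paste0("mean_", st)]] <- means[, st]
  out$fold_change <- unname(fc)
  out$test <- test
  out$statistic <- stat
  out$p_value <- p
  out$direction <- calls$direction
  out$unsupported_by_test <- calls$unsupported_by_test
  class(out) <- c("DEResult", "data.frame")
  out
}
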