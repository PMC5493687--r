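#' Compute TPM, optionally restricted to a gene subset
#'
#' TPM for gene i is `1e6 * (c_i / l_i) / sum_j (c_j / l_j)` with the sum taken
#' over the declared gene universe only. When a subset (typically the genes
#' with one-to-one orthologs across all study species) is supplied, genes
#' outside it are excluded from both the numerator candidates and the
#' normalizer, which makes relative abundances comparable across species with
#' different annotation sizes. Mean TPM over N genes is then exactly 1e6/N.
#'
#' @param counts A [count_matrix()] object.
#' @param gene_subset Optional character vector of gene ids; must be a subset
#'   of the genes in `counts`. `NULL` uses the full per-species universe.
#' @return An `ExpressionMatrix`: list with `species_id`, `values` (genes x
#'   samples), `scale = "TPM"`, and `ortholog_restricted` flag.
#' @export
compute_tpm <- function(counts, gene_subset = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  restricted <- !is.null(gene_subset)
  if (restricted) {
    gene_subset <- unique(as.character(gene_subset))
    if (length(gene_subset) == 0L) stop("empty gene subset")
    extra <- setdiff(gene_subset, rownames(counts$counts))
    if (length(extra) > 0L)
      stop("gene subset contains ids absent from the count matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
  } else {
    gene_subset <- rownames(counts$counts)
  }
  c_sub <- counts$counts[gene_subset, , drop = FALSE]
  rates <- c_sub / counts$gene_lengths[gene_subset]
  denom <- colSums(rates)
  zero <- which(denom == 0)
  if (length(zero) > 0L)
    stop("sample with zero total length-normalized counts over the subset: ",
         paste(colnames(c_sub)[zero], collapse = ", "))
  vals <- sweep(rates, 2L, denom, "/") * 1e6
  expression_matrix(counts$species_id, vals, scale = "TPM",
                    ortholog_restricted = restricted)
}

#' Construct a validated expression matrix
#'
#' @param species_id Species identifier.
#' @param values Non-negative numeric matrix, genes x samples.
#' @param scale `"TPM"` or `"SQRT_TPM"`.
#' @param ortholog_restricted Whether the gene universe was restricted to
#'   one-to-one orthologs before normalization.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(species_id, values, scale = c("TPM", "SQRT_TPM"),
                              ortholog_restricted = FALSE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (any(is.na(values)) || any(values < 0)) stop("expression values must be >= 0")
  structure(list(species_id = species_id, values = values, scale = scale,
                 ortholog_restricted = ortholog_restricted),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s] %s%s: %d genes x %d samples\n",
              x$species_id, x$scale,
              if (x$ortholog_restricted) " (ortholog-restricted)" else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Square-root transform an expression matrix
#'
#' The square root is used as the variance-stabilizing transform for TPM:
#' unlike the log it maps 0 to 0, so zero-abundance genes need no pseudocount,
#' and it does not inflate variance at low abundances.
#'
#' @param expr A TPM-scale `ExpressionMatrix`.
#' @return An `ExpressionMatrix` with `scale = "SQRT_TPM"`.
#' @export
sqrt_transform <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr$scale != "TPM") stop("sqrt_transform expects a TPM-scale matrix")
  out <- expr
  out$values <- sqrt(expr$values)
  out$scale <- "SQRT_TPM"
  out
}

#' Pearson correlations between samples
#'
#' Computed on the shared gene universe of the matrix, by convention on
#' sqrt-TPM values (the scale on which correlations are variance-stabilized).
#'
#' @param expr `ExpressionMatrix` with >= 2 samples.
#' @return A symmetric correlation matrix (class `CorrelationMatrix`) with
#'   unit diagonal.
#' @export
sample_correlation <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (ncol(v) < 2L) stop("need >= 2 samples for a correlation matrix")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample column: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  r <- stats::cor(v, method = "pearson")
  diag(r) <- 1
  class(r) <- c("CorrelationMatrix", class(r))
  r
}

#' Flag poor-quality samples by mean within-species correlation
#'
#' A sample is flagged when its mean Pearson correlation to all other samples
#' of the same species falls below `min_mean_r`. This operationalizes outlier
#' elimination by within-species comparison; with fewer than three samples an
#' outlier cannot be distinguished from mere pair disagreement, so flagging is
#' skipped with a warning.
#'
#' @param corr `CorrelationMatrix` for the samples of one species.
#' @param design `StageDesign` rows for those samples (used for reporting).
#' @param min_mean_r Threshold on the mean correlation; default 0.5 on
#'   sqrt-TPM, a deliberately conservative default since no principled value
#'   exists.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_poor_samples <- function(corr, design, min_mean_r = 0.5) {
  ids <- colnames(corr)
  sp <- unique(as.character(design$species[design$sample %in% ids]))
  if (length(sp) > 1L) stop("flag_poor_samples expects samples from one species")
  if (ncol(corr) < 3L) {
    warning("fewer than 3 samples; outlier flagging skipped")
    return(character(0))
  }
  mean_r <- (rowSums(corr) - 1) / (ncol(corr) - 1L)
  ids[mean_r < min_mean_r]
}
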