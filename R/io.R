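#' Construct a validated per-species count matrix
#'
#' A `CountMatrix` holds raw gene-level read counts for one species together
#' with the per-gene lengths needed for TPM normalization. Counts are
#' non-negative integers; lengths are positive and given in base pairs
#' (TPM is invariant to the length unit, but the unit is fixed for file-format
#' clarity).
#'
#' @param species_id Single species identifier string.
#' @param counts Integer matrix, genes x samples, with unique rownames
#'   (gene ids) and unique colnames (sample ids).
#' @param gene_lengths Named numeric vector of positive gene lengths (bp);
#'   must cover every gene in `counts`.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(species_id, counts, gene_lengths) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id in counts: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id in counts")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("non-integer count encountered (counts must be raw read counts)")
  storage.mode(counts) <- "double"  # keeps exact integers, avoids int overflow
  missing_len <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing_len) > 0L)
    stop("genes without a length entry: ", paste(utils::head(missing_len, 5), collapse = ", "))
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0))
    stop("every gene length must be a positive number")
  structure(
    list(species_id = species_id, counts = counts, gene_lengths = gene_lengths),
    class = "CountMatrix"
  )
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix [%s]: %d genes x %d samples\n",
              x$species_id, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a per-species count table and gene-length table
#'
#' Count TSV layout: `gene_id<TAB>sample1<TAB>...` with a header row; lengths
#' TSV layout: `gene_id<TAB>length_bp`. Genes present in the count table but
#' absent from the lengths table are an error.
#'
#' @param path Count TSV path.
#' @param lengths_path Gene-length TSV path.
#' @param species_id Species identifier attached to the result.
#' @return A [count_matrix()] object.
#' @export
read_count_table <- function(path, lengths_path, species_id) {
  tab <- read_tsv_checked(path)
  if (ncol(tab) < 2L) stop("count table needs a gene id column plus >=1 sample column: ", path)
  gene_ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(tab[, -1L, drop = FALSE], 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric count cell in ", path,
         if (length(bad)) paste0(" (first at data line ", bad[1L, 1L], ")") else "")
  }
  rownames(m) <- gene_ids
  lt <- read_tsv_checked(lengths_path)
  if (ncol(lt) != 2L) stop("lengths table must have exactly two columns: ", lengths_path)
  lens <- stats::setNames(as.numeric(lt[[2L]]), as.character(lt[[1L]]))
  count_matrix(species_id, m, lens)
}

#' Read a sample design table
#'
#' Layout: `species<TAB>sample<TAB>stage<TAB>replicate`. Stages are restricted
#' to the three-level factor NP (non-pregnant), MG (mid-gestation),
#' LG (late gestation).
#'
#' @param path Design TSV path.
#' @return A `StageDesign` data frame with columns species, sample, stage,
#'   replicate.
#' @export
read_design <- function(path) {
  tab <- read_tsv_checked(path)
  names(tab) <- c("species", "sample", "stage", "replicate")[seq_len(ncol(tab))]
  stage_design(tab)
}

#' Validate a stage design table
#'
#' @param df Data frame with columns species, sample, stage, replicate.
#' @return The validated data frame, classed `StageDesign`, with `stage` as a
#'   factor with levels NP, MG, LG.
#' @export
stage_design <- function(df) {
  need <- c("species", "sample", "stage", "replicate")
  if (!all(need %in% names(df))) stop("design needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  bad <- setdiff(unique(as.character(df$stage)), STAGES)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), " (allowed: NP, MG, LG)")
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in design: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  df$stage <- factor(as.character(df$stage), levels = STAGES)
  class(df) <- c("StageDesign", "data.frame")
  df
}

#' Stage levels used throughout the pipeline
#' @export
STAGES <- c("NP", "MG", "LG")

#' Read a one-to-one ortholog map
#'
#' One row per orthogroup; the first column is the orthogroup id, one further
#' column per species. Empty cells, `NA` and `-` all denote a species with no
#' mapped ortholog (common export dialects). Within an orthogroup there is at
#' most one gene per species, and a gene id may appear in only one orthogroup.
#'
#' @param path Ortholog TSV path.
#' @param species_ids Species column names expected in the file.
#' @return An `OrthologMap`: data frame with column `orthogroup` plus one
#'   character column per species, `NA` marking MISSING entries.
#' @export
read_ortholog_map <- function(path, species_ids) {
  tab <- read_tsv_checked(path, colClasses = "character")
  if (!all(species_ids %in% names(tab)))
    stop("ortholog map lacks species column(s): ",
         paste(setdiff(species_ids, names(tab)), collapse = ", "))
  ortholog_map(tab[[1L]], tab[species_ids])
}

#' Construct a validated ortholog map
#'
#' @param orthogroup_ids Character vector of orthogroup ids.
#' @param genes Data frame (one column per species) of gene ids; `NA`, `""`
#'   and `"-"` are MISSING.
#' @return `OrthologMap` data frame.
#' @export
ortholog_map <- function(orthogroup_ids, genes) {
  genes <- as.data.frame(lapply(genes, as.character), stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (s in names(genes)) genes[[s]][genes[[s]] %in% c("", "-", "NA")] <- NA_character_
  if (anyDuplicated(orthogroup_ids)) stop("duplicate orthogroup id")
  all_genes <- unlist(genes, use.names = FALSE)
  all_genes <- all_genes[!is.na(all_genes)]
  if (anyDuplicated(all_genes))
    stop("gene id assigned to more than one orthogroup: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  out <- cbind(data.frame(orthogroup = as.character(orthogroup_ids),
                          stringsAsFactors = FALSE), genes)
  class(out) <- c("OrthologMap", "data.frame")
  out
}

#' Species covered by an ortholog map
#' @param map An `OrthologMap`.
#' @return Character vector of species column names.
#' @export
map_species <- function(map) setdiff(names(map), "orthogroup")

#' Parse a Newick string into an `ape` phylo tree
#'
#' Unquoted labels must match `[A-Za-z0-9_.-]+`; quoted labels are supported
#' by the underlying parser. Leaf labels must be unique. The serialization of
#' the result re-parses to an isomorphic tree.
#'
#' @param text Newick string ending in a semicolon.
#' @return A rooted `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text))
    stop("Newick parse error: missing terminating semicolon (at position ",
         nchar(text), ")")
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("Newick parse error: unbalanced parentheses at position ", i)
  }
  if (depth != 0L) stop("Newick parse error: unbalanced parentheses (", depth,
                        " unclosed at end of string)")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: unreadable tree string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Read a Newick tree file
#' @param path File containing one Newick tree.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a phylo tree to Newick
#' @param tree `phylo` object.
#' @param path Optional output file; if `NULL` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a result table as TSV
#'
#' Fields containing a tab, newline or carriage return are rejected: the TSV
#' dialect used throughout is unescaped, so such fields cannot round-trip.
#'
#' @param rows Non-empty data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty table: ", path)
  for (cl in names(rows)) {
    v <- rows[[cl]]
    if (is.character(v) && any(grepl("[\t\n\r]", v)))
      stop("field in column '", cl, "' contains a tab/newline; unsupported in TSV output")
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CountMatrix (counts + lengths) to TSV files
#' @param cm `CountMatrix`.
#' @param path Count TSV path.
#' @param lengths_path Lengths TSV path.
#' @export
write_count_table <- function(cm, path, lengths_path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
  write_table(data.frame(gene_id = names(cm$gene_lengths),
                         length_bp = unname(cm$gene_lengths)), lengths_path)
  invisible(path)
}

#' Write an ortholog map to TSV (MISSING as "NA")
#' @param map `OrthologMap`.
#' @param path Output path.
#' @export
write_ortholog_map <- function(map, path) {
  out <- as.data.frame(map)
  for (s in map_species(map)) out[[s]][is.na(out[[s]])] <- "NA"
  write_table(out, path)
}

# Strict TSV reader: header row required, consistent field counts.
read_tsv_checked <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_fields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(n_fields) == 0L) stop("empty file: ", path)
  if (length(unique(n_fields)) != 1L)
    stop("malformed TSV ", path, ": inconsistent field count at line ",
         which(n_fields != n_fields[1L])[1L])
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = colClasses, stringsAsFactors = FALSE)
}
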