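#' Genotype matrix container
#'
#' Bundles a samples x variants dosage matrix (alternate-allele counts in
#' \{0, 1, 2\}, possibly with missing entries) with its variant metadata.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#'   Row names are sample identifiers, column names variant identifiers.
#' @param variants data.frame with at least \code{variant_id}, \code{chrom},
#'   \code{pos} (1-based basepairs). Optional columns \code{ref}, \code{alt},
#'   \code{maf}, \code{block_id}.
#' @return An object of class \code{GenotypeMatrix}: a list with elements
#'   \code{dosage} and \code{variants}.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)))
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in variant metadata")
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$variant_id
  if (!identical(colnames(dosage), as.character(variants$variant_id)))
    stop("dosage column names must match variants$variant_id (same order)")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, variants = variants),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants (%d chromosome(s))\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$variants$chrom))))
  invisible(x)
}

#' Molecular phenotype matrix container
#'
#' Holds a samples x phenotypes value matrix together with per-phenotype
#' metadata: the phenotype layer (\code{gene}, \code{exon}, \code{splice},
#' \code{protein}, \code{metabolite}), the genomic anchor (chromosome and
#' TSS; both \code{NA} for unanchored phenotypes such as metabolites), the
#' grouping id used for exon/splice phenotypes sharing a TSS, and strand.
#'
#' @param values Numeric matrix, samples in rows, phenotypes in columns;
#'   \code{NA} marks missing measurements.
#' @param meta data.frame with columns \code{phenotype_id}, \code{type} and
#'   optionally \code{chrom}, \code{tss}, \code{group_id}, \code{strand}.
#' @return An object of class \code{PhenotypeMatrix}.
#' @export
phenotype_matrix <- function(values, meta) {
  values <- as.matrix(values)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  stopifnot(all(c("phenotype_id", "type") %in% names(meta)))
  for (col in c("chrom", "tss", "group_id", "strand"))
    if (is.null(meta[[col]])) meta[[col]] <- rep(NA, nrow(meta))
  bad <- !meta$type %in% c("gene", "exon", "splice", "protein", "metabolite")
  if (any(bad))
    stop("unknown phenotype type(s): ", paste(unique(meta$type[bad]), collapse = ", "))
  if (anyDuplicated(meta$phenotype_id))
    stop("duplicate phenotype_id in metadata")
  if (is.null(colnames(values))) colnames(values) <- meta$phenotype_id
  if (ncol(values) > 0L &&
      !identical(colnames(values), as.character(meta$phenotype_id)))
    stop("values column names must match meta$phenotype_id (same order)")
  # tss present iff chrom present
  if (any(is.na(meta$chrom) != is.na(meta$tss)))
    stop("tss must be present exactly when chrom is present")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  structure(list(values = values, meta = meta), class = "PhenotypeMatrix")
}

#' @export
print.PhenotypeMatrix <- function(x, ...) {
  tab <- table(x$meta$type)
  cat(sprintf("PhenotypeMatrix: %d samples x %d phenotypes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Subset a GenotypeMatrix by variant ids, keeping metadata aligned.
#' @rdname genotype_matrix
#' @param x A \code{GenotypeMatrix}.
#' @param variant_ids Character vector of variants to keep (order preserved).
#' @export
geno_subset <- function(x, variant_ids) {
  stopifnot(inherits(x, "GenotypeMatrix"))
  idx <- match(variant_ids, x$variants$variant_id)
  if (anyNA(idx)) stop("unknown variant id(s)")
  genotype_matrix(x$dosage[, idx, drop = FALSE],
                  x$variants[idx, , drop = FALSE])
}
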