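# Text-format I/O: VCF 4.2 (GT only) for genotypes, a BED-like TSV for
# anchored phenotypes (half-open 0-based coordinates on output, 1-based
# internally), covariates as a covariate x sample TSV, and the planted truth
# as JSON.  Reading VCFs goes through vcfR; the writer is a minimal GT-only
# emitter so fixtures round-trip losslessly.

#' Write a genotype matrix as VCF 4.2
#'
#' Dosages 0/1/2 become GT fields 0/0, 0/1, 1/1; missing dosages become ./.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param path Output file path (plain text, uncompressed).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  v <- genotypes$variants
  D <- genotypes$dosage
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(D)), function(j) {
    calls <- ifelse(is.na(D[, j]), "./.", gt[D[, j] + 1L])
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
            if (is.null(v$ref)) "A" else v$ref[j],
            if (is.null(v$alt)) "G" else v$alt[j],
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Parses the GT field with vcfR and returns alternate-allele counts.
#'
#' @param path VCF file path.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_vcf_dosage <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(as.integer(a) > 0L), integer(1)))
  }
  D <- apply(gt, 2, count_alt)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1, dimnames = list(NULL, names(D)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  D <- t(D)                         # vcfR gives variants x samples
  colnames(D) <- variants$variant_id
  genotype_matrix(D, variants)
}

#' Write phenotypes as a BED-like TSV
#'
#' Columns: \code{#chr}, \code{start}, \code{end} (half-open, 0-based:
#' \code{start = tss - 1}, \code{end = tss}), \code{id}, \code{gid} (group
#' id), \code{strand}, \code{type}, then one column per sample.  Unanchored
#' phenotypes (metabolites) are written with sentinel chromosome \code{"NA"}
#' and coordinates 0/1.
#'
#' @param phenos A \code{\link{phenotype_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotype_bed <- function(phenos, path) {
  stopifnot(inherits(phenos, "PhenotypeMatrix"))
  meta <- phenos$meta
  tss <- ifelse(is.na(meta$tss), 1L, meta$tss)
  dt <- data.table(
    `#chr` = ifelse(is.na(meta$chrom), "NA", as.character(meta$chrom)),
    start = as.integer(tss) - 1L, end = as.integer(tss),
    id = meta$phenotype_id,
    gid = ifelse(is.na(meta$group_id), ".", as.character(meta$group_id)),
    strand = ifelse(is.na(meta$strand), ".", as.character(meta$strand)),
    type = meta$type)
  vals <- as.data.table(t(phenos$values))
  dt <- cbind(dt, vals)
  data.table::setnames(dt, c(names(dt)[1:7], rownames(phenos$values)))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a BED-like phenotype TSV
#'
#' @param path File written by \code{\link{write_phenotype_bed}}.
#' @return A \code{\link{phenotype_matrix}}.
#' @export
read_phenotype_bed <- function(path) {
  dt <- fread(path, sep = "\t")
  anno <- dt[, 1:7]
  vals <- t(as.matrix(dt[, -(1:7)]))
  colnames(vals) <- anno$id
  chrom <- as.character(anno[["#chr"]])
  chrom[chrom == "NA"] <- NA
  meta <- data.frame(phenotype_id = anno$id, type = anno$type,
                     chrom = chrom,
                     tss = ifelse(is.na(chrom), NA_integer_, anno$end),
                     group_id = ifelse(anno$gid == ".", NA, anno$gid),
                     strand = ifelse(anno$strand == ".", NA, anno$strand),
                     stringsAsFactors = FALSE)
  phenotype_matrix(vals, meta)
}

#' Write / read a covariate matrix TSV (rows = covariates)
#'
#' @param covariates Numeric matrix samples x covariates.
#' @param path File path.
#' @return \code{path} (write) or the samples x covariates matrix (read).
#' @export
write_covariates <- function(covariates, path) {
  M <- t(as.matrix(covariates))
  dt <- data.table(id = rownames(M))
  dt <- cbind(dt, as.data.table(M))
  data.table::setnames(dt, c("id", colnames(M)))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  dt <- fread(path, sep = "\t")
  M <- t(as.matrix(dt[, -1]))
  colnames(M) <- dt[[1]]
  M
}

#' Write a synthetic study's fixtures to a directory
#'
#' Emits \code{genotypes.vcf}, \code{phenotypes.bed}, \code{covariates.tsv}
#' and \code{truth.json}; all round-trip losslessly through the bundled
#' readers (dosage matrices exactly, real values at full write precision).
#'
#' @param genotypes,phenos,covariates,truth Study components (covariates and
#'   truth may be NULL).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the written paths.
#' @export
write_fixtures <- function(genotypes, phenos, covariates = NULL,
                           truth = NULL, out_dir) {
  if (!identical(rownames(genotypes$dosage), rownames(phenos$values)))
    stop("genotype and phenotype sample ids differ")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             bed = file.path(out_dir, "phenotypes.bed"),
             cov = file.path(out_dir, "covariates.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(genotypes, paths["vcf"])
  write_phenotype_bed(phenos, paths["bed"])
  if (!is.null(covariates)) write_covariates(covariates, paths["cov"])
  else paths <- paths[names(paths) != "cov"]
  if (!is.null(truth))
    write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
               na = "null")
  else paths <- paths[names(paths) != "truth"]
  paths
}
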