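# Typed SNP -> phenotype association networks.  Nodes are variants or
# molecular phenotypes, edges are deduplicated significant QTL records;
# connected components are found with union-find (path compression),
# component ids are deterministic (smallest member node id).

#' Build the SNP-phenotype regulatory network
#'
#' Combines significant QTL tables into a bipartite network: SNP nodes,
#' phenotype nodes typed by layer, and one edge per deduplicated (variant,
#' phenotype, association type) record keeping the best p.
#'
#' @param qtl_tables A data.frame, or list of data.frames, with columns
#'   \code{variant_id}, \code{phenotype_id}, \code{phenotype_type} (gene /
#'   protein / metabolite / exon / splice), \code{assoc_type} (e.g.
#'   \code{cis-e}, \code{trans-p}, \code{metabo}), \code{beta}, \code{p}.
#' @return Object of class \code{QTLNetwork}: list with \code{nodes}
#'   (\code{node_id}, \code{node_type}, \code{component_id}) and
#'   \code{edges} (\code{source}, \code{target}, \code{assoc_type},
#'   \code{beta}, \code{p}).
#' @export
build_network <- function(qtl_tables) {
  if (is.data.frame(qtl_tables)) qtl_tables <- list(qtl_tables)
  edges <- rbindlist(lapply(qtl_tables, as.data.table), fill = TRUE)
  req <- c("variant_id", "phenotype_id", "phenotype_type", "assoc_type",
           "beta", "p")
  stopifnot(all(req %in% names(edges)))
  bad <- !edges$phenotype_type %in%
    c("gene", "exon", "splice", "protein", "metabolite")
  if (any(bad)) stop("unknown phenotype type in QTL table")
  setorder(edges, p)
  edges <- edges[!duplicated(edges[, c("variant_id", "phenotype_id",
                                       "assoc_type")]), ]
  edges <- data.frame(source = edges$variant_id, target = edges$phenotype_id,
                      assoc_type = edges$assoc_type,
                      phenotype_type = edges$phenotype_type,
                      beta = edges$beta, p = edges$p,
                      stringsAsFactors = FALSE)
  snp_ids <- unique(edges$source)
  ph <- edges[!duplicated(edges$target), c("target", "phenotype_type")]
  nodes <- rbind(
    data.frame(node_id = snp_ids,
               node_type = rep("snp", length(snp_ids)),
               stringsAsFactors = FALSE),
    data.frame(node_id = ph$target,
               node_type = as.character(ph$phenotype_type),
               stringsAsFactors = FALSE))
  if (any(nodes$node_id[nodes$node_type == "snp"] %in% edges$target))
    stop("self-loop or SNP appearing as a phenotype target")
  nodes$component_id <- .components(nodes$node_id, edges$source, edges$target)
  structure(list(nodes = nodes, edges = edges), class = "QTLNetwork")
}

# Union-find with path compression; component labelled by its smallest
# member node id.
.components <- function(node_ids, from, to) {
  idx <- seq_along(node_ids)
  names(idx) <- node_ids
  parent <- idx
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  for (e in seq_along(from)) {
    a <- find(idx[[from[e]]]); b <- find(idx[[to[e]]])
    if (a != b) parent[b] <- a
  }
  root <- vapply(idx, find, integer(1))
  lab <- vapply(split(node_ids, root), min, character(1))
  unname(lab[as.character(root)])
}

#' @export
print.QTLNetwork <- function(x, ...) {
  tab <- table(x$nodes$node_type)
  cat(sprintf("QTLNetwork: %d nodes (%s), %d edges, %d components\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$edges), length(unique(x$nodes$component_id))))
  invisible(x)
}

#' Component sizes and degree statistics of a QTL network
#'
#' @param net A \code{\link{build_network}} result.
#' @return List: \code{component_sizes} (named, decreasing), \code{degree}
#'   (edges incident per node), \code{mean_degree} (2E/V) and
#'   \code{mean_neighbors} (mean count of distinct neighbor nodes, the
#'   alternative definition).
#' @export
components_and_degree <- function(net) {
  stopifnot(inherits(net, "QTLNetwork"))
  if (nrow(net$nodes) == 0L)
    return(list(component_sizes = integer(0), degree = integer(0),
                mean_degree = NaN, mean_neighbors = NaN))
  sizes <- sort(table(net$nodes$component_id), decreasing = TRUE)
  deg <- table(factor(c(net$edges$source, net$edges$target),
                      levels = net$nodes$node_id))
  nb <- c(split(net$edges$target, net$edges$source),
          split(net$edges$source, net$edges$target))
  nnb <- vapply(nb, function(v) length(unique(v)), integer(1))
  neighbors <- setNames(integer(nrow(net$nodes)), net$nodes$node_id)
  neighbors[names(nnb)] <- nnb
  list(component_sizes = sizes,
       degree = setNames(as.integer(deg), names(deg)),
       mean_degree = 2 * nrow(net$edges) / nrow(net$nodes),
       mean_neighbors = mean(neighbors))
}

#' Annotate SNP nodes with GWAS-catalog traits
#'
#' Flags SNP nodes that are lead GWAS variants and attaches a per-trait
#' count table (number of flagged SNPs per trait).
#'
#' @param net A \code{QTLNetwork}.
#' @param gwas data.frame with \code{variant_id}, \code{trait}, optional
#'   logical \code{is_lead} (default TRUE) and \code{exclusion_class}
#'   (molecular-trait GWAS entries to drop from enrichment tests, e.g.
#'   protein/metabolite-level GWAS).
#' @return The network with \code{gwas} (logical) and
#'   \code{gwas_excluded} columns on nodes and attribute
#'   \code{"trait_counts"}.
#' @export
annotate_gwas <- function(net, gwas) {
  stopifnot(inherits(net, "QTLNetwork"),
            all(c("variant_id", "trait") %in% names(gwas)))
  if (is.null(gwas$is_lead)) gwas$is_lead <- TRUE
  gwas <- gwas[gwas$is_lead, , drop = FALSE]
  snp <- net$nodes$node_type == "snp"
  net$nodes$gwas <- snp & net$nodes$node_id %in% gwas$variant_id
  excl_ids <- if (is.null(gwas$exclusion_class)) character(0) else
    gwas$variant_id[!is.na(gwas$exclusion_class) & gwas$exclusion_class != ""]
  net$nodes$gwas_excluded <- net$nodes$node_id %in% excl_ids
  flagged <- gwas[gwas$variant_id %in% net$nodes$node_id[net$nodes$gwas], ,
                  drop = FALSE]
  tab <- table(as.character(flagged$trait))
  counts <- data.frame(trait = as.character(names(tab)),
                       n_snps = as.integer(tab),
                       stringsAsFactors = FALSE)
  if (nrow(counts))
    counts <- counts[order(-counts$n_snps, counts$trait), , drop = FALSE]
  rownames(counts) <- NULL
  attr(net, "trait_counts") <- counts
  net
}

#' Connectivity tests for GWAS variants in the network
#'
#' Two-sided Wilcoxon rank-sum test of SNP out-degree, GWAS-flagged vs
#' unflagged, and per-layer Fisher enrichments of GWAS status against
#' being connected to each phenotype layer.  SNPs whose GWAS entry is a
#' molecular-trait study (\code{gwas_excluded}) are dropped from the layer
#' enrichments to avoid circularity.
#'
#' @param net An \code{\link{annotate_gwas}}-annotated network.
#' @return List: \code{wilcoxon_degree} (statistic, p_value),
#'   \code{layer_enrichment} (named list of
#'   \code{\link{fisher_enrichment}} results per layer present).
#' @export
gwas_connectivity_tests <- function(net) {
  stopifnot(inherits(net, "QTLNetwork"), !is.null(net$nodes$gwas))
  snp_nodes <- net$nodes[net$nodes$node_type == "snp", , drop = FALSE]
  if (sum(snp_nodes$gwas) < 2L || sum(!snp_nodes$gwas) < 2L)
    stop("need >= 2 GWAS-flagged and >= 2 unflagged SNP nodes")
  outdeg <- table(factor(net$edges$source, levels = snp_nodes$node_id))
  deg <- as.integer(outdeg)
  wt <- wilcox.test(deg[snp_nodes$gwas], deg[!snp_nodes$gwas], exact = FALSE)
  keep <- !snp_nodes$gwas_excluded
  layer_of <- split(net$edges$phenotype_type, net$edges$source)
  layers <- intersect(c("gene", "protein", "metabolite", "exon", "splice"),
                      unique(net$edges$phenotype_type))
  enr <- lapply(layers, function(ly) {
    hits <- vapply(snp_nodes$node_id,
                   function(id) ly %in% layer_of[[id]], logical(1))
    tab <- table(factor(snp_nodes$gwas[keep], c(TRUE, FALSE)),
                 factor(hits[keep], c(TRUE, FALSE)))
    tryCatch(fisher_enrichment(unclass(tab)), error = function(e) NULL)
  })
  names(enr) <- layers
  list(wilcoxon_degree = list(statistic = unname(wt$statistic),
                              p_value = wt$p.value),
       layer_enrichment = enr)
}

#' Export a network's node and edge tables
#'
#' Writes \code{nodes.tsv} and a Cytoscape-importable \code{edges.tsv}
#' (source, target, interaction, beta, p); the pair round-trips through
#' \code{\link{import_network}}.
#'
#' @param net A \code{QTLNetwork}.
#' @param out_dir Output directory.
#' @return Named paths, invisibly.
#' @export
export_network <- function(net, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nodes = file.path(out_dir, "nodes.tsv"),
             edges = file.path(out_dir, "edges.tsv"))
  fwrite(net$nodes, paths["nodes"], sep = "\t", quote = FALSE)
  ed <- data.frame(source = net$edges$source, target = net$edges$target,
                   interaction = net$edges$assoc_type,
                   phenotype_type = net$edges$phenotype_type,
                   beta = net$edges$beta, p = net$edges$p)
  fwrite(ed, paths["edges"], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' @rdname export_network
#' @param dir Directory holding \code{nodes.tsv} / \code{edges.tsv}.
#' @export
import_network <- function(dir) {
  ed <- fread(file.path(dir, "edges.tsv"), sep = "\t")
  build_network(data.frame(variant_id = ed$source, phenotype_id = ed$target,
                           phenotype_type = ed$phenotype_type,
                           assoc_type = ed$interaction, beta = ed$beta,
                           p = ed$p, stringsAsFactors = FALSE))
}
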