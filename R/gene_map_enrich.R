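#' Build gene regulatory domains (basal plus extension)
#'
#' Each gene gets a basal domain around its TSS — `basal_up` bp upstream and
#' `basal_down` bp downstream on the + strand, mirrored on the - strand —
#' extended outward in both directions up to `distal` bp, but never into a
#' neighbouring gene's basal domain (extensions stop at the nearest
#' neighbouring basal edge). Coordinates are 1-based inclusive; domains are
#' clipped at position 1. Duplicate gene symbols on one chromosome are
#' suffixed with a warning.
#'
#' @param genes data frame: gene, chr, strand ("+"/"-"), tss, start, end
#' @param basal_up,basal_down basal window sizes in bp (defaults 5000/1000)
#' @param distal maximum distal extension in bp (default 5000; the common
#'   1 Mb convention is available by setting `distal = 1e6`)
#' @return data frame: gene, chr, strand, tss, basal_start, basal_end,
#'   domain_start, domain_end
#' @export
build_domains <- function(genes, basal_up = 5000, basal_down = 1000,
                          distal = 5000) {
  g <- genes
  if (any(g$start > g$end)) stop("gene start must be <= end")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dup <- ave(seq_len(nrow(g)), g$chr, g$gene, FUN = seq_along)
  if (any(dup > 1)) {
    warning("duplicate gene symbols on one chromosome; suffixing")
    g$gene[dup > 1] <- paste0(g$gene[dup > 1], ".", dup[dup > 1])
  }
  plus <- g$strand == "+"
  g$basal_start <- ifelse(plus, g$tss - basal_up, g$tss - basal_down)
  g$basal_end <- ifelse(plus, g$tss + basal_down, g$tss + basal_up)
  g$basal_start <- pmax(g$basal_start, 1)

  g$domain_start <- pmax(g$basal_start - distal, 1)
  g$domain_end <- g$basal_end + distal
  for (i in seq_len(nrow(g))) {
    same <- which(g$chr == g$chr[i])
    same <- same[same != i]
    # nearest neighbouring basal edge on each side bounds the extension
    left_edges <- g$basal_end[same][g$basal_end[same] < g$basal_start[i]]
    if (length(left_edges))
      g$domain_start[i] <- max(g$domain_start[i], max(left_edges) + 1)
    right_edges <- g$basal_start[same][g$basal_start[same] > g$basal_end[i]]
    if (length(right_edges))
      g$domain_end[i] <- min(g$domain_end[i], min(right_edges) - 1)
  }
  g[, c("gene", "chr", "strand", "tss", "basal_start", "basal_end",
        "domain_start", "domain_end")]
}

#' Map probes to genes physically and by regulatory domain
#'
#' Physical mapping places a probe inside a gene body (start..end,
#' inclusive); regulatory mapping places it inside any regulatory domain
#' (see [build_domains()]); `union` deduplicates both. A probe may map to
#' several genes and all pairs are retained. If at least half the probes map
#' nowhere a genome-assembly mismatch warning is issued.
#'
#' @param probes data frame: probe_id, chr, pos (1-based)
#' @param genes gene-model data frame (gene, chr, start, end)
#' @param domains output of [build_domains()] (required for regulatory/union)
#' @param mode "physical", "regulatory" or "union" (default)
#' @return list: `pairs` data frame (probe_id, gene, mode), `genes` unique
#'   mapped gene symbols
#' @export
map_probes <- function(probes, genes, domains = NULL,
                       mode = c("union", "physical", "regulatory")) {
  mode <- match.arg(mode)
  gr_probes <- GenomicRanges::GRanges(
    probes$chr, IRanges::IRanges(probes$pos, probes$pos))
  overlap_pairs <- function(tab, start, end, label) {
    gr <- GenomicRanges::GRanges(tab$chr, IRanges::IRanges(start, end))
    hits <- GenomicRanges::findOverlaps(gr_probes, gr)
    data.frame(probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
               gene = tab$gene[S4Vectors::subjectHits(hits)],
               mode = label, stringsAsFactors = FALSE)
  }
  phys <- if (mode %in% c("physical", "union"))
    overlap_pairs(genes, genes$start, genes$end, "physical")
  else NULL
  reg <- if (mode %in% c("regulatory", "union")) {
    if (is.null(domains)) stop("regulatory mapping requires domains")
    overlap_pairs(domains, domains$domain_start, domains$domain_end, "regulatory")
  } else NULL
  pairs <- rbind(phys, reg)
  pairs <- pairs[!duplicated(pairs[, c("probe_id", "gene")]), , drop = FALSE]
  mapped <- unique(pairs$probe_id)
  if (nrow(probes) > 0 && length(mapped) < 0.5 * nrow(probes))
    warning("over half the probes map to no gene; check genome assembly")
  list(pairs = pairs, genes = sort(unique(pairs$gene)))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated)
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[[`, "", 1))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene list and each gene set, both intersected with the background, with
#' BH adjustment across sets. Results are sorted by adjusted p.
#'
#' @param query_genes character vector (must be a subset of the background)
#' @param gene_sets named list of character vectors (e.g. [read_gmt()])
#' @param background_genes the gene universe
#' @return data frame: set, overlap, set_size, query_size, background_size,
#'   p, p_adj
#' @export
enrich_gene_sets <- function(query_genes, gene_sets, background_genes) {
  bg <- unique(background_genes)
  if (length(bg) == 0) stop("empty background")
  q <- unique(intersect(query_genes, bg))
  if (length(setdiff(query_genes, bg)))
    warning("query genes outside the background were dropped")
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], bg)
    k <- length(intersect(q, s))
    p <- phyper(k - 1, length(s), length(bg) - length(s), length(q),
                lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(q), background_size = length(bg),
               p = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res[order(res$p_adj, res$p), , drop = FALSE]
}
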