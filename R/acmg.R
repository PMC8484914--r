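#' Load local annotation resources for CNV classification
#'
#' Local stand-ins for the online catalogs used in clinical CNV review:
#' a gene interval table (BED4: chrom, start, end, symbol), a
#' known-pathogenic region table and a common-benign region table (TSV
#' with header `chrom start end label min_overlap sign`; `sign` is
#' `dup`, `del` or `any`), plus an optional list of dosage-sensitive
#' gene symbols (one per line). All intervals are 0-based half-open.
#'
#' @param genes_bed path to the gene BED file.
#' @param pathogenic_tsv path to the pathogenic-region TSV.
#' @param benign_tsv path to the benign-region TSV.
#' @param dosage_genes_txt optional path listing dosage-sensitive gene
#'   symbols.
#' @return an `annotation_resources` list.
#' @export
load_resources <- function(genes_bed, pathogenic_tsv, benign_tsv,
                           dosage_genes_txt = NULL) {
  genes <- utils::read.table(genes_bed, header = FALSE, sep = "\t",
                             col.names = c("chrom", "start", "end", "symbol"),
                             stringsAsFactors = FALSE)
  path <- utils::read.table(pathogenic_tsv, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  ben <- utils::read.table(benign_tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dosage <- if (!is.null(dosage_genes_txt)) readLines(dosage_genes_txt) else character()
  annotation_resources(genes, path, ben, dosage)
}

#' Build annotation resources from data frames
#'
#' @param genes data.frame `chrom start end symbol`.
#' @param pathogenic_regions data.frame `chrom start end label min_overlap
#'   sign`.
#' @param benign_regions data.frame `chrom start end label min_overlap sign`.
#' @param dosage_genes character vector of dosage-sensitive symbols.
#' @return an `annotation_resources` list.
#' @export
annotation_resources <- function(genes, pathogenic_regions, benign_regions,
                                 dosage_genes = character()) {
  check_iv <- function(df, what) {
    if (nrow(df) && any(df$end <= df$start))
      stop("invalid interval in ", what)
    df
  }
  structure(list(genes = check_iv(genes, "genes"),
                 pathogenic_regions = check_iv(pathogenic_regions, "pathogenic_regions"),
                 benign_regions = check_iv(benign_regions, "benign_regions"),
                 dosage_genes = dosage_genes),
            class = "annotation_resources")
}

# 0-based half-open data.frame -> GRanges (1-based closed internally)
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Genes overlapped by an event
#'
#' Symbols of genes whose interval overlaps the event by at least 1 bp,
#' sorted by genomic position.
#'
#' @param event one event row (chrom, start_bp, end_bp).
#' @param resources an `annotation_resources`.
#' @return character vector of symbols.
#' @export
annotate_genes <- function(event, resources) {
  g <- resources$genes
  if (!nrow(g) || !event$chrom %in% g$chrom) return(character())
  ev <- GenomicRanges::GRanges(event$chrom,
                               IRanges::IRanges(event$start_bp + 1, event$end_bp))
  hits <- GenomicRanges::findOverlaps(ev, as_granges(g))
  idx <- S4Vectors::subjectHits(hits)
  idx <- idx[order(g$start[idx])]
  g$symbol[idx]
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

sign_matches <- function(region_sign, kind) {
  region_sign == "any" |
    (region_sign == "dup" & kind == "duplication") |
    (region_sign == "del" & kind == "deletion")
}

#' Five-tier clinical classification of a CNV event
#'
#' Overlap cascade against local knowledge tables, a desk-reproducible
#' reduction of guideline-based review:
#' 1. reciprocal overlap >= the region's `min_overlap` (default 0.5)
#'    with a pathogenic region of matching sign -> `pathogenic`;
#' 2. reciprocal overlap >= 0.25 with a pathogenic region, or fully
#'    containing a dosage-sensitive gene -> `likely pathogenic`;
#' 3. event fully inside a benign region of matching sign -> `benign`;
#' 4. reciprocal overlap >= 0.5 with a benign region and no gene content
#'    -> `likely benign`;
#' 5. otherwise -> `VOUS`.
#'
#' @param event one event row.
#' @param resources an `annotation_resources`.
#' @param genes optional precomputed [annotate_genes()] result.
#' @return one of `pathogenic`, `likely pathogenic`, `VOUS`,
#'   `likely benign`, `benign`.
#' @export
classify_tier <- function(event, resources, genes = NULL) {
  if (is.null(resources)) stop("annotation resources are required")
  if (is.null(genes)) genes <- annotate_genes(event, resources)
  s <- event$start_bp; e <- event$end_bp

  pa <- resources$pathogenic_regions
  if (nrow(pa)) {
    pa <- pa[pa$chrom == event$chrom & sign_matches(pa$sign, event$kind), , drop = FALSE]
    if (nrow(pa)) {
      ro <- reciprocal_overlap(s, e, pa$start, pa$end)
      thr <- ifelse(is.na(pa$min_overlap), 0.5, pa$min_overlap)
      if (any(ro >= thr)) return("pathogenic")
      if (any(ro >= 0.25)) return("likely pathogenic")
    }
  }
  if (length(resources$dosage_genes) && length(genes)) {
    g <- resources$genes
    contained <- g$symbol %in% resources$dosage_genes &
      g$chrom == event$chrom & g$start >= s & g$end <= e
    if (any(contained)) return("likely pathogenic")
  }
  be <- resources$benign_regions
  if (nrow(be)) {
    be <- be[be$chrom == event$chrom & sign_matches(be$sign, event$kind), , drop = FALSE]
    if (nrow(be)) {
      inside <- any(be$start <= s & be$end >= e)
      if (inside) return("benign")
      ro <- reciprocal_overlap(s, e, be$start, be$end)
      if (any(ro >= 0.5) && !length(genes)) return("likely benign")
    }
  }
  "VOUS"
}

#' Size class of a CNV event
#'
#' The three reporting bins for structural events: `<1 Mb` (size below
#' 10^6 bp), `1-10 Mb` (closed: 10^6 and 10^7 both belong here),
#' `>10 Mb`.
#'
#' @param size_bp event span in bp (> 0), or an event row.
#' @return character size class.
#' @export
size_class <- function(size_bp) {
  if (is.data.frame(size_bp)) size_bp <- size_bp$size_bp
  if (any(size_bp <= 0)) stop("event size must be positive")
  ifelse(size_bp < 1e6, "<1 Mb", ifelse(size_bp <= 1e7, "1-10 Mb", ">10 Mb"))
}

#' Tier and annotate a set of called events
#'
#' @param events event data.frame.
#' @param resources an `annotation_resources`.
#' @return the events with `tier`, `size_class` and `genes`
#'   (comma-separated symbols) columns appended.
#' @export
tier_events <- function(events, resources) {
  if (!nrow(events)) {
    events$tier <- character()
    events$size_class <- character()
    events$genes <- character()
    return(events)
  }
  res <- lapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    g <- annotate_genes(ev, resources)
    data.frame(tier = classify_tier(ev, resources, genes = g),
               size_class = size_class(ev$size_bp),
               genes = paste(g, collapse = ","))
  })
  cbind(events, do.call(rbind, res))
}
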