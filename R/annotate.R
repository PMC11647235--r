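# Candidate-gene annotation: Ensembl-dialect GTF loading and bedtools-style
# region/gene intersection (minimum overlap 1 bp, strand ignored).

#' Load protein-coding gene intervals from an Ensembl GTF
#'
#' Keeps only feature-type `gene` records with biotype `protein_coding` and
#' a `gene_name` attribute; everything else is discarded with a logged
#' count. Duplicate `gene_id` records are collapsed to one interval
#' spanning min(start)..max(end). Coordinates are GTF-native (1-based
#' inclusive); strand is ignored.
#'
#' @param path GTF file (Ensembl attribute dialect).
#' @return data.frame: `gene_id`, `gene_name`, `chrom`, `start_bp`,
#'   `end_bp`, `biotype`.
#' @export
loadGTF <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(regmatches(lines[body], gregexpr("\t", lines[body]))) + 1L
  if (any(nf != 9L))
    stop("malformed GTF record (expected 9 tab-separated fields) at line ",
         body[which(nf != 9L)[1L]])
  g <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  nIn <- nrow(g)
  if (is.null(g$type)) stop("GTF has no feature type column")
  if (is.null(g$gene_biotype)) g$gene_biotype <- NA_character_
  if (is.null(g$gene_name)) g$gene_name <- NA_character_
  keep <- g$type == "gene" & !is.na(g$gene_biotype) &
    g$gene_biotype == "protein_coding" & !is.na(g$gene_name) &
    nzchar(g$gene_name)
  message("loadGTF: retained ", sum(keep), " of ", nIn,
          " records (protein-coding genes with a gene_name)")
  g <- g[keep, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), start_bp = integer(),
                      end_bp = integer(), biotype = character()))
  out <- do.call(rbind, lapply(split(g, g$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1L], gene_name = d$gene_name[1L],
               chrom = as.character(d$seqnames[1L]),
               start_bp = min(d$start), end_bp = max(d$end),
               biotype = d$gene_biotype[1L])))
  rownames(out) <- NULL
  out[order(out$chrom, out$start_bp), ]
}

#' Intersect candidate regions with gene intervals
#'
#' A gene is reported for a region iff their 1-based inclusive intervals
#' share at least 1 bp (the `intersectBed` default); strand is ignored.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (e.g. the
#'   `regions` element of a [windowScan()] result).
#' @param genes data.frame from [loadGTF()].
#' @return list with `per_region` (region_id, chrom, region start/end,
#'   gene_name, gene_id, overlap_bp; one row per overlapping pair) and
#'   `genes` (deduplicated global gene list).
#' @export
intersectRegions <- function(regions, genes) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(regions)),
            all(c("chrom", "start_bp", "end_bp") %in% names(genes)))
  empty <- data.frame(region_id = integer(), chrom = character(),
                      region_start = integer(), region_end = integer(),
                      gene_name = character(), gene_id = character(),
                      overlap_bp = integer())
  if (!nrow(regions) || !nrow(genes))
    return(list(per_region = empty, genes = character()))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start_bp,
                                                regions$end_bp))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start_bp,
                                                genes$end_bp))
  hits <- GenomicRanges::findOverlaps(gr, gg, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(regions$end_bp[qi], genes$end_bp[si]) -
    pmax(regions$start_bp[qi], genes$start_bp[si]) + 1L
  per <- data.frame(
    region_id = qi, chrom = regions$chrom[qi],
    region_start = regions$start_bp[qi], region_end = regions$end_bp[qi],
    gene_name = genes$gene_name[si], gene_id = genes$gene_id[si],
    overlap_bp = ov)
  list(per_region = per[order(per$region_id, per$gene_id), ],
       genes = sort(unique(per$gene_name)))
}
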