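# GenomeAnnotation: gene models with strand, part intervals by class
# (CDS/UTR5/UTR3/intron/promoter), and enhancer->gene links. All coordinates
# 0-based half-open internally; GFF3 is converted at the I/O boundary.

.PART_CLASSES <- c("CDS", "UTR5", "UTR3", "intron", "promoter", "enhancer")

#' Construct a genome annotation
#'
#' Builds the internal gene-model container from gene spans and exon/CDS/UTR
#' part intervals. Introns are derived as the gene span minus its exons;
#' promoters are derived from the TSS using a strand-oriented window covering
#' `promoter_up` bases upstream and `promoter_down` bases downstream of the
#' TSS, clipped to the contig. On the plus strand the TSS is the span start;
#' on the minus strand it is the last base of the span.
#'
#' @param genes data.frame with columns `gene_id`, `contig`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open span).
#' @param parts data.frame with columns `gene_id`, `class` (one of `exon`,
#'   `CDS`, `UTR5`, `UTR3`), `start`, `end`.
#' @param contig_lengths named vector of contig lengths.
#' @param enhancers optional data.frame `enhancer_id`, `contig`, `start`,
#'   `end`.
#' @param links optional data.frame `enhancer_id`, `gene_id` (many-to-many).
#' @param promoter_up,promoter_down promoter window in bases (defaults 2000
#'   upstream, 200 downstream of the TSS).
#' @return object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(genes, parts, contig_lengths,
                              enhancers = NULL, links = NULL,
                              promoter_up = 2000, promoter_down = 200) {
  stopifnot(all(genes$strand %in% c("+", "-")),
            all(genes$end > genes$start),
            all(genes$contig %in% names(contig_lengths)))
  has_exons <- genes$gene_id %in% parts$gene_id[parts$class == "exon"]
  if (any(!has_exons)) {
    warning("skipping gene(s) with zero exons: ",
            paste(genes$gene_id[!has_exons], collapse = ", "))
    genes <- genes[has_exons, , drop = FALSE]
    parts <- parts[parts$gene_id %in% genes$gene_id, , drop = FALSE]
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)

  derived <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    p <- parts[parts$gene_id == g$gene_id, , drop = FALSE]
    ex <- p[p$class == "exon", c("start", "end"), drop = FALSE]
    span <- IRanges::IRanges(g$start + 1, g$end)
    introns <- .ir_to_mat(IRanges::setdiff(span, .mat_to_ir(as.matrix(ex))))
    L <- contig_lengths[[g$contig]]
    if (g$strand == "+") {
      pr <- c(g$tss - promoter_up, g$tss + promoter_down)
    } else {
      pr <- c(g$tss - promoter_down + 1, g$tss + promoter_up + 1)
    }
    pr <- c(max(0, pr[1]), min(L, pr[2]))
    rbind(
      if (nrow(introns) > 0)
        data.frame(gene_id = g$gene_id, class = "intron",
                   start = introns[, 1], end = introns[, 2]),
      if (pr[2] > pr[1])
        data.frame(gene_id = g$gene_id, class = "promoter",
                   start = pr[1], end = pr[2]))
  })
  parts <- rbind(parts[, c("gene_id", "class", "start", "end")],
                 do.call(rbind, derived))
  parts$contig <- genes$contig[match(parts$gene_id, genes$gene_id)]

  cds_len <- tapply(parts$end[parts$class == "CDS"] -
                      parts$start[parts$class == "CDS"],
                    parts$gene_id[parts$class == "CDS"], sum)
  bad <- names(cds_len)[cds_len %% 3 != 0]
  if (length(bad) > 0)
    warning("CDS length not divisible by 3 (partial?): ",
            paste(bad, collapse = ", "))

  if (is.null(enhancers))
    enhancers <- data.frame(enhancer_id = character(0), contig = character(0),
                            start = integer(0), end = integer(0))
  if (is.null(links))
    links <- data.frame(enhancer_id = character(0), gene_id = character(0))
  structure(list(genes = genes,
                 parts = parts[, c("gene_id", "contig", "class",
                                   "start", "end")],
                 enhancers = enhancers, links = links,
                 contig_lengths = contig_lengths,
                 promoter_window = c(up = promoter_up, down = promoter_down)),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes, %d enhancers on %d contig(s)\n",
              nrow(x$genes), nrow(x$enhancers), length(x$contig_lengths)))
  invisible(x)
}

#' Part intervals of one class, as a ConstrainedSet-style interval set
#'
#' For `class = "enhancer"` the enhancer catalog is returned; for gene part
#' classes the union over all genes (or one gene) is returned.
#'
#' @param ann a `GenomeAnnotation`.
#' @param class one of `CDS`, `UTR5`, `UTR3`, `intron`, `promoter`,
#'   `enhancer`, `exon`.
#' @param gene_id optional gene restriction (ignored for `enhancer` unless
#'   linked; linked enhancers of that gene are returned).
#' @return a `ConstrainedSet` holding the base union of the parts.
#' @export
ann_part_set <- function(ann, class, gene_id = NULL) {
  if (class == "enhancer") {
    e <- ann$enhancers
    if (!is.null(gene_id)) {
      ids <- ann$links$enhancer_id[ann$links$gene_id == gene_id]
      e <- e[e$enhancer_id %in% ids, , drop = FALSE]
    }
    return(constrained_set(data.frame(contig = e$contig, start = e$start,
                                      end = e$end)))
  }
  p <- ann$parts[ann$parts$class == class, , drop = FALSE]
  if (!is.null(gene_id)) p <- p[p$gene_id %in% gene_id, , drop = FALSE]
  constrained_set(data.frame(contig = p$contig, start = p$start, end = p$end))
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; BED12 is native. For GFF3 the reader expects
#' gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR features
#' linked by `Parent`; one transcript per gene is assumed (the first is
#' taken). For BED12 each record is one gene: blocks are exons and the thick
#' range is the CDS.
#'
#' @param path GFF3 (`.gff3`/`.gff`) or BED12 (`.bed`) file.
#' @param contig_lengths named vector of contig lengths.
#' @param promoter_up,promoter_down promoter window, see
#'   [genome_annotation()].
#' @return a `GenomeAnnotation` (without enhancers; attach those via
#'   [read_enhancers()]).
#' @export
read_annotation <- function(path, contig_lengths,
                            promoter_up = 2000, promoter_down = 200) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    return(.read_annotation_bed12(path, contig_lengths,
                                  promoter_up, promoter_down))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p)
    if (length(p) == 0) NA_character_ else p[[1]], character(1))
  contig <- as.character(GenomicRanges::seqnames(gr))
  start0 <- IRanges::start(gr) - 1L
  end0 <- IRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))

  gi <- type == "gene"
  genes <- data.frame(gene_id = id[gi], contig = contig[gi],
                      strand = strand[gi], start = start0[gi], end = end0[gi])
  # transcript -> gene map (features may also attach directly to the gene)
  ti <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(parent[ti], id[ti])
  owner <- ifelse(parent %in% genes$gene_id, parent,
                  unname(tx2gene[parent]))
  cls <- c(exon = "exon", CDS = "CDS", five_prime_UTR = "UTR5",
           three_prime_UTR = "UTR3")
  pi <- type %in% names(cls) & !is.na(owner)
  parts <- data.frame(gene_id = owner[pi], class = unname(cls[type[pi]]),
                      start = start0[pi], end = end0[pi])
  genome_annotation(genes, parts, contig_lengths,
                    promoter_up = promoter_up, promoter_down = promoter_down)
}

.read_annotation_bed12 <- function(path, contig_lengths, promoter_up,
                                   promoter_down) {
  gr <- rtracklayer::import(path, format = "BED")
  md <- S4Vectors::mcols(gr)
  contig <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  genes <- data.frame(gene_id = md$name, contig = contig,
                      strand = strand,
                      start = IRanges::start(gr) - 1L, end = IRanges::end(gr))
  parts <- do.call(rbind, lapply(seq_along(gr), function(i) {
    bl <- md$blocks[[i]] # exon offsets relative to gene start, 1-based
    ex_s <- genes$start[i] + IRanges::start(bl) - 1L
    ex_e <- genes$start[i] + IRanges::end(bl)
    th <- md$thick[i]
    cds_s <- IRanges::start(th) - 1L; cds_e <- IRanges::end(th)
    ex <- data.frame(gene_id = genes$gene_id[i], class = "exon",
                     start = ex_s, end = ex_e)
    cds <- NULL; utr <- NULL
    if (cds_e > cds_s) {
      ci <- .ir_to_mat(IRanges::intersect(
        .mat_to_ir(cbind(ex_s, ex_e)),
        IRanges::IRanges(cds_s + 1, cds_e)))
      if (nrow(ci) > 0)
        cds <- data.frame(gene_id = genes$gene_id[i], class = "CDS",
                          start = ci[, 1], end = ci[, 2])
      ui <- .ir_to_mat(IRanges::setdiff(.mat_to_ir(cbind(ex_s, ex_e)),
                                        IRanges::IRanges(cds_s + 1, cds_e)))
      if (nrow(ui) > 0) {
        five <- if (strand[i] == "+") ui[, 2] <= cds_s else ui[, 1] >= cds_e
        utr <- data.frame(gene_id = genes$gene_id[i],
                          class = ifelse(five, "UTR5", "UTR3"),
                          start = ui[, 1], end = ui[, 2])
      }
    }
    rbind(ex, cds, utr)
  }))
  genome_annotation(genes, parts, contig_lengths,
                    promoter_up = promoter_up, promoter_down = promoter_down)
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS / UTR features (one transcript per gene),
#' converting internal 0-based half-open coordinates to GFF3 1-based
#' inclusive. Derived classes (intron, promoter) are not written; they are
#' re-derived on read.
#'
#' @param ann a `GenomeAnnotation`.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gfftype <- c(exon = "exon", CDS = "CDS", UTR5 = "five_prime_UTR",
               UTR3 = "three_prime_UTR")
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tx <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tck\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start + 1, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tck\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$contig, g$start + 1, g$end, g$strand, tx,
                       g$gene_id), con)
    p <- ann$parts[ann$parts$gene_id == g$gene_id &
                     ann$parts$class %in% names(gfftype), , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 0) {
      writeLines(sprintf("%s\tck\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
                         g$contig, gfftype[p$class], p$start + 1, p$end,
                         g$strand, ifelse(p$class == "CDS", "0", "."), tx),
                 con)
    }
  }
  invisible(path)
}

#' Read enhancer intervals and enhancer-gene links
#'
#' @param bed_path BED file of enhancer intervals (name column = enhancer id).
#' @param links_path TSV with header columns `enhancer_id`, `gene_id`.
#' @param ann a `GenomeAnnotation` to attach them to.
#' @return the annotation with enhancers and links replaced.
#' @export
read_enhancers <- function(ann, bed_path, links_path) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  ann$enhancers <- data.frame(
    enhancer_id = S4Vectors::mcols(gr)$name,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr) - 1L, end = IRanges::end(gr))
  ann$links <- read.table(links_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ann
}
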