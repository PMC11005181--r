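#' @importFrom utils read.delim write.table
#' @importFrom rtracklayer import export
#' @importFrom GenomicRanges GRanges sort findOverlaps mid
#' @importFrom IRanges IRanges
NULL

# All on-disk interval formats are 0-based half-open (BED convention); the
# in-memory representation is GRanges (1-based closed). Conversion happens
# exactly once, here.

#' Read a gene annotation (TSV or GTF-like)
#'
#' TSV input needs columns `gene_id`, `chrom`, `strand`, `tss` (0-based).
#' GTF-like input is parsed with rtracklayer and the TSS of each gene is the
#' most 5' annotated transcript start on the gene's strand (minimum start on
#' `+`, maximum end on `-`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gtf"`; guessed from the extension by default.
#' @return `GRanges` of width-1 TSS positions, sorted by (chrom, tss), with
#'   metadata columns `gene_id` and `class_label` (filled with
#'   "unclassified" when absent from the file).
#' @export
readGeneAnnotation <- function(path, format = c("auto", "tsv", "gtf")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
            "gtf" else "tsv"
    if (format == "gtf") {
        gr <- rtracklayer::import(path)
        gr <- gr[gr$type %in% c("transcript", "mRNA", "exon")]
        if (!length(gr)) stop("no transcript features in ", path)
        tssPos <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
        df <- data.frame(gene_id = gr$gene_id,
                         chrom = as.character(seqnames(gr)),
                         strand = as.character(strand(gr)),
                         pos = tssPos)
        most5 <- function(d)
            if (d$strand[1] == "-") max(d$pos) else min(d$pos)
        agg <- do.call(rbind, lapply(split(df, df$gene_id), function(d)
            data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                       strand = d$strand[1], tss1 = most5(d))))
        ann <- GRanges(agg$chrom, IRanges(agg$tss1, width = 1L),
                       strand = agg$strand, gene_id = agg$gene_id,
                       class_label = "unclassified")
    } else {
        tab <- read.delim(path, stringsAsFactors = FALSE)
        need <- c("gene_id", "chrom", "strand", "tss")
        if (!all(need %in% names(tab)))
            stop("annotation TSV must have columns: ",
                 paste(need, collapse = ", "))
        bad <- which(is.na(suppressWarnings(as.numeric(tab$tss))) |
                         tab$tss < 0 | tab$gene_id == "" | is.na(tab$gene_id))
        if (length(bad))
            stop("malformed annotation row at line ", bad[1] + 1L)
        badStrand <- which(!tab$strand %in% c("+", "-"))
        if (length(badStrand))
            stop("unknown strand symbol '", tab$strand[badStrand[1]],
                 "' at line ", badStrand[1] + 1L)
        ann <- GRanges(tab$chrom, IRanges(as.numeric(tab$tss) + 1L, width = 1L),
                       strand = tab$strand, gene_id = tab$gene_id,
                       class_label = if ("class_label" %in% names(tab))
                           tab$class_label else "unclassified")
    }
    if (anyDuplicated(ann$gene_id))
        stop("duplicated gene_id: ",
             paste(unique(ann$gene_id[duplicated(ann$gene_id)]),
                   collapse = ", "))
    GenomicRanges::sort(ann, ignore.strand = TRUE)
}

#' Write a gene annotation TSV (0-based TSS)
#' @param ann `GRanges` as returned by [readGeneAnnotation()].
#' @param path output path.
#' @export
writeGeneAnnotation <- function(ann, path) {
    write.table(data.frame(gene_id = ann$gene_id,
                           chrom = as.character(seqnames(ann)),
                           strand = as.character(strand(ann)),
                           tss = start(ann) - 1L,
                           class_label = ann$class_label),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read intervals from a BED file
#'
#' Thin validation wrapper over `rtracklayer::import`: rejects empty
#' intervals, sorts unsorted input (with a log message) and preserves extra
#' columns as metadata.
#'
#' @param path BED3+ file (0-based half-open).
#' @param extraCols named character vector passed to `rtracklayer::import`
#'   for non-standard columns (name = column, value = class).
#' @return sorted `GRanges`.
#' @export
readRegionsBed <- function(path, extraCols = character()) {
    gr <- tryCatch(
        rtracklayer::import(path, format = "BED", extraCols = extraCols),
        error = function(e) stop("malformed BED in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (any(width(gr) < 1L))
        stop("BED interval with end <= start in ", path)
    srt <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    if (!identical(ranges(srt), ranges(gr)))
        message("readRegionsBed: input not sorted; sorted on load")
    srt
}

#' Read TAD intervals from BED, rejecting overlaps
#'
#' @param path BED file of TAD intervals.
#' @return `GRanges` with a `tad_id` column (taken from the BED name field
#'   when present, generated otherwise). Overlapping TADs on the same
#'   chromosome are an error.
#' @export
readTads <- function(path) {
    gr <- readRegionsBed(path)
    hits <- findOverlaps(gr, drop.self = TRUE, ignore.strand = TRUE)
    if (length(hits))
        stop("overlapping TAD intervals in ", path)
    gr$tad_id <- if (!is.null(gr$name) && !anyDuplicated(gr$name))
        gr$name else sprintf("tad_%05d", seq_along(gr))
    gr$name <- NULL
    gr
}

#' Write called regions as BED (name = lineage|class, score = 1000 * Dom)
#' @param regions `GRanges` from [callAccessibilityRegions()] or
#'   [callMethylationRegions()].
#' @param path output BED path.
#' @export
writeRegionsBed <- function(regions, path) {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L, end = end(regions),
                     name = paste(regions$lineage, regions$region_class,
                                  sep = "|"),
                     score = round(regions$dominance * 1000))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
}

.CATALOGUE_HEADER <- c("chrom", "start", "end", "gene_id", "score", "strand",
                       "lineage", "tad_id", "distance")

#' Write a gene-region link catalogue as BED6+
#'
#' One row per link: region coordinates (0-based half-open), name = gene_id,
#' score = |distance| (bp), strand = gene strand, plus `lineage`, `tad_id`
#' and the signed strand-aware `distance`. Rows are ordered by
#' (chrom, start, gene_id); an empty catalogue writes the header comment
#' only.
#'
#' @param links `GRanges` from [linkRegions()].
#' @param path output path.
#' @export
writeCatalogue <- function(links, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(.CATALOGUE_HEADER, collapse = "\t")), con)
    if (length(links) == 0L) return(invisible(path))
    o <- order(as.character(seqnames(links)), start(links), links$gene_id)
    links <- links[o]
    df <- data.frame(chrom = as.character(seqnames(links)),
                     start = start(links) - 1L, end = end(links),
                     gene_id = links$gene_id, score = abs(links$distance),
                     strand = as.character(strand(links)),
                     lineage = links$lineage, tad_id = links$tad_id,
                     distance = links$distance)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a link catalogue written by [writeCatalogue()]
#' @param path catalogue path.
#' @return `GRanges` with `gene_id`, `distance`, `lineage`, `tad_id`.
#' @export
readCatalogue <- function(path) {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      col.names = .CATALOGUE_HEADER)
    if (nrow(tab) == 0L)
        return(GRanges(gene_id = character(), distance = numeric(),
                       lineage = character(), tad_id = character()))
    GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
            strand = tab$strand, gene_id = tab$gene_id,
            distance = tab$distance, lineage = tab$lineage,
            tad_id = tab$tad_id)
}

#' Read a pseudo-bulk expression table (log2 RPKM)
#' @param path TSV with columns `gene_id`, `GE_ect`, `GE_end`, `GE_mes`.
#' @return numeric matrix (genes x ect/end/mes); `NA` cells mean
#'   "not expressed".
#' @export
readExpression <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", paste0("GE_", .LINEAGES))
    if (!all(need %in% names(tab)))
        stop("expression TSV must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id in ", path)
    m <- as.matrix(tab[, paste0("GE_", .LINEAGES)])
    dimnames(m) <- list(tab$gene_id, .LINEAGES)
    m
}

#' Write an expression matrix as TSV
#' @param expr log2 RPKM matrix (genes x ect/end/mes).
#' @param path output path.
#' @export
writeExpression <- function(expr, path) {
    expr <- .checkExpr(expr)
    write.table(data.frame(gene_id = rownames(expr),
                           GE_ect = expr[, "ect"], GE_end = expr[, "end"],
                           GE_mes = expr[, "mes"]),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-window signal counts into a [SignalWindows-class]
#'
#' @param path TSV with columns `chrom`, `start` (0-based window start) and,
#'   per lineage code (ect/end/mes), `reads_<lin>`, `dinuc_<lin>`,
#'   `meth_<lin>`.
#' @param width fixed window width in bp (100 accessibility /
#'   500 methylation).
#' @return A [SignalWindows-class] object.
#' @export
readSignalWindows <- function(path, width) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start",
              paste0(rep(c("reads_", "dinuc_", "meth_"), each = 3),
                     .LINEAGES))
    if (!all(need %in% names(tab)))
        stop("signal window TSV must have columns: ",
             paste(need, collapse = ", "))
    pick <- function(p) as.matrix(tab[, paste0(p, .LINEAGES)])
    SignalWindows(
        GRanges(tab$chrom, IRanges(tab$start + 1L, width = width)),
        reads = pick("reads_"), dinucTotal = pick("dinuc_"),
        dinucMeth = pick("meth_"))
}

#' Write a [SignalWindows-class] as TSV (0-based starts)
#' @param sw a `SignalWindows` object.
#' @param path output path.
#' @export
writeSignalWindows <- function(sw, path) {
    gr <- rowRanges(sw)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L)
    for (p in c("reads", "dinucTotal", "dinucMeth")) {
        m <- assay(sw, p)
        colnames(m) <- paste0(c(reads = "reads_", dinucTotal = "dinuc_",
                                dinucMeth = "meth_")[p], .LINEAGES)
        df <- cbind(df, m)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an enriched-motif list
#' @param path TSV with columns `motif`, `score` (enrichment, e.g. -log10 p),
#'   `consensus`, `origin_gene`.
#' @return data.frame of motif entries.
#' @export
readMotifList <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("motif", "score", "consensus", "origin_gene")
    if (!all(need %in% names(tab)))
        stop("motif TSV must have columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(tab$score))) stop("non-finite motif score in ", path)
    if (any(nchar(tab$consensus) == 0)) stop("empty consensus in ", path)
    tab
}

#' Write a motif list TSV
#' @param entries data.frame as from [readMotifList()].
#' @param path output path.
#' @export
writeMotifList <- function(entries, path) {
    write.table(entries[, c("motif", "score", "consensus", "origin_gene")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `annotation.tsv`, `expression.tsv`, `acc_windows.tsv`,
#' `meth_windows.tsv`, `tads.bed`, `motifs/<set>.tsv` and `truth.json` in
#' the formats the package readers consume.
#'
#' @param ds dataset list from [generateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(ds, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGeneAnnotation(ds$annotation, file.path(dir, "annotation.tsv"))
    writeExpression(ds$expression, file.path(dir, "expression.tsv"))
    writeSignalWindows(ds$accWindows, file.path(dir, "acc_windows.tsv"))
    writeSignalWindows(ds$methWindows, file.path(dir, "meth_windows.tsv"))
    tads <- ds$tads
    write.table(data.frame(chrom = as.character(seqnames(tads)),
                           start = start(tads) - 1L, end = end(tads),
                           name = tads$tad_id),
                file.path(dir, "tads.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    mdir <- file.path(dir, "motifs")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(ds$motifLists))
        writeMotifList(ds$motifLists[[nm]], file.path(mdir,
                                                      paste0(nm, ".tsv")))
    truth <- ds$truth
    jsonlite::write_json(
        list(genes = as.data.frame(truth$genes),
             regions = data.frame(chrom = as.character(seqnames(truth$regions)),
                                  start = start(truth$regions) - 1L,
                                  end = end(truth$regions),
                                  class = truth$regions$class,
                                  lineage = truth$regions$lineage,
                                  target_gene = truth$regions$target_gene),
             zone_bp = truth$zone_bp),
        file.path(dir, "truth.json"))
    invisible(dir)
}
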