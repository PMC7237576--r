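#' @include methods-accessors.R
NULL

#' Read transcript annotation from GTF
#'
#' Keeps transcript-level records (falling back to all records if the file
#' has no \code{type} column) and requires \code{gene_id}.
#'
#' @param path GTF file.
#' @return GRanges of transcripts with \code{gene_id} metadata.
#' @export
readTranscripts <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
        any(gr$type == "transcript"))
        gr <- gr[gr$type == "transcript"]
    if (!"gene_id" %in% colnames(S4Vectors::mcols(gr)))
        stop("GTF records carry no gene_id attribute")
    if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
        stop("transcripts must have strand '+' or '-'")
    gr
}

#' Strand-aware promoter windows around transcription start sites
#'
#' For a + strand transcript the window spans \code{up} bp upstream of the
#' TSS through \code{down} bp downstream; on the - strand the arithmetic is
#' mirrored (upstream is toward larger coordinates). Windows are clamped at
#' the chromosome origin. One window per transcript; a multi-transcript
#' gene contributes the union of its windows to edge calling.
#'
#' @param transcripts GRanges with \code{gene_id} (from
#'   \code{\link{readTranscripts}}).
#' @param up,down window extent in bp (defaults 5000 upstream / 1000
#'   downstream, a standard promoter definition).
#' @return GRanges of width \code{up + down} windows with \code{gene_id}.
#' @export
promoterWindows <- function(transcripts, up = 5000, down = 1000) {
    if (any(!as.character(GenomicRanges::strand(transcripts)) %in% c("+", "-")))
        stop("unknown strand symbol")
    win <- suppressWarnings(
        GenomicRanges::promoters(transcripts, upstream = up,
                                 downstream = down))
    # clamp at the chromosome origin (works without seqlengths)
    GenomicRanges::restrict(win, start = 1L)
}

#' Read TF binding intervals from BED
#'
#' BED4+ (chrom, start, end, TF name, optional score). Lines with fewer
#' than four fields are a hard error reporting the offending line number.
#' When a score column is present, sites below \code{minScore} are dropped.
#'
#' @param path BED file.
#' @param minScore optional minimum score filter.
#' @return GRanges with \code{name} (TF id).
#' @export
readBindingSites <- function(path, minScore = NULL) {
    raw <- readLines(path)
    keep <- !grepl("^(#|track|browser)", raw) & nzchar(raw)
    nf <- lengths(strsplit(raw[keep], "[\t ]+"))
    if (any(nf < 4))
        stop("malformed BED line (fewer than 4 fields) at line ",
             which(keep)[which(nf < 4)[1]], " of ", path)
    gr <- rtracklayer::import(path, format = "bed")
    if (!is.null(minScore) && "score" %in% colnames(S4Vectors::mcols(gr)))
        gr <- gr[!is.na(gr$score) & gr$score >= minScore]
    gr
}

#' Call candidate edges from binding-site/promoter overlap
#'
#' A TF-gene edge is emitted iff at least one site labelled with that TF
#' overlaps at least one promoter window of the gene by >= 1 bp,
#' irrespective of strand. Edges are deduplicated across transcripts and
#' sites.
#'
#' @param windows promoter windows with \code{gene_id}
#'   (\code{\link{promoterWindows}}).
#' @param sites GRanges with \code{name} = TF id
#'   (\code{\link{readBindingSites}}).
#' @return data.frame (\code{tf}, \code{lnc}), sorted.
#' @export
overlapCandidates <- function(windows, sites) {
    hits <- GenomicRanges::findOverlaps(sites, windows, minoverlap = 1L,
                                        ignore.strand = TRUE)
    if (!length(hits))
        return(data.frame(tf = character(), lnc = character()))
    e <- unique(data.frame(
        tf = sites$name[S4Vectors::queryHits(hits)],
        lnc = windows$gene_id[S4Vectors::subjectHits(hits)]))
    e <- e[order(e$tf, e$lnc), , drop = FALSE]
    rownames(e) <- NULL
    e
}

#' Union two evidence-specific edge sets
#'
#' Keyed by (tf, lnc); evidence flags are merged so an edge supported by
#' both sources carries both labels.
#'
#' @param tfbsEdges,peakEdges data.frames with columns \code{tf},
#'   \code{lnc}.
#' @return data.frame (\code{tf}, \code{lnc}, \code{evidence}).
#' @export
mergeEvidence <- function(tfbsEdges, peakEdges) {
    a <- unique(data.frame(tf = tfbsEdges$tf, lnc = tfbsEdges$lnc))
    b <- unique(data.frame(tf = peakEdges$tf, lnc = peakEdges$lnc))
    ka <- edgeIds(a$tf, a$lnc)
    kb <- edgeIds(b$tf, b$lnc)
    all <- unique(rbind(a, b))
    k <- edgeIds(all$tf, all$lnc)
    all$evidence <- ifelse(k %in% ka & k %in% kb,
                           "conserved_tfbs;chipseq_peak",
                           ifelse(k %in% ka, "conserved_tfbs",
                                  "chipseq_peak"))
    all <- all[order(all$tf, all$lnc), , drop = FALSE]
    rownames(all) <- NULL
    all
}

#' Candidate TF-lncRNA graph from annotation and binding files
#'
#' End-to-end wrapper: read the GTF, build promoter windows, overlap the
#' conserved-TFBS and ChIP-seq peak BED files separately, and take the
#' union of the two evidence sources.
#'
#' @param gtf transcript annotation path.
#' @param tfbs,peaks BED4+ paths (either may be NULL).
#' @param up,down promoter window in bp.
#' @param minScore optional TFBS score threshold.
#' @return data.frame (\code{tf}, \code{lnc}, \code{evidence}).
#' @export
findCandidates <- function(gtf, tfbs = NULL, peaks = NULL,
                           up = 5000, down = 1000, minScore = NULL) {
    win <- promoterWindows(readTranscripts(gtf), up = up, down = down)
    none <- data.frame(tf = character(), lnc = character())
    a <- if (is.null(tfbs)) none else
        overlapCandidates(win, readBindingSites(tfbs, minScore = minScore))
    b <- if (is.null(peaks)) none else
        overlapCandidates(win, readBindingSites(peaks))
    mergeEvidence(a, b)
}
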