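#' Construct an Annotation
#'
#' Builds a validated [Annotation-class] from per-chromosome interval
#' matrices.  The constructor is strict: intervals must already be sorted,
#' non-empty, within \eqn{[0, L)} and separated by at least one base; use
#' [readAnnotation()] (or coerce from a \code{GRanges}) for inputs that may
#' need merging.
#'
#' @param ranges named list of numeric matrices with columns begin, end
#'   (0-based half-open); chromosomes in \code{seqlengths} missing from the
#'   list get an empty matrix.
#' @param seqlengths named numeric vector of chromosome lengths.
#' @return an [Annotation-class].
#' @examples
#' Annotation(list(chr1 = cbind(c(2, 7), c(4, 9))), c(chr1 = 12))
#' @export
Annotation <- function(ranges = list(), seqlengths) {
    seqlengths <- .asSeqlengths(seqlengths)
    ranges <- lapply(ranges, function(iv) {
        iv <- matrix(as.numeric(iv), ncol = 2L,
                     dimnames = list(NULL, c("begin", "end")))
        iv
    })
    missing <- setdiff(names(seqlengths), names(ranges))
    for (chrom in missing)
        ranges[[chrom]] <- matrix(numeric(0), ncol = 2L,
                                  dimnames = list(NULL, c("begin", "end")))
    extra <- setdiff(names(ranges), names(seqlengths))
    if (length(extra))
        stop("ranges name chromosomes with unknown length: ",
             paste(extra, collapse = ", "))
    new("Annotation", ranges = ranges[names(seqlengths)],
        seqlengths = seqlengths)
}

.asSeqlengths <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        x <- readChromSizes(x)
    if (is.null(names(x))) stop("chromosome lengths must be named")
    setNames(as.numeric(x), names(x))
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated table: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    tab <- utils::read.table(path, header = FALSE, colClasses = c("character", "numeric"),
                             col.names = c("chrom", "length"),
                             stringsAsFactors = FALSE)
    if (anyDuplicated(tab$chrom))
        stop("duplicated chromosome in ", path)
    setNames(tab$length, tab$chrom)
}

## Parse the first `ncol` whitespace-separated fields of a BED-like file,
## keeping 1-based line numbers for error messages.  Skips empty lines and
## browser/track/comment lines.
.readBedFields <- function(path, ncol, what) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*$|^#|^browser\\b|^track\\b", lines)
    lineno <- which(keep)
    if (!length(lineno))
        return(list(fields = vector("list", ncol), lineno = integer(0)))
    parts <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < ncol))
        stop(sprintf("%s line %d: expected >= %d fields, found %d",
                     what, lineno[which(nf < ncol)[1L]], ncol,
                     min(nf[nf < ncol])))
    fields <- lapply(seq_len(ncol), function(k)
        vapply(parts, `[[`, "", k))
    list(fields = fields, lineno = lineno)
}

.validateBedRecords <- function(chrom, begin, end, lineno, seqlengths, what) {
    bad <- which(is.na(begin) | is.na(end))
    if (length(bad))
        stop(sprintf("%s line %d: non-numeric coordinates", what, lineno[bad[1L]]))
    bad <- which(begin < 0)
    if (length(bad))
        stop(sprintf("%s line %d: begin %g < 0", what, lineno[bad[1L]],
                     begin[bad[1L]]))
    bad <- which(begin >= end)
    if (length(bad))
        stop(sprintf("%s line %d: begin %g >= end %g", what, lineno[bad[1L]],
                     begin[bad[1L]], end[bad[1L]]))
    known <- chrom %in% names(seqlengths)
    if (any(known)) {
        L <- seqlengths[chrom]
        bad <- which(known & end > L)
        if (length(bad))
            stop(sprintf("%s line %d: end %g > length %g of %s", what,
                         lineno[bad[1L]], end[bad[1L]], L[bad[1L]],
                         chrom[bad[1L]]))
    }
    if (!all(known)) {
        dropped <- unique(chrom[!known])
        warning(sprintf("%s: dropping %d record(s) on chromosome(s) absent from chrom sizes: %s",
                        what, sum(!known), paste(dropped, collapse = ", ")))
    }
    known
}

#' Read a BED3 annotation
#'
#' Reads the first three columns of a BED file (chrom, begin, end; 0-based
#' half-open), validates every record against the chromosome lengths, drops
#' (with a warning) records on unknown chromosomes, and normalizes the result
#' so that intervals are sorted, disjoint and separated by at least one base:
#' overlapping and bookended records are merged.
#'
#' @param path BED file path.
#' @param chromSizes named numeric vector of chromosome lengths, or the path
#'   of a chrom.sizes file.
#' @return an [Annotation-class].
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t5\t10", "chr1\t8\t12"), bed)
#' readAnnotation(bed, c(chr1 = 20))
#' @importFrom IRanges IRanges reduce start end
#' @export
readAnnotation <- function(path, chromSizes) {
    seqlengths <- .asSeqlengths(chromSizes)
    parsed <- .readBedFields(path, 3L, basename(path))
    if (!length(parsed$lineno))
        return(Annotation(list(), seqlengths))
    chrom <- parsed$fields[[1L]]
    begin <- suppressWarnings(as.numeric(parsed$fields[[2L]]))
    end <- suppressWarnings(as.numeric(parsed$fields[[3L]]))
    keep <- .validateBedRecords(chrom, begin, end, parsed$lineno, seqlengths,
                                basename(path))
    chrom <- chrom[keep]; begin <- begin[keep]; end <- end[keep]
    ranges <- lapply(setNames(nm = names(seqlengths)), function(ch) {
        sel <- chrom == ch
        if (!any(sel))
            return(matrix(numeric(0), ncol = 2L))
        ir <- IRanges::reduce(IRanges::IRanges(start = begin[sel] + 1,
                                               end = end[sel]),
                              min.gapwidth = 1L)
        cbind(begin = IRanges::start(ir) - 1, end = IRanges::end(ir))
    })
    Annotation(ranges, seqlengths)
}

#' Write an annotation as BED3
#'
#' @param x an [Annotation-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeAnnotation <- function(x, path) {
    stopifnot(is(x, "Annotation"))
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(x@ranges)) {
        iv <- x@ranges[[chrom]]
        if (!nrow(iv)) next
        writeLines(sprintf("%s\t%.0f\t%.0f", chrom, iv[, 1L], iv[, 2L]), con)
    }
    invisible(path)
}

.sharedChroms <- function(a, b) {
    if (!identical(a@seqlengths[sort(names(a@seqlengths))],
                   b@seqlengths[sort(names(b@seqlengths))]))
        stop("annotations/contexts disagree on chromosome names or lengths")
    names(a@seqlengths)
}

#' Observed colocalization statistics
#'
#' Computes the observed value of a colocalization statistic between a
#' reference and a query annotation: \code{"overlaps"} is the number of
#' reference intervals intersecting at least one query interval;
#' \code{"bases"} is the number of genome positions covered by both
#' annotations.  Summed over chromosomes.
#'
#' @param reference,query [Annotation-class] objects on the same genome.
#' @param statistic \code{"overlaps"} or \code{"bases"}.
#' @param perChromosome return the per-chromosome breakdown.
#' @return numeric value (or named vector).
#' @examples
#' sl <- c(chr1 = 10)
#' R <- Annotation(list(chr1 = cbind(c(0, 4), c(2, 6))), sl)
#' Q <- Annotation(list(chr1 = cbind(1, 5)), sl)
#' observedStatistic(R, Q, "overlaps")  # 2
#' observedStatistic(R, Q, "bases")     # 2
#' @importFrom IRanges IRanges countOverlaps intersect width
#' @export
observedStatistic <- function(reference, query,
                              statistic = c("overlaps", "bases"),
                              perChromosome = FALSE) {
    statistic <- match.arg(statistic)
    chroms <- .sharedChroms(reference, query)
    vals <- vapply(chroms, function(chrom) {
        ivr <- reference@ranges[[chrom]]
        ivq <- query@ranges[[chrom]]
        if (!nrow(ivr) || !nrow(ivq)) return(0)
        rr <- IRanges::IRanges(start = ivr[, 1L] + 1, end = ivr[, 2L])
        qq <- IRanges::IRanges(start = ivq[, 1L] + 1, end = ivq[, 2L])
        if (statistic == "overlaps")
            sum(IRanges::countOverlaps(rr, qq) > 0L)
        else
            sum(IRanges::width(IRanges::intersect(rr, qq)))
    }, 0)
    if (perChromosome) vals else sum(vals)
}
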