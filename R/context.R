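#' Construct a GenomeContext
#'
#' Builds a validated [GenomeContext-class] from per-chromosome run lists.
#' Adjacent runs with equal labels are merged, so any run-length input that
#' tiles the chromosome is accepted.
#'
#' @param runs named list, one per chromosome: a list (or data.frame) with
#'   components \code{start} (numeric, increasing, first element 0) and
#'   \code{label} (character).
#' @param seqlengths named numeric vector of chromosome lengths, or path to a
#'   chrom.sizes file.
#' @return a [GenomeContext-class].
#' @examples
#' GenomeContext(list(chr1 = list(start = c(0, 10, 20),
#'                                label = c("bg", "gap", "bg"))),
#'               c(chr1 = 30))
#' @export
GenomeContext <- function(runs, seqlengths) {
    seqlengths <- .asSeqlengths(seqlengths)
    runs <- lapply(runs, function(r) {
        r <- list(start = as.numeric(r$start), label = as.character(r$label))
        keep <- c(TRUE, r$label[-1L] != r$label[-length(r$label)])
        list(start = r$start[keep], label = r$label[keep])
    })
    missing <- setdiff(names(seqlengths), names(runs))
    if (length(missing))
        stop("no context runs for chromosome(s): ",
             paste(missing, collapse = ", "))
    new("GenomeContext", runs = runs[names(seqlengths)],
        seqlengths = seqlengths)
}

#' Single-class context covering a whole genome
#'
#' With one class the context-aware null reduces to the plain two-state
#' Markov chain null; this is the context used when none is supplied.
#'
#' @param seqlengths named numeric vector of chromosome lengths (or
#'   chrom.sizes path).
#' @param label the single class label.
#' @return a [GenomeContext-class] with one run per chromosome.
#' @export
uniformContext <- function(seqlengths, label = "background") {
    seqlengths <- .asSeqlengths(seqlengths)
    runs <- lapply(seqlengths, function(L) list(start = 0, label = label))
    GenomeContext(runs, seqlengths)
}

#' Read a BED4 genome context
#'
#' The fourth BED column is the class label.  Records within a chromosome
#' must not overlap with conflicting labels; positions covered by no record
#' receive \code{defaultLabel}.  The result tiles every chromosome exactly.
#'
#' @param path BED4 file path.
#' @param chromSizes named numeric lengths or chrom.sizes path.
#' @param defaultLabel label given to uncovered positions.
#' @return a [GenomeContext-class].
#' @export
readContext <- function(path, chromSizes, defaultLabel = "background") {
    seqlengths <- .asSeqlengths(chromSizes)
    parsed <- .readBedFields(path, 4L, basename(path))
    if (!length(parsed$lineno))
        return(uniformContext(seqlengths, defaultLabel))
    chrom <- parsed$fields[[1L]]
    begin <- suppressWarnings(as.numeric(parsed$fields[[2L]]))
    end <- suppressWarnings(as.numeric(parsed$fields[[3L]]))
    label <- parsed$fields[[4L]]
    if (any(label == ""))
        stop(basename(path), ": empty context label")
    keep <- .validateBedRecords(chrom, begin, end, parsed$lineno, seqlengths,
                                basename(path))
    chrom <- chrom[keep]; begin <- begin[keep]; end <- end[keep]
    label <- label[keep]; lineno <- parsed$lineno[keep]
    runs <- lapply(setNames(nm = names(seqlengths)), function(ch) {
        sel <- which(chrom == ch)
        L <- seqlengths[[ch]]
        if (!length(sel)) return(list(start = 0, label = defaultLabel))
        o <- sel[order(begin[sel])]
        b <- begin[o]; e <- end[o]; lab <- label[o]
        ov <- which(b[-1L] < e[-length(e)])
        for (k in ov) {
            if (lab[k] != lab[k + 1L])
                stop(sprintf("%s line %d: records overlap with conflicting labels ('%s' vs '%s')",
                             basename(path), lineno[o[k + 1L]], lab[k], lab[k + 1L]))
        }
        ## tile [0, L): alternate default-label gaps with records
        start <- numeric(0); rl <- character(0)
        pos <- 0
        for (k in seq_along(b)) {
            bb <- max(b[k], pos)          # same-label overlap: clip
            if (bb > pos) { start <- c(start, pos); rl <- c(rl, defaultLabel) }
            if (e[k] > bb) { start <- c(start, bb); rl <- c(rl, lab[k]) }
            pos <- max(pos, e[k])
        }
        if (pos < L) { start <- c(start, pos); rl <- c(rl, defaultLabel) }
        ## clipping can create zero-length record runs; drop them
        len <- diff(c(start, L))
        list(start = start[len > 0], label = rl[len > 0])
    })
    GenomeContext(runs, seqlengths)
}

#' Two-class context marking the inside of a reference annotation
#'
#' Labels every position covered by \code{outer} as \code{insideLabel} and
#' every other position as \code{outsideLabel}.  This is the context used for
#' differential enrichment of a nested reference R1 within a superset R2: the
#' null chain inside R2 is trained from the query's behaviour inside R2, so
#' significance of the query in R1 is measured relative to R2 rather than to
#' the whole genome.
#'
#' @param outer an [Annotation-class] (the superset reference R2).
#' @param insideLabel,outsideLabel class labels.
#' @return a [GenomeContext-class].
#' @seealso [differentialColocTest()]
#' @export
relativeContext <- function(outer, insideLabel = "inside",
                            outsideLabel = "outside") {
    stopifnot(is(outer, "Annotation"))
    runs <- lapply(setNames(nm = names(outer@seqlengths)), function(chrom) {
        iv <- outer@ranges[[chrom]]
        L <- outer@seqlengths[[chrom]]
        if (!nrow(iv)) return(list(start = 0, label = outsideLabel))
        start <- numeric(0); lab <- character(0)
        pos <- 0
        for (k in seq_len(nrow(iv))) {
            if (iv[k, 1L] > pos) { start <- c(start, pos); lab <- c(lab, outsideLabel) }
            start <- c(start, iv[k, 1L]); lab <- c(lab, insideLabel)
            pos <- iv[k, 2L]
        }
        if (pos < L) { start <- c(start, pos); lab <- c(lab, outsideLabel) }
        list(start = start, label = lab)
    })
    GenomeContext(runs, outer@seqlengths)
}

#' GC-content context from a genome FASTA
#'
#' Tiles each chromosome into fixed-size windows (the last window may be
#' short), labels windows that are at least half ambiguous bases (N) with
#' \code{gapLabel}, and the remaining windows by the equal-width GC-fraction
#' bin they fall into.  GC fraction is computed over the non-N bases of the
#' window.  Bin \code{k} covers GC fractions in \eqn{[k/n, (k+1)/n)}, with
#' GC = 1 in the top bin; labels are \code{"gc0" ... "gc<n-1>"}.
#'
#' @param fasta path to a genome FASTA file.
#' @param chromSizes named numeric lengths or chrom.sizes path; sequences in
#'   the FASTA absent from it are skipped with a warning.
#' @param window window size in bp (default 1000).
#' @param nBins number of GC bins (default 5).
#' @param gapLabel label for N-dominated windows.
#' @return a [GenomeContext-class].
#' @importFrom Biostrings readDNAStringSet letterFrequency
#' @importFrom IRanges Views
#' @export
gcContext <- function(fasta, chromSizes, window = 1000, nBins = 5,
                      gapLabel = "gap") {
    stopifnot(window >= 1, nBins >= 1)
    seqlengths <- .asSeqlengths(chromSizes)
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    known <- names(seqs) %in% names(seqlengths)
    if (!all(known)) {
        warning("skipping FASTA sequence(s) absent from chrom sizes: ",
                paste(names(seqs)[!known], collapse = ", "))
        seqs <- seqs[known]
    }
    missing <- setdiff(names(seqlengths), names(seqs))
    if (length(missing))
        stop("no FASTA sequence for chromosome(s): ",
             paste(missing, collapse = ", "))
    runs <- lapply(setNames(nm = names(seqlengths)), function(chrom) {
        L <- seqlengths[[chrom]]
        if (length(seqs[[chrom]]) != L)
            stop(sprintf("FASTA length %d of %s differs from chrom sizes (%g)",
                         length(seqs[[chrom]]), chrom, L))
        starts <- seq(0, L - 1, by = window)
        ends <- pmin(starts + window, L)
        v <- IRanges::Views(seqs[[chrom]], start = starts + 1, end = ends)
        freq <- Biostrings::letterFrequency(v, letters = c("CG", "N"))
        w <- ends - starts
        nN <- freq[, "N"]
        nonN <- w - nN
        gc <- ifelse(nonN > 0, freq[, "C|G"] / nonN, 0)
        bin <- pmin(floor(gc * nBins), nBins - 1)
        lab <- ifelse(nN >= w / 2, gapLabel, sprintf("gc%d", bin))
        list(start = starts, label = lab)
    })
    GenomeContext(runs, seqlengths)
}

#' Class label at given genome positions
#'
#' @param ctx a [GenomeContext-class].
#' @param chrom chromosome name.
#' @param pos numeric vector of 0-based positions.
#' @return character vector of labels.
#' @export
labelAt <- function(ctx, chrom, pos) {
    r <- ctx@runs[[chrom]]
    if (is.null(r)) stop("unknown chromosome: ", chrom)
    if (any(pos < 0) || any(pos >= ctx@seqlengths[[chrom]]))
        stop("position outside [0, L)")
    r$label[findInterval(pos, r$start)]
}

## Clip the context runs of `chrom` to the half-open span [i, j).
## Returns list(label=..., len=...) with len summing to j - i.
.runsWithin <- function(ctx, chrom, i, j) {
    if (j <= i) return(list(label = character(0), len = numeric(0)))
    r <- ctx@runs[[chrom]]
    s <- r$start
    k1 <- findInterval(i, s)
    k2 <- findInterval(j - 1, s)
    idx <- k1:k2
    lo <- pmax(s[idx], i)
    hi <- pmin(c(s[-1L], ctx@seqlengths[[chrom]])[idx], j)
    list(label = r$label[idx], len = hi - lo)
}
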