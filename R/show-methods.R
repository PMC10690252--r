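setMethod("show", "Annotation", function(object) {
    cat(sprintf("Annotation: %d interval(s), %.0f covered base(s) on %d chromosome(s)\n",
                intervalCount(object), coveredBases(object),
                length(object@seqlengths)))
    for (chrom in head(names(object@seqlengths), 5L)) {
        iv <- object@ranges[[chrom]]
        cat(sprintf("  %s (L=%.0f): %d interval(s)", chrom,
                    object@seqlengths[[chrom]], nrow(iv)))
        if (nrow(iv))
            cat(sprintf("  [%.0f,%.0f)%s", iv[1L, 1L], iv[1L, 2L],
                        if (nrow(iv) > 1L) " ..." else ""))
        cat("\n")
    }
    if (length(object@seqlengths) > 5L)
        cat("  ...\n")
})

setMethod("show", "GenomeContext", function(object) {
    cat(sprintf("GenomeContext: %d class(es) {%s}, %d boundary position(s), %d chromosome(s)\n",
                length(contextLabels(object)),
                paste(head(contextLabels(object), 8L), collapse = ", "),
                boundaryCount(object), length(object@seqlengths)))
})

setMethod("show", "ContextChain", function(object) {
    cat(sprintf("ContextChain: %d class(es)%s\n", length(object@matrices),
                if (length(object@counts))
                    sprintf(", trained (pseudocount %g)", object@pseudocount)
                else ""))
    for (lab in head(names(object@matrices), 4L)) {
        Tm <- object@matrices[[lab]]
        cat(sprintf("  %s: T = [%.4g %.4g; %.4g %.4g]\n", lab,
                    Tm[1L, 1L], Tm[1L, 2L], Tm[2L, 1L], Tm[2L, 2L]))
    }
    if (length(object@matrices) > 4L) cat("  ...\n")
})

setMethod("show", "NullPmf", function(object) {
    cat(sprintf("NullPmf (%s): support 0..%g, mean %.6g, variance %.6g\n",
                object@statistic, max(object@support), pmfMean(object),
                pmfVariance(object)))
})

setMethod("show", "MomentResult", function(object) {
    cat(sprintf("MomentResult (%s): mean %.6g, variance %.6g over %d chromosome(s); %g combine call(s)\n",
                object@statistic, object@mean, object@variance,
                nrow(object@perChromosome), object@combineCalls))
})

setMethod("show", "TwoSidedPlumbus", function(object) {
    cat(sprintf("TwoSidedPlumbus over [%g,%g)\n", object@span[1L],
                object@span[2L]))
    cat("  psi:\n"); print(round(object@psi, 6))
    cat("  mu:\n"); print(round(object@mu, 6))
    cat("  var:\n"); print(round(object@var, 6))
})

setMethod("show", "ColocResult", function(object) {
    cat(sprintf("Colocalization test (%s statistic, %s mode): %s\n",
                object@statistic, object@mode, object@status))
    cat(sprintf("  observed %.6g vs null mean %.6g (sd %.6g)\n",
                object@observed, object@nullMean,
                sqrt(object@nullVariance)))
    if (object@status == "ok") {
        cat(sprintf("  Z = %.4g\n", object@zScore))
        cat(sprintf("  p(enrichment) = %.4g   [log10 %.4g]\n",
                    object@pEnrichment, object@log10PEnrichment))
        cat(sprintf("  p(depletion)  = %.4g   [log10 %.4g]\n",
                    object@pDepletion, object@log10PDepletion))
    } else {
        cat("  null variance is zero; p-values omitted\n")
    }
})
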