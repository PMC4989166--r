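# Central S4 containers. Sequence alignments are stored as a character
# matrix (samples x sites) because every downstream operation is columnwise;
# Biostrings handles file IO in the readers.

#' Aligned chloroplast sequences
#'
#' Holds an alignment of equal-length sequences over \{A,C,G,T,N,-\} together
#' with the column ranges of the concatenated spacer regions.
#'
#' @slot seqs character matrix, samples in rows (unique rownames), one
#'   alignment column per matrix column.
#' @slot locusBounds integer matrix with columns \code{start}, \code{end}:
#'   0-based half-open column ranges, one row per concatenated locus,
#'   partitioning \code{[0, L)}.
#' @exportClass HapAlignment
setClass("HapAlignment",
         representation(seqs = "matrix", locusBounds = "matrix"))

setValidity("HapAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("sample ids (rownames) must be present and unique")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    return(paste("illegal characters in alignment:", paste(bad, collapse = " ")))
  b <- object@locusBounds
  if (ncol(b) != 2L) return("locusBounds must have two columns")
  o <- b[order(b[, 1L]), , drop = FALSE]
  if (o[1L, 1L] != 0L || o[nrow(o), 2L] != ncol(m) ||
      (nrow(o) > 1L && any(o[-1L, 1L] != o[-nrow(o), 2L])))
    return("locusBounds must partition [0, L)")
  TRUE
})

#' Recoded mutation matrix
#'
#' Variable alignment columns after recoding: substitutions kept per site,
#' each indel (maximal shared gap run) and each declared inversion collapsed
#' to a single binary column, so that every mutational event contributes one
#' recoded column.
#'
#' @slot states character matrix, samples x recoded columns.
#' @slot meta data.frame with per-column \code{type}
#'   (substitution/indel/inversion), \code{start}, \code{end} (1-based,
#'   inclusive alignment positions).
#' @slot alignmentLength integer, original alignment length L (bp).
#' @exportClass MutationMatrix
setClass("MutationMatrix",
         representation(states = "matrix", meta = "data.frame",
                        alignmentLength = "integer"))

#' Collapsed haplotypes with sample membership
#'
#' @slot labels haplotype labels (prefix + rank of first appearance).
#' @slot vectors character matrix, haplotypes x recoded columns.
#' @slot membership named character vector mapping sample id -> haplotype.
#' @slot popCounts integer matrix, populations x haplotypes.
#' @slot meta recoded-column metadata (from the \linkS4class{MutationMatrix}).
#' @slot alignmentLength alignment length L used for per-site diversity.
#' @slot monomorphic TRUE when a single haplotype was observed.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
         representation(labels = "character", vectors = "matrix",
                        membership = "character", popCounts = "matrix",
                        meta = "data.frame", alignmentLength = "integer",
                        monomorphic = "logical"))

setValidity("HaplotypeSet", function(object) {
  if (nrow(object@vectors) != length(object@labels))
    return("one vector per haplotype required")
  if (!all(object@membership %in% object@labels))
    return("membership refers to unknown haplotypes")
  if (sum(object@popCounts) != length(object@membership))
    return("population counts must sum to the number of samples")
  if (length(object@labels) > 1L) {
    d <- .hammingMatrix(object@vectors)
    if (any(d[upper.tri(d)] < 1L))
      return("distinct haplotypes must differ in at least one recoded column")
  }
  TRUE
})

setClass("AmovaResult",
         representation(sigma = "numeric", phi = "numeric", ss = "data.frame",
                        flags = "character"))

setClass("SamovaResult",
         representation(K = "integer", grouping = "integer", fct = "numeric",
                        amova = "AmovaResult", trace = "data.frame",
                        seed = "integer"))

#' Mismatch-distribution fit under the sudden-expansion model
#'
#' @slot observed integer vector of pair counts, names "0", "1", ...
#' @slot n number of individuals behind the histogram.
#' @slot tau,theta0,theta1 fitted expansion parameters (mutational units).
#' @slot ssd sum of squared deviations between observed and expected
#'   relative frequencies.
#' @slot raggedness Harpending's raggedness index of the observed histogram.
#' @slot expected expected relative frequencies at the fit (folded tail).
#' @slot modality label from \code{\link{classifyModality}}.
#' @slot gof bootstrap results (p-values, tau CI) once
#'   \code{\link{expansionGof}} has been run; empty list before that.
#' @exportClass MismatchFit
setClass("MismatchFit",
         representation(observed = "integer", n = "integer", tau = "numeric",
                        theta0 = "numeric", theta1 = "numeric", ssd = "numeric",
                        raggedness = "numeric", expected = "numeric",
                        modality = "character", gof = "list"))

setClass("HaplotypeNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        states = "matrix", totalLength = "numeric",
                        mstLength = "numeric"))

#' Co-registered environmental raster stack
#'
#' @slot layers numeric array (rows x cols x variables) with layer dimnames.
#' @slot mask logical matrix of valid cells (shared by all layers).
#' @slot xll,yll lower-left corner coordinates (WGS84 decimal degrees).
#' @slot cellsize cell size in degrees.
#' @exportClass EnvStack
setClass("EnvStack",
         representation(layers = "array", mask = "matrix", xll = "numeric",
                        yll = "numeric", cellsize = "numeric"))

setValidity("EnvStack", function(object) {
  d <- dim(object@layers)
  if (length(d) != 3L) return("layers must be a 3-d array")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask must match the layer grid")
  if (is.null(dimnames(object@layers)[[3L]]))
    return("layers must be named")
  TRUE
})

setClass("SuitabilityRaster",
         representation(values = "matrix", mask = "matrix", xll = "numeric",
                        yll = "numeric", cellsize = "numeric", model = "list"))

setValidity("SuitabilityRaster", function(object) {
  v <- object@values[object@mask]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("suitability values must lie in [0, 1]")
  TRUE
})

setClass("NicheOverlap",
         representation(D = "numeric", I = "numeric", nullD = "numeric",
                        nullI = "numeric", pD = "numeric", pI = "numeric",
                        nReps = "integer", seed = "integer"))

## ---- show methods -------------------------------------------------------

setMethod("show", "HapAlignment", function(object) {
  cat("HapAlignment:", nrow(object@seqs), "sequences x",
      ncol(object@seqs), "bp,", nrow(object@locusBounds), "locus region(s)\n")
})

setMethod("show", "MutationMatrix", function(object) {
  cat("MutationMatrix:", nrow(object@states), "samples,",
      ncol(object@states), "variable recoded columns (",
      paste(names(table(object@meta$type)), table(object@meta$type),
            collapse = ", "), ")\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@labels), "haplotypes from",
      length(object@membership), "individuals in",
      nrow(object@popCounts), "population(s)",
      if (object@monomorphic) "[monomorphic]" else "", "\n")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA variance components:\n")
  print(round(object@sigma, 6))
  cat("Phi statistics:\n")
  print(round(object@phi, 4))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "SamovaResult", function(object) {
  cat("SAMOVA K =", object@K, " F_CT =", round(object@fct, 4), "\n")
  print(object@grouping)
})

setMethod("show", "MismatchFit", function(object) {
  cat("Sudden-expansion fit: tau =", signif(object@tau, 4),
      " theta0 =", signif(object@theta0, 4),
      " theta1 =", signif(object@theta1, 4), "\n")
  cat("SSD =", signif(object@ssd, 4), " H_Rag =", signif(object@raggedness, 4),
      " modality:", object@modality, "\n")
  if (length(object@gof))
    cat("bootstrap: p_SSD =", object@gof$pSSD, " p_rag =", object@gof$pRag,
        " tau 95% CI [", paste(signif(object@gof$tauCI, 4), collapse = ", "),
        "]\n")
})

setMethod("show", "HaplotypeNetwork", function(object) {
  cat("HaplotypeNetwork:", sum(!object@nodes$isMedian), "observed +",
      sum(object@nodes$isMedian), "median nodes,", nrow(object@edges),
      "links, total length", object@totalLength, "\n")
})

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@layers)
  cat("EnvStack:", d[3], "layers on a", d[1], "x", d[2], "grid (",
      sum(object@mask), "valid cells )\n")
})

setMethod("show", "NicheOverlap", function(object) {
  cat("Niche overlap: D =", round(object@D, 4), " I =", round(object@I, 4), "\n")
  if (length(object@nullD))
    cat("identity test (", object@nReps, "reps ): p_D =", round(object@pD, 4),
        " p_I =", round(object@pI, 4), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname HaplotypeSet-class
#' @param object a \linkS4class{HaplotypeSet}
#' @export
setGeneric("haplotypeLabels", function(object) standardGeneric("haplotypeLabels"))
#' @rdname HaplotypeSet-class
#' @export
setMethod("haplotypeLabels", "HaplotypeSet", function(object) object@labels)

#' @rdname HaplotypeSet-class
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @rdname HaplotypeSet-class
#' @export
setMethod("membership", "HaplotypeSet", function(object) object@membership)

#' @rdname HaplotypeSet-class
#' @export
setGeneric("popCounts", function(object) standardGeneric("popCounts"))
#' @rdname HaplotypeSet-class
#' @export
setMethod("popCounts", "HaplotypeSet", function(object) object@popCounts)

#' @rdname EnvStack-class
#' @param object an \linkS4class{EnvStack}
#' @export
setGeneric("layerNames", function(object) standardGeneric("layerNames"))
#' @rdname EnvStack-class
#' @export
setMethod("layerNames", "EnvStack", function(object) dimnames(object@layers)[[3L]])

# internal: Hamming distance between rows of a character matrix
.hammingMatrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L || ncol(m) == 0L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}
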