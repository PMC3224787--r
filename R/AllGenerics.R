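#' @import methods
#' @importFrom BiocGenerics start end width strand
NULL

#' Extract the genomic intervals of an object
#'
#' Returns the underlying [GenomicRanges::GRanges] of a `Segmentation` or
#' `Annotation`, with the segment label (or record group) in the `label`
#' (resp. `group`) metadata column.
#'
#' @param x a `Segmentation` or `Annotation`.
#' @return A `GRanges`.
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' Label vocabulary of a segmentation
#'
#' @param x a `Segmentation`.
#' @return Character vector of distinct labels, in input order.
#' @export
setGeneric("labelSet", function(x) standardGeneric("labelSet"))

#' Group vocabulary of an annotation
#'
#' @param x an `Annotation`.
#' @return Character vector of distinct groups, in input order.
#' @export
setGeneric("groupSet", function(x) standardGeneric("groupSet"))

#' Write a result as a tab-delimited file
#'
#' Every analysis result can be serialized to a TSV file with a deterministic
#' column and row order (labels appear in segmentation input order) and a
#' comment header recording the command, package version and parameters.
#' Floating point values are written with 6 significant digits.
#'
#' @param x an analysis result object.
#' @param path output file path.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
setGeneric("writeTable", function(x, path, ...) standardGeneric("writeTable"))

#' Render the standard plots for a result
#'
#' Writes the visualization(s) associated with a result object (violin/bar
#' plots, heat maps, line plots) as PNG and PDF files into a directory.
#'
#' @param x an analysis result object.
#' @param outdir output directory (created if needed).
#' @param ... options specific to the result type.
#' @return Character vector of the files written, invisibly.
#' @export
setGeneric("writePlots", function(x, outdir, ...) standardGeneric("writePlots"))
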