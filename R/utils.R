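#' @importFrom IRanges coverage RleList
#' @importFrom S4Vectors runLength runValue
NULL

## Chromosome sizes inferred from one or more objects: declared seqlengths
## win, otherwise the maximum end coordinate seen. Exact string matching of
## chromosome names throughout (no "chr" aliasing).
.chromSizes <- function(..., sizes = NULL) {
  objs <- list(...)
  out <- if (is.null(sizes)) integer() else
    structure(as.integer(sizes), names = names(sizes))
  for (x in objs) {
    if (is.null(x)) next
    gr <- if (is(x, "Segmentation") || is(x, "Annotation")) intervals(x)
          else if (is(x, "SignalTrack")) NULL
          else x
    if (is(x, "SignalTrack")) {
      lens <- vapply(x@values, length, numeric(1))
      for (ch in names(lens))
        out[ch] <- max(out[ch], lens[ch], na.rm = TRUE)
      next
    }
    sl <- seqlengths(gr)
    for (ch in seqlevels(gr)) {
      idx <- as.character(seqnames(gr)) == ch
      m <- if (!is.na(sl[ch])) sl[ch] else
           if (any(idx)) max(end(gr)[idx]) else NA_integer_
      if (!is.na(m)) out[ch] <- max(out[ch], m, na.rm = TRUE)
    }
  }
  out
}

## Warn if two inputs disagree on the chromosomes they mention.
.warnChromMismatch <- function(a, b, whatA = "first input", whatB = "second input") {
  ca <- unique(as.character(seqnames(intervals(a))))
  cb <- unique(as.character(seqnames(intervals(b))))
  onlyA <- setdiff(ca, cb); onlyB <- setdiff(cb, ca)
  if (length(onlyA) || length(onlyB))
    warning(sprintf(
      "chromosomes present in only one input: %s",
      paste(c(sprintf("%s: %s", whatA, paste(onlyA, collapse = ",")),
              sprintf("%s: %s", whatB, paste(onlyB, collapse = ",")))[
                c(length(onlyA) > 0, length(onlyB) > 0)], collapse = "; ")),
      call. = FALSE)
  invisible(NULL)
}

## Per-chromosome integer Rle of label codes: 0 = uncovered, i = labels[i].
## chromSizes: named integer vector; chromosomes absent from the segmentation
## come back as all-zero Rles.
.labelRle <- function(seg, chromSizes) {
  gr <- intervals(seg)
  labs <- labelSet(seg)
  code <- match(mcols(gr)$label, labs)
  out <- list()
  chn <- as.character(seqnames(gr))
  for (ch in names(chromSizes)) {
    n <- chromSizes[[ch]]
    idx <- which(chn == ch)
    if (!length(idx)) { out[[ch]] <- Rle(0L, n); next }
    s <- start(gr)[idx]; e <- pmin(end(gr)[idx], n); v <- code[idx]
    keep <- s <= n
    s <- s[keep]; e <- e[keep]; v <- v[keep]
    # segments are sorted and disjoint: interleave gap runs with segment runs
    prev <- c(0L, e[-length(e)])
    runlen <- as.integer(rbind(s - prev - 1L, e - s + 1L))
    runval <- as.integer(rbind(0L, v))
    if (e[length(e)] < n) {
      runlen <- c(runlen, n - e[length(e)])
      runval <- c(runval, 0L)
    }
    keep <- runlen > 0L
    out[[ch]] <- Rle(runval[keep], runlen[keep])
  }
  out
}

## Treat strand "." as "+" where orientation matters, with a warning.
.effectiveStrand <- function(st, what = "feature") {
  st <- as.character(st)
  if (any(st == "." | st == "*")) {
    warning(sprintf("%d %s(s) with unknown strand treated as '+'",
                    sum(st == "." | st == "*"), what), call. = FALSE)
    st[st == "." | st == "*"] <- "+"
  }
  st
}

## bases covered per label (reduced; within a Segmentation segments are
## disjoint so plain width sums are exact)
.labelBases <- function(seg) {
  gr <- intervals(seg)
  vapply(labelSet(seg), function(l)
    sum(width(gr)[mcols(gr)$label == l]), numeric(1))
}

.fmt6 <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

## standard comment header for TSV outputs
.tsvHeader <- function(command, params = list()) {
  p <- if (length(params))
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(v) paste(format(v), collapse = ","),
                         character(1))), collapse = " ")
  else "none"
  c(sprintf("# command: %s", command),
    sprintf("# package: segexplore %s",
            as.character(utils::packageVersion("segexplore"))),
    sprintf("# parameters: %s", p))
}

.writeTSV <- function(df, path, command, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsvHeader(command, params), con)
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- .fmt6(df[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## enrichment statistic shared by all aggregation modes
#' Aggregation enrichment statistic
#'
#' `e = log2((f_obs + 1) / (f_rand + 1))`: zero when the observed label
#' frequency equals its background abundance, positive when the label is
#' over-represented at the offset, negative when depleted. Because both
#' frequencies lie in `[0, 1]`, `e` is bounded by
#' `[log2(1/(f_rand+1)), log2(2/(f_rand+1))]`.
#'
#' @param fObs observed frequency in `[0, 1]`.
#' @param fRand background frequency in `[0, 1]`.
#' @return The log2 enrichment.
#' @examples
#' enrichment(0.75, 0.25)  # log2(1.75/1.25)
#' enrichment(0.4, 0.4)    # exactly 0
#' @export
enrichment <- function(fObs, fRand) log2((fObs + 1) / (fRand + 1))
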