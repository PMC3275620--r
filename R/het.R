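## Homoplasy excess test for reticulation: a hybrid taxon carries a mosaic
## genome that destabilizes clades ancestral to its parents; removing it
## makes bootstrap support for those clades jump. The screen removes one
## taxon at a time, recomputes bootstrap support for every baseline split
## retained on the reduced taxon set, and flags (taxon, split) pairs whose
## support rise is a boxplot-rule outlier across removals and at least
## `minRise` points.

## Restrict full-taxon canonical split keys to the taxon set without
## position `tpos`; canonicalize; drop trivial results.
.restrictKeys <- function(keys, tpos) {
  if (!length(keys)) return(character(0))
  n <- nchar(keys[1L])
  red <- paste0(substr(keys, 1L, tpos - 1L), substr(keys, tpos + 1L, n))
  flip <- substr(red, 1L, 1L) == "1"
  red[flip] <- chartr("01", "10", red[flip])
  ones <- nchar(gsub("0", "", red))
  unique(red[ones >= 2L & ones <= (n - 1L) - 2L])
}

#' Homoplasy excess test
#'
#' @param x an [AFLPMatrix-class] with >= 5 taxa.
#' @param method tree method for the bootstraps, "nj" (default) or "mp".
#' @param replicates bootstrap replicates per run; below 100 a stability
#'   warning is recorded in the result.
#' @param seed integer seed.
#' @param minRise minimum absolute support rise (percentage points) for a
#'   flag (default 10).
#' @param mpStarts random-addition starts when `method = "mp"`.
#' @return a [HETResult-class].
#' @export
homoplasyExcessTest <- function(x, method = c("nj", "mp"), replicates = 500L,
                                seed = 1L, minRise = 10, mpStarts = 1L) {
  method <- match.arg(method)
  stopifnot(is(x, "AFLPMatrix"))
  if (nTaxa(x) < 5L) stop("need at least 5 taxa", call. = FALSE)
  warnings <- character(0)
  if (replicates < 100L) {
    msg <- sprintf("replicates = %d: quartiles of the support-change %s",
                   replicates, "distribution may be unstable (< 100)")
    warning(msg, call. = FALSE)
    warnings <- c(warnings, msg)
  }

  base <- .bootstrapRun(x, method, replicates, deriveSeed(seed, "baseline"),
                        mpStarts)
  taxa <- base$taxa
  refKeys <- treeSplits(base$reference, taxa)

  rows <- list()
  for (t_ in taxa) {
    tpos <- match(t_, taxa)
    # baseline reference splits that remain non-trivial once t is dropped,
    # keyed both on the full and the reduced taxon ordering
    restricted <- vapply(refKeys, function(fk) {
      r <- .restrictKeys(fk, tpos)
      if (length(r)) r else NA_character_
    }, character(1))
    sel <- !is.na(restricted) & !duplicated(restricted)
    if (!any(sel)) next
    fullKeyFor <- refKeys[sel]
    keep <- restricted[sel]
    # support of the split in the full analysis, as drawn on the reference
    # tree (the hybrid's destabilizing effect included)
    supFull <- .supportFromSplits(base$repSplits, fullKeyFor)

    xr <- dropTaxa(x, t_)
    run <- .bootstrapRun(xr, method, replicates,
                         deriveSeed(seed, paste0("drop_", t_)), mpStarts)
    # run$taxa is sort(taxa minus t_), the same ordering .restrictKeys
    # produces, so the keys are directly comparable
    supWithout <- .supportFromSplits(run$repSplits, keep)

    rows[[t_]] <- data.frame(taxon = t_, split = fullKeyFor,
                             supportFull = supFull,
                             supportWithout = supWithout,
                             delta = supWithout - supFull,
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  delta <- do.call(rbind, rows)
  if (is.null(delta))
    delta <- data.frame(taxon = character(0), split = character(0),
                        supportFull = numeric(0), supportWithout = numeric(0),
                        delta = numeric(0))

  flags <- delta[0, ]
  for (s in unique(delta$split)) {
    d <- delta[delta$split == s, ]
    if (nrow(d) < 4L) next   # too few removals retain this split
    q <- quantile(d$delta, c(0.25, 0.75), names = FALSE, type = 7)
    cut <- q[2L] + 1.5 * (q[2L] - q[1L])
    hit <- d$delta > cut & d$delta >= minRise
    if (any(hit)) flags <- rbind(flags, d[hit, ])
  }
  new("HETResult", delta = delta, flags = flags,
      replicates = as.integer(replicates), method = method,
      minRise = minRise, taxa = taxa, warnings = warnings)
}

setMethod("show", "HETResult", function(object) {
  cat("Homoplasy excess test (", object@method, ", ", object@replicates,
      " replicates, min rise ", object@minRise, " points)\n", sep = "")
  cat("  (taxon, split) pairs examined:", nrow(object@delta), "\n")
  if (nrow(object@flags)) {
    cat("  flagged pairs suggesting reticulation:\n")
    print(object@flags, row.names = FALSE)
  } else {
    cat("  no reticulation flagged\n")
  }
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})
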