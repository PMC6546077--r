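#' Construct a genetic map
#'
#' An ordered table of molecular markers with linkage group (chromosome)
#' membership and genetic position in cM. Marker names must be unique and
#' positions strictly increasing within each chromosome.
#'
#' @param marker Character vector of marker names (or a data frame with
#'   columns \code{marker}, \code{chr}, \code{pos_cM}).
#' @param chr Chromosome / linkage group labels.
#' @param pos_cM Genetic positions in cM.
#' @return A \code{genetic_map}: a data frame with columns \code{marker},
#'   \code{chr}, \code{pos_cM}, rows ordered by chromosome then position.
#' @export
genetic_map <- function(marker, chr = NULL, pos_cM = NULL) {
  if (is.data.frame(marker)) {
    df <- marker
    need <- c("marker", "chr", "pos_cM")
    if (!all(need %in% names(df)))
      stop("map table must have columns marker, chr, pos_cM")
    df <- df[need]
  } else {
    df <- data.frame(marker = as.character(marker), chr = as.character(chr),
                     pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  }
  df$marker <- as.character(df$marker)
  df$chr <- as.character(df$chr)
  df$pos_cM <- as.numeric(df$pos_cM)
  if (anyNA(df$pos_cM)) stop("map positions must be numeric")
  if (any(df$pos_cM < 0)) stop("map positions must be >= 0")
  df <- df[order(match(df$chr, unique(df$chr)), df$pos_cM), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$marker))
    stop("duplicated marker names in map: ",
         paste(unique(df$marker[duplicated(df$marker)]), collapse = ", "))
  for (ch in unique(df$chr)) {
    p <- df$pos_cM[df$chr == ch]
    if (any(diff(p) <= 0))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

as_genetic_map <- function(x) {
  if (inherits(x, "genetic_map")) x else genetic_map(x)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map>", nrow(x), "markers on", length(unique(x$chr)),
      "chromosome(s); span",
      sum(tapply(x$pos_cM, x$chr, function(p) diff(range(p)))), "cM\n")
  invisible(x)
}
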