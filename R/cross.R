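#' Experimental cross types
#'
#' Defines the mapping population design: backcross (BC), F2 intercross,
#' recombinant inbred lines by selfing (RIL), or doubled haploids (DH).
#' BC, RIL and DH segregate two genotype classes per locus (coded 0/1);
#' F2 segregates three (coded 0/1/2 with 1 the heterozygote).
#'
#' @param name One of \code{"BC"}, \code{"F2"}, \code{"RIL"}, \code{"DH"}
#'   (case-insensitive), or an existing \code{cross_type} object.
#' @return A \code{cross_type} object with fields \code{name},
#'   \code{n_classes} (J), \code{labels} and \code{prior} (the population
#'   expectation of the genotype classes, used as fallback when flanking
#'   marker information is missing).
#' @examples
#' cross_type("F2")$n_classes  # 3
#' @export
cross_type <- function(name) {
  if (inherits(name, "cross_type")) return(name)
  nm <- toupper(as.character(name))
  if (!nm %in% c("BC", "F2", "RIL", "DH"))
    stop("unknown cross type: ", name, " (expected BC, F2, RIL or DH)")
  info <- switch(nm,
    BC  = list(n_classes = 2L, labels = c("Qq", "QQ"), prior = c(0.5, 0.5)),
    DH  = list(n_classes = 2L, labels = c("qq", "QQ"), prior = c(0.5, 0.5)),
    RIL = list(n_classes = 2L, labels = c("qq", "QQ"), prior = c(0.5, 0.5)),
    F2  = list(n_classes = 3L, labels = c("qq", "Qq", "QQ"),
               prior = c(0.25, 0.5, 0.25)))
  structure(c(list(name = nm), info), class = "cross_type")
}

#' @export
print.cross_type <- function(x, ...) {
  cat("<cross_type>", x$name, "with", x$n_classes, "genotype classes (",
      paste(x$labels, collapse = ", "), ")\n")
  invisible(x)
}
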