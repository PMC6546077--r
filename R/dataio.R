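# CSV dialect (documented, enforced):
#   marker file:    columns marker,chr,pos_cM (header required)
#   genotype file:  first column id, remaining columns named by marker;
#                   codes 0..J-1, missing as empty cell, NA or -1
#   phenotype file: first column id, remaining columns time labels (numeric
#                   labels used verbatim, else "t1".."t11" -> 1..11)
#   covariate file: first column id, remaining columns numeric
# All files UTF-8, comma-separated, "." decimal.

new_fm_dataset <- function(cross, map, geno, pheno) {
  structure(list(cross = cross_type(cross), map = as_genetic_map(map),
                 geno = geno, pheno = pheno),
            class = "fm_dataset")
}

parse_time_labels <- function(labels) {
  t <- suppressWarnings(as.numeric(labels))
  if (anyNA(t)) {
    stripped <- sub("^[^0-9+.-]*", "", labels)
    t <- suppressWarnings(as.numeric(stripped))
  }
  if (anyNA(t))
    stop("phenotype column labels are not parseable as time points: ",
         paste(labels[is.na(t)], collapse = ", "))
  t
}

read_fm_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV in ", what, " file ", path, ": ",
                        conditionMessage(e)))
  if (nrow(df) == 0L) stop(what, " file ", path, " has no data rows")
  df
}

#' Load and cross-link a functional-mapping dataset from CSV files
#'
#' Reads the marker map, genotype, phenotype and (optionally) covariate CSV
#' files, checks formats, and links them by individual ID into one
#' consistent dataset. Individuals present in only one file are dropped
#' with a warning; genotype codes outside the cross's alphabet become
#' missing with a warning. IDs are matched case-sensitively as strings.
#'
#' @param pheno_path Phenotype CSV path.
#' @param covar_path Optional covariate CSV path (or \code{NULL}).
#' @param geno_path Genotype CSV path.
#' @param marker_path Marker map CSV path.
#' @param cross Cross type (\code{"BC"}, \code{"F2"}, \code{"RIL"},
#'   \code{"DH"} or a \code{cross_type}).
#' @return An \code{fm_dataset} with components \code{cross}, \code{map},
#'   \code{geno} (\code{ids}, \code{codes}) and \code{pheno} (\code{ids},
#'   \code{times}, \code{values}, \code{covariates}).
#' @export
load_dataset <- function(pheno_path, covar_path = NULL, geno_path,
                         marker_path, cross) {
  cross <- cross_type(cross)
  J <- cross$n_classes

  mk <- read_fm_csv(marker_path, "marker map")
  if (!all(c("marker", "chr", "pos_cM") %in% names(mk)))
    stop("marker file ", marker_path, " must have columns marker,chr,pos_cM")
  map <- genetic_map(mk)

  gn <- read_fm_csv(geno_path, "genotype")
  if (names(gn)[1L] != "id") stop("genotype file first column must be 'id'")
  gids <- as.character(gn$id)
  missing_markers <- setdiff(map$marker, names(gn))
  if (length(missing_markers))
    stop("genotype file lacks columns for mapped markers: ",
         paste(utils::head(missing_markers, 5L), collapse = ", "))
  codes <- as.matrix(gn[, map$marker, drop = FALSE])
  codes[codes %in% c("", "NA", "-1", "-1.0")] <- NA
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & (codes < 0L | codes >= J)
  if (any(bad)) {
    warning(sum(bad), " genotype code(s) outside 0..", J - 1,
            " for cross ", cross$name, " set to missing")
    codes[bad] <- NA_integer_
  }
  rownames(codes) <- gids

  ph <- read_fm_csv(pheno_path, "phenotype")
  if (names(ph)[1L] != "id") stop("phenotype file first column must be 'id'")
  pids <- as.character(ph$id)
  times <- parse_time_labels(names(ph)[-1L])
  if (any(diff(times) <= 0))
    stop("phenotype time points must be strictly increasing, got: ",
         paste(times, collapse = ", "))
  values <- as.matrix(ph[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- pids

  covariates <- NULL
  if (!is.null(covar_path)) {
    cv <- read_fm_csv(covar_path, "covariate")
    if (names(cv)[1L] != "id") stop("covariate file first column must be 'id'")
    covariates <- as.matrix(cv[, -1L, drop = FALSE])
    storage.mode(covariates) <- "double"
    rownames(covariates) <- as.character(cv$id)
  }

  ids <- pids[pids %in% gids]
  if (!is.null(covariates)) ids <- ids[ids %in% rownames(covariates)]
  if (length(ids) == 0L)
    stop("no overlapping individual IDs across input files")
  dropped <- setdiff(union(pids, gids), ids)
  if (length(dropped))
    warning(length(dropped), " individual(s) present in only some files ",
            "dropped: ", paste(utils::head(dropped, 5L), collapse = ", "))

  new_fm_dataset(
    cross, map,
    geno = list(ids = ids, codes = codes[ids, , drop = FALSE]),
    pheno = list(ids = ids, times = times,
                 values = values[ids, , drop = FALSE],
                 covariates = if (is.null(covariates)) NULL
                              else covariates[ids, , drop = FALSE]))
}

diagnostic <- function(code, location, message) {
  list(code = code, location = location, message = message)
}

#' Validate an fm_dataset
#'
#' Checks every structural invariant of the dataset and returns a list of
#' machine-readable diagnostics (empty iff the dataset is valid). Unlike
#' \code{\link{load_dataset}}, violations are reported, not raised.
#'
#' @param ds An \code{fm_dataset}.
#' @return List of diagnostics, each with \code{code}, \code{location},
#'   \code{message}.
#' @export
validate_dataset <- function(ds) {
  out <- list()
  add <- function(code, loc, msg) out[[length(out) + 1L]] <<- diagnostic(code, loc, msg)

  dup <- unique(ds$map$marker[duplicated(ds$map$marker)])
  for (d in dup) add("DUPLICATE_MARKER", d, paste0("marker '", d, "' duplicated in map"))
  for (ch in unique(ds$map$chr)) {
    p <- ds$map$pos_cM[ds$map$chr == ch]
    if (any(diff(p) <= 0))
      add("NON_INCREASING_POSITIONS", ch,
          paste0("positions not strictly increasing on chromosome ", ch))
  }
  tm <- ds$pheno$times
  if (any(diff(tm) <= 0))
    add("NON_INCREASING_TIMES", "pheno$times",
        paste0("time points not strictly increasing: ", paste(tm, collapse = ",")))
  if (anyDuplicated(ds$pheno$ids))
    add("DUPLICATE_ID", "pheno$ids", "duplicated individual IDs")
  if (!identical(ds$geno$ids, ds$pheno$ids))
    add("ID_MISMATCH", "geno/pheno", "individual IDs not aligned across genotype and phenotype")
  if (ncol(ds$geno$codes) != nrow(ds$map))
    add("MARKER_COUNT_MISMATCH", "geno$codes",
        "genotype column count differs from map marker count")
  J <- ds$cross$n_classes
  cd <- ds$geno$codes
  if (any(!is.na(cd) & (cd < 0L | cd >= J)))
    add("BAD_GENOTYPE_CODE", "geno$codes",
        paste0("genotype codes outside 0..", J - 1))
  cv <- ds$pheno$covariates
  if (!is.null(cv) && nrow(cv) != nrow(ds$pheno$values))
    add("COVARIATE_MISALIGNED", "pheno$covariates",
        "covariate rows do not align with phenotype rows")
  out
}

#' @export
print.fm_dataset <- function(x, ...) {
  cat("<fm_dataset>", x$cross$name, "cross:", length(x$pheno$ids),
      "individuals,", nrow(x$map), "markers on",
      length(unique(x$map$chr)), "chromosome(s),",
      length(x$pheno$times), "time points\n")
  if (!is.null(x$pheno$covariates))
    cat("  ", ncol(x$pheno$covariates), "covariate(s)\n")
  invisible(x)
}
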