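#' Canonical trait set
#'
#' The seven tissue traits spanning the three vegetative organs: leaf mass
#' per area (LMA, g/m2), leaf tissue density (LTD, mg/mm3), leaf dry matter
#' content (LDMC, fraction), wood density (WD, mg/mm3), wood dry matter
#' content (WDMC, fraction), fine-root tissue density (RTD, mg/mm3) and
#' fine-root dry matter content (RDMC, fraction).
#'
#' @export
TRAIT_NAMES <- c("LMA", "LTD", "LDMC", "WD", "WDMC", "RTD", "RDMC")

#' Species-level trait table
#'
#' A species x trait matrix of mean trait values for one environment (or
#' ontogeny group), with per-cell replicate counts. All analyses downstream
#' of the measurement layer operate on these species means. Missing cells
#' are explicit \code{NA}, never silently zero.
#'
#' @param traits numeric matrix, species in rows (rownames required), traits
#'   in columns (colnames required).
#' @param counts integer matrix of replicate counts, same dimensions as
#'   \code{traits}; defaults to 1 for every non-missing cell.
#' @param environment label for the growing environment, e.g.
#'   \code{"cultivated"}, \code{"wild_juvenile"} or \code{"wild_mature"}.
#'
#' @return An object of class \code{trait_table}: a list with elements
#'   \code{species}, \code{traits} (matrix), \code{counts}, \code{environment}.
#' @export
trait_table <- function(traits, counts = NULL, environment = "unspecified") {
  traits <- as.matrix(traits)
  if (is.null(rownames(traits)) || is.null(colnames(traits)))
    stop("trait matrix must have species rownames and trait colnames")
  if (anyDuplicated(rownames(traits)))
    stop("duplicate species in trait table")
  if (is.null(counts)) {
    counts <- matrix(1L, nrow(traits), ncol(traits),
                     dimnames = dimnames(traits))
    counts[is.na(traits)] <- 0L
  }
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), dim(traits)))
  structure(list(species = rownames(traits), traits = traits,
                 counts = counts, environment = environment),
            class = "trait_table")
}

#' @export
as.matrix.trait_table <- function(x, ...) x$traits

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Species trait table (%s): %d species x %d traits\n",
              x$environment, nrow(x$traits), ncol(x$traits)))
  cat("Traits:", paste(colnames(x$traits), collapse = ", "), "\n")
  n_missing <- sum(is.na(x$traits))
  if (n_missing > 0) cat("Missing cells:", n_missing, "\n")
  print(utils::head(x$traits, 6L))
  if (nrow(x$traits) > 6L) cat("...", nrow(x$traits) - 6L, "more species\n")
  invisible(x)
}

#' Trait names of a trait table
#' @param x a \code{trait_table}.
#' @return character vector of trait column names.
#' @export
trait_names <- function(x) colnames(x$traits)

#' Restrict a trait table to species with complete rows
#'
#' @param x a \code{trait_table}.
#' @param traits traits that must be non-missing (default: all columns).
#' @return a \code{trait_table} containing only complete species; a message
#'   reports how many species were dropped.
#' @export
complete_species <- function(x, traits = trait_names(x)) {
  stopifnot(inherits(x, "trait_table"), all(traits %in% trait_names(x)))
  keep <- stats::complete.cases(x$traits[, traits, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " species dropped (missing values in ",
            paste(traits, collapse = ", "), ")")
  trait_table(x$traits[keep, , drop = FALSE],
              x$counts[keep, , drop = FALSE], x$environment)
}
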