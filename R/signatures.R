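#' Named gene-set collection
#'
#' Holds named gene sets (the DDG signature, immune-cell signatures, ...) as a
#' named list of character vectors plus one description per set, mirroring the
#' GMT format.
#'
#' @param sets Named list of non-empty character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @return An object of class `signature_collection`.
#' @export
signature_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    ln_stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    ln_stop("duplicate set names: %s",
            paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) ln_stop("empty gene set(s): %s", paste(empty, collapse = ", "))
  descriptions <- descriptions %||% stats::setNames(rep("", length(sets)), names(sets))
  descriptions <- descriptions[names(sets)]
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("<signature_collection> %d set(s)\n", length(x$sets)))
  for (nm in utils::head(names(x$sets), 10))
    cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  if (length(x$sets) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
length.signature_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then gene symbols. Within-set duplicates are removed, order preserved; a
#' line with fewer than three fields is a hard error. An empty file yields an
#' empty collection.
#'
#' @param path Path to a GMT file.
#' @return A [signature_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(structure(list(sets = stats::setNames(list(), character()),
                          descriptions = stats::setNames(character(), character())),
                     class = "signature_collection"))
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      ln_stop("GMT line %d has %d field(s); need name, description and >=1 gene",
              i, length(fields))
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    desc[fields[1]] <- fields[2]
  }
  signature_collection(sets, desc)
}

#' Write a GMT gene-set file
#'
#' @param x A [signature_collection()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, if (nzchar(x$descriptions[[nm]])) x$descriptions[[nm]] else "na",
            x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(x)
}
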