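#' Construct a module set
#'
#' A module is a character vector of gene ids (size >= 2 in normal operation);
#' a module set is a uniquely named list of modules carrying a shared stage
#' tag (\code{"SPE"}, \code{"large"} or \code{"FGMD"}) and optional per-module
#' provenance (the originating seed pair or parent module).
#'
#' @param modules Named (or unnamed, auto-named) list of character vectors.
#' @param stage Stage tag.
#' @param provenance Optional character vector, one entry per module.
#' @return An object of class \code{module_set}.
#' @export
module_set <- function(modules, stage = c("SPE", "large", "FGMD"),
                       provenance = NULL) {
  stage <- match.arg(stage)
  if (!is.list(modules)) stop("modules must be a list", call. = FALSE)
  if (is.null(names(modules)))
    names(modules) <- sprintf("%s_%d", stage, seq_along(modules))
  if (anyDuplicated(names(modules)))
    stop("module names must be unique", call. = FALSE)
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  if (!is.null(provenance) && length(provenance) != length(modules))
    stop("provenance must have one entry per module", call. = FALSE)
  structure(list(modules = modules, stage = stage, provenance = provenance),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat("Module set (stage ", x$stage, "): ", length(sizes), " modules\n",
      sep = "")
  if (length(sizes))
    cat("  sizes: min ", min(sizes), ", mean ", round(mean(sizes), 1),
        ", max ", max(sizes), "; unique genes ",
        length(unique(unlist(x$modules))), "\n", sep = "")
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$modules)

#' Export a module set as TSV
#'
#' One line per module: \code{module_id}, \code{stage}, \code{n_genes},
#' comma-separated members (sorted, so exports are byte-stable).
#'
#' @param ms A \code{module_set}.
#' @param path Output path.
#' @export
write_modules_tsv <- function(ms, path) {
  stopifnot(inherits(ms, "module_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("module_id\tstage\tn_genes\tmembers", con)
  for (nm in names(ms$modules))
    writeLines(paste(nm, ms$stage, length(ms$modules[[nm]]),
                     paste(ms$modules[[nm]], collapse = ","), sep = "\t"),
               con)
  invisible(path)
}

#' Read a module-set TSV written by \code{\link{write_modules_tsv}}
#'
#' @param path File path.
#' @return A \code{module_set}.
#' @export
read_modules_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mods <- strsplit(df$members, ",", fixed = TRUE)
  names(mods) <- df$module_id
  stage <- if (nrow(df)) df$stage[1L] else "FGMD"
  module_set(mods, stage = stage)
}
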