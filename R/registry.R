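# FA / HFA building-block registries.
#
# A registry is a data frame with columns abbreviation, carbon_count,
# double_bonds, hydroxyl_position (NA for plain FAs) and full_name.  The
# package ships default registries of 23 common long-chain fatty acids and
# 23 hydroxy fatty acids under inst/extdata; both are synthetic placeholder
# lists of common species (the hydroxyl placed at C9 throughout the HFA
# list) and can be replaced by any user table with the same columns.

.REGISTRY_COLS <- c("abbreviation", "carbon_count", "double_bonds",
                    "hydroxyl_position", "full_name")

#' Read a fatty-acyl registry from a delimited table
#'
#' @param path TSV file with columns `abbreviation`, `carbon_count`,
#'   `double_bonds`, `hydroxyl_position` (blank/NA for a plain FA) and
#'   `full_name`.
#' @return a data frame with those columns; every row validated against the
#'   fatty-acyl invariants and the abbreviation checked to round-trip
#'   through [parse_shorthand()].
#' @export
read_registry <- function(path) {
  reg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing <- setdiff(.REGISTRY_COLS, names(reg))
  if (length(missing)) {
    stop("registry ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(reg))) {
    acyl <- fatty_acyl(reg$carbon_count[i], reg$double_bonds[i],
                       if (is.na(reg$hydroxyl_position[i])) NULL
                       else reg$hydroxyl_position[i])
    parsed <- parse_shorthand(reg$abbreviation[i])
    if (!identical(unclass(parsed), unclass(acyl))) {
      stop("registry row ", i, ": abbreviation '", reg$abbreviation[i],
           "' does not match its (carbon, double-bond, hydroxyl) fields")
    }
  }
  reg[.REGISTRY_COLS]
}

#' Write a fatty-acyl registry
#' @param reg registry data frame (see [read_registry()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  utils::write.table(reg[.REGISTRY_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Default building-block registries
#'
#' The 23-entry fatty-acid and 23-entry hydroxy-fatty-acid lists shipped
#' with the package (`inst/extdata/fa_registry.tsv`,
#' `inst/extdata/hfa_registry.tsv`).  The HFA list mirrors the FA chain set
#' with a hydroxyl at C9, so the 23 x 23 combinatorial product spans 529
#' distinct FAHFA families.  Both lists are synthetic placeholders for a
#' laboratory's own standards table.
#'
#' @return `default_fa_registry()` and `default_hfa_registry()` each return
#'   a registry data frame.
#' @export
default_fa_registry <- function() {
  read_registry(system.file("extdata", "fa_registry.tsv", package = "cilfahfa",
                            mustWork = TRUE))
}

#' @rdname default_fa_registry
#' @export
default_hfa_registry <- function() {
  read_registry(system.file("extdata", "hfa_registry.tsv", package = "cilfahfa",
                            mustWork = TRUE))
}

#' Convert registry rows to fatty_acyl objects
#' @param reg a registry data frame.
#' @return a list of [fatty_acyl], named by abbreviation.
#' @export
registry_acyls <- function(reg) {
  out <- lapply(seq_len(nrow(reg)), function(i) {
    fatty_acyl(reg$carbon_count[i], reg$double_bonds[i],
               if (is.na(reg$hydroxyl_position[i])) NULL
               else reg$hydroxyl_position[i])
  })
  names(out) <- reg$abbreviation
  out
}
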