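# Molecular formulas and monoisotopic masses.
#
# A chem_formula is a named integer vector of element counts (Hill order:
# C, H, then remaining symbols alphabetically).  Deuterium is carried as the
# pseudo-element "D" so that light/heavy labeling reagents differ only in
# their count maps.

# Most-abundant-isotope masses, fixed so results are bit-stable across
# library versions.  Extend here if a new element is ever needed.
.ISOTOPE_MASS <- c(
  C  = 12.000000,
  H  = 1.0078250319,
  D  = 2.0141017780,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928
)

#' Mass of the charge-carrying proton in Da
#' @export
PROTON_MASS <- 1.00727646

#' Construct a molecular formula
#'
#' @param x either a named numeric vector of element counts
#'   (e.g. `c(C = 16, H = 32, O = 2)`) or a formula string such as
#'   `"C16H32O2"`.  Counts must be non-negative integers; zero counts are
#'   dropped.
#' @return an object of class `chem_formula`: a named integer vector in
#'   Hill order (C, H, then alphabetical).
#' @examples
#' chem_formula("C16H32O2")
#' chem_formula(c(H = 2, O = 1))
#' @export
chem_formula <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- .parse_formula_string(x)
  }
  if (length(x) == 0L) {
    return(structure(integer(0), class = "chem_formula"))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("element counts must be named by element symbol")
  }
  if (any(x < 0)) {
    stop("negative element count for ", paste(names(x)[x < 0], collapse = ", "))
  }
  if (any(x != round(x))) stop("element counts must be integers")
  counts <- tapply(as.integer(x), names(x), sum)
  counts <- counts[counts > 0L]
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(.hill_order(out), class = "chem_formula")
}

.parse_formula_string <- function(s) {
  s0 <- s
  s <- gsub("[[:space:]]", "", s)
  counts <- integer(0)
  while (nzchar(s)) {
    m <- regmatches(s, regexec("^([A-Z][a-z]?)([0-9]*)", s))[[1]]
    if (length(m) == 0L || !nzchar(m[1])) {
      stop("cannot parse formula '", s0, "' at '", s, "'")
    }
    n <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    counts[m[2]] <- (if (m[2] %in% names(counts)) counts[[m[2]]] else 0L) + n
    s <- substring(s, nchar(m[1]) + 1L)
  }
  counts
}

.hill_order <- function(counts) {
  syms <- names(counts)
  first <- intersect(c("C", "H"), syms)
  rest <- sort(setdiff(syms, first))
  counts[c(first, rest)]
}

#' @export
format.chem_formula <- function(x, ...) {
  counts <- unclass(x)
  if (length(counts) == 0L) return("")
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "chem_formula"), inherits(e2, "chem_formula"))
  chem_formula(c(unclass(e1), unclass(e2)))
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "chem_formula"), inherits(e2, "chem_formula"))
  res <- unclass(e1)
  for (el in names(e2)) {
    res[el] <- (if (el %in% names(res)) res[[el]] else 0L) - e2[[el]]
  }
  if (any(res < 0)) {
    stop("subtraction would give a negative count for ",
         paste(names(res)[res < 0], collapse = ", "))
  }
  chem_formula(res[res > 0L])
}

#' @export
`==.chem_formula` <- function(e1, e2) {
  stopifnot(inherits(e1, "chem_formula"), inherits(e2, "chem_formula"))
  identical(unclass(e1), unclass(e2))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums element counts times the mass of each element's most abundant
#' isotope.  Additive: `monoisotopic_mass(a + b)` equals
#' `monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param f a [chem_formula] (or something coercible by [chem_formula()]).
#' @return mass in Da; `0` for the empty formula.
#' @examples
#' monoisotopic_mass(chem_formula("H2O"))     # 18.0106
#' monoisotopic_mass(chem_formula("C16H32O2")) # 256.2402, palmitic acid
#' @export
monoisotopic_mass <- function(f) {
  if (!inherits(f, "chem_formula")) f <- chem_formula(f)
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(.ISOTOPE_MASS))
  if (length(unknown)) {
    stop("no isotope mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.ISOTOPE_MASS[names(f)] * as.numeric(f))
}

# Water, lost in every condensation handled by the package.
water_formula <- function() chem_formula(c(H = 2L, O = 1L))
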