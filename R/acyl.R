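# Fatty acyl chains, hydroxy fatty acids and FAHFA regioisomers.
#
# Shorthand follows the lipidomics C:D convention ("18:1"); a hydroxy fatty
# acid carries its hydroxyl position as a numeric prefix ("9-OH-18:0").
# Positions are numbered from the carboxyl carbon (C1) throughout, matching
# FAHFA trivial nomenclature such as 9-PAHSA.

#' Construct a fatty acyl chain
#'
#' @param carbon number of carbons (integer, >= 4).
#' @param double_bonds number of C=C double bonds (integer, >= 0, at most
#'   `carbon - 2`).
#' @param hydroxyl hydroxyl position counted from the carboxyl carbon C1,
#'   or `NULL`/`NA` for a plain (non-hydroxy) fatty acid.  When present it
#'   must lie in `[2, carbon]` and marks the acyl as a hydroxy fatty acid.
#' @return an object of class `fatty_acyl`.
#' @examples
#' fatty_acyl(18, 1)          # oleic acid, "18:1"
#' fatty_acyl(18, 0, 9)       # 9-hydroxystearic acid, "9-OH-18:0"
#' @export
fatty_acyl <- function(carbon, double_bonds = 0L, hydroxyl = NULL) {
  carbon <- as.integer(carbon)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbon) || carbon < 4L) stop("carbon count must be an integer >= 4")
  if (is.na(double_bonds) || double_bonds < 0L) {
    stop("double bond count must be a non-negative integer")
  }
  if (double_bonds > carbon - 2L) {
    stop("double bond count ", double_bonds, " impossible for a C", carbon, " acid")
  }
  if (!is.null(hydroxyl) && !is.na(hydroxyl)) {
    hydroxyl <- as.integer(hydroxyl)
    if (hydroxyl < 2L || hydroxyl > carbon) {
      stop("hydroxyl position must lie in [2, ", carbon, "], got ", hydroxyl)
    }
  } else {
    hydroxyl <- NA_integer_
  }
  structure(
    list(carbon = carbon, double_bonds = double_bonds, hydroxyl = hydroxyl),
    class = "fatty_acyl"
  )
}

#' @export
format.fatty_acyl <- function(x, ...) {
  base <- sprintf("%d:%d", x$carbon, x$double_bonds)
  if (is_hfa(x)) sprintf("%d-OH-%s", x$hydroxyl, base) else base
}

#' @export
print.fatty_acyl <- function(x, ...) {
  kind <- if (is_hfa(x)) "hydroxy fatty acid" else "fatty acid"
  cat("<fatty_acyl> ", format(x), " (", kind, ")\n", sep = "")
  invisible(x)
}

#' Is the acyl a hydroxy fatty acid?
#' @param x a [fatty_acyl].
#' @return `TRUE` iff a hydroxyl position is present.
#' @export
is_hfa <- function(x) {
  inherits(x, "fatty_acyl") && !is.na(x$hydroxyl)
}

#' Neutral free-acid formula of a fatty acyl
#'
#' A saturated acid is CnH(2n)O2; each double bond removes H2; a hydroxyl
#' adds one oxygen.
#'
#' @param acyl a [fatty_acyl].
#' @return a [chem_formula] for the free (hydroxy) fatty acid.
#' @examples
#' acyl_formula(fatty_acyl(16, 0))      # C16H32O2
#' acyl_formula(fatty_acyl(18, 0, 9))   # C18H36O3
#' @export
acyl_formula <- function(acyl) {
  stopifnot(inherits(acyl, "fatty_acyl"))
  h <- 2L * acyl$carbon - 2L * acyl$double_bonds
  o <- if (is_hfa(acyl)) 3L else 2L
  chem_formula(c(C = acyl$carbon, H = h, O = o))
}

#' Esterify a fatty acid onto a hydroxy fatty acid
#'
#' Condenses the FA carboxyl with the HFA hydroxyl, losing one water, to
#' give a FAHFA regioisomer.  The ester position is the carbon index of the
#' HFA hydroxyl bearing the FA, counted from the carboxyl carbon C1.
#'
#' @param fa a non-hydroxylated [fatty_acyl].
#' @param hfa a [fatty_acyl]; its hydroxyl position, if present, is the
#'   default ester position.
#' @param position ester position; defaults to `hfa`'s hydroxyl position.
#'   Must lie in `[2, hfa$carbon]`.
#' @return an object of class `fahfa_regioisomer` with fields `fa`,
#'   `hfa_chain` (the HFA base chain), `ester_position`, `family`
#'   (identifier ignoring the position) and `formula` (neutral).
#' @examples
#' combine_esterify(fatty_acyl(16, 0), fatty_acyl(18, 0, 9))  # 9-PAHSA
#' @export
combine_esterify <- function(fa, hfa, position = NULL) {
  stopifnot(inherits(fa, "fatty_acyl"), inherits(hfa, "fatty_acyl"))
  if (is_hfa(fa)) stop("the FA partner must not carry a hydroxyl")
  if (is.null(position)) {
    if (!is_hfa(hfa)) stop("no ester position given and the HFA has no hydroxyl")
    position <- hfa$hydroxyl
  }
  position <- as.integer(position)
  if (is.na(position) || position < 2L || position > hfa$carbon) {
    stop("ester position must lie in [2, ", hfa$carbon, "], got ", position)
  }
  chain <- fatty_acyl(hfa$carbon, hfa$double_bonds)          # base chain
  hfa_acid <- fatty_acyl(hfa$carbon, hfa$double_bonds, position)
  formula <- acyl_formula(fa) + acyl_formula(hfa_acid) - water_formula()
  structure(
    list(
      fa = fa,
      hfa_chain = chain,
      ester_position = position,
      family = family_key(fa, chain),
      formula = formula
    ),
    class = "fahfa_regioisomer"
  )
}

#' Family identifier for a FAHFA composition
#'
#' A family names which FA sits on which HFA backbone, ignoring the ester
#' position, e.g. `"16:0-O-18:0"`.
#'
#' @param fa the fatty acid ([fatty_acyl], no hydroxyl).
#' @param hfa_chain the HFA base chain ([fatty_acyl]; any hydroxyl is
#'   ignored).
#' @return a character scalar.
#' @export
family_key <- function(fa, hfa_chain) {
  sprintf("%d:%d-O-%d:%d", fa$carbon, fa$double_bonds,
          hfa_chain$carbon, hfa_chain$double_bonds)
}

#' @export
format.fahfa_regioisomer <- function(x, ...) {
  if (is.na(x$ester_position)) {
    sprintf("FAHFA (%s)", x$family)
  } else {
    sprintf("%s-O-%d-OH-%s", format(x$fa), x$ester_position, format(x$hfa_chain))
  }
}

#' @export
print.fahfa_regioisomer <- function(x, ...) {
  cat("<fahfa_regioisomer> ", format(x),
      "  [family ", x$family, ", ", format(x$formula), "]\n", sep = "")
  invisible(x)
}

# Trivial-name aliases (position prefix allowed, e.g. "9-PAHSA").
.FAHFA_ALIASES <- list(
  PAHSA = list(fa = c(16L, 0L), hfa = c(18L, 0L)),  # palmitic on hydroxystearic
  OAHSA = list(fa = c(18L, 1L), hfa = c(18L, 0L)),  # oleic on hydroxystearic
  PAHPA = list(fa = c(16L, 0L), hfa = c(16L, 0L)),  # palmitic on hydroxypalmitic
  SAHSA = list(fa = c(18L, 0L), hfa = c(18L, 0L))   # stearic on hydroxystearic
)

#' Parse fatty-acyl / FAHFA shorthand
#'
#' Grammar:
#' \itemize{
#'   \item `"18:1"` — fatty acid.
#'   \item `"9-OH-18:0"` — hydroxy fatty acid, hydroxyl at C9.
#'   \item `"FAHFA (16:0-O-18:0)"` or `"16:0-O-18:0"` — FAHFA family
#'     (ester position unspecified, returned with `ester_position = NA`).
#'   \item `"16:0-O-9-OH-18:0"` — FAHFA regioisomer at a stated position.
#'   \item `"9-PAHSA"` — trivial names via a small alias table
#'     (PAHSA, OAHSA, PAHPA, SAHSA).
#' }
#' `parse_shorthand(format(x))` round-trips every registry entry.
#'
#' @param text a single shorthand string.
#' @return a [fatty_acyl] or a `fahfa_regioisomer` (family entries carry
#'   `ester_position = NA`).
#' @examples
#' parse_shorthand("18:1")
#' parse_shorthand("9-OH-18:0")
#' parse_shorthand("9-PAHSA")
#' @export
parse_shorthand <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  # unwrap "FAHFA ( ... )"
  m <- regmatches(s, regexec("^FAHFA\\s*\\((.*)\\)$", s))[[1]]
  if (length(m)) s <- trimws(m[2])

  # trivial alias, optional position prefix
  m <- regmatches(s, regexec("^(?:([0-9]+)-)?([A-Z]{5})$", s))[[1]]
  if (length(m) && m[3] %in% names(.FAHFA_ALIASES)) {
    a <- .FAHFA_ALIASES[[m[3]]]
    fa <- fatty_acyl(a$fa[1], a$fa[2])
    if (nzchar(m[2])) {
      return(combine_esterify(fa, fatty_acyl(a$hfa[1], a$hfa[2]), as.integer(m[2])))
    }
    return(.fahfa_family(fa, fatty_acyl(a$hfa[1], a$hfa[2])))
  }

  if (grepl("-O-", s, fixed = TRUE)) {
    halves <- strsplit(s, "-O-", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("cannot parse FAHFA shorthand '", text, "'")
    fa <- parse_shorthand(halves[1])
    if (!inherits(fa, "fatty_acyl") || is_hfa(fa)) {
      stop("FA part of '", text, "' must be a plain fatty acid: '", halves[1], "'")
    }
    hfa <- parse_shorthand(halves[2])
    if (!inherits(hfa, "fatty_acyl")) stop("cannot parse HFA part '", halves[2], "'")
    if (is_hfa(hfa)) return(combine_esterify(fa, hfa))
    return(.fahfa_family(fa, hfa))
  }

  m <- regmatches(s, regexec("^(?:([0-9]+)-OH-)?([0-9]+):([0-9]+)$", s))[[1]]
  if (length(m) == 0L || !nzchar(m[1])) {
    stop("unparseable shorthand token '", s, "'")
  }
  hydroxyl <- if (nzchar(m[2])) as.integer(m[2]) else NULL
  fatty_acyl(as.integer(m[3]), as.integer(m[4]), hydroxyl)
}

# family-level regioisomer record: position unknown
.fahfa_family <- function(fa, chain) {
  structure(
    list(
      fa = fa,
      hfa_chain = fatty_acyl(chain$carbon, chain$double_bonds),
      ester_position = NA_integer_,
      family = family_key(fa, chain),
      formula = acyl_formula(fa) +
        acyl_formula(fatty_acyl(chain$carbon, chain$double_bonds, 2L)) -
        water_formula()
    ),
    class = "fahfa_regioisomer"
  )
}
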