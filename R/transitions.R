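# Combinatorial MRM transition design for DMED / d4-DMED labeled FAHFAs.
#
# Derivatization chemistry: the FAHFA free carboxyl (on the HFA) is amide-
# coupled to DMED (2-dimethylaminoethylamine, C4H12N2) with loss of water;
# the heavy channel uses d4-DMED (four H -> D, +4.0251 Da).  Ionization is
# positive, singly protonated.  Fragmentation: the labeled precursor loses
# the FA as a ketene-type neutral to give the labeled HFA fragment, which
# further loses dimethylamine + water (63.0684 Da light, 67.0935 Da heavy),
# so the light and heavy product ions coincide while the precursors sit
# 4.0251 Da apart -- the peak-pair signature screened downstream.

#' Construct a labeling scheme
#'
#' @param name `"light"` or `"heavy"`.
#' @param reagent [chem_formula] of the amine reagent; amide condensation
#'   with the analyte carboxyl loses one water.
#' @param charge_carrier_mass Da added by the charge carrier (a proton).
#' @param neutral_loss [chem_formula] lost from the labeled HFA fragment to
#'   form the product ion.
#' @return an object of class `labeling_scheme`.
#' @export
labeling_scheme <- function(name, reagent, charge_carrier_mass = PROTON_MASS,
                            neutral_loss) {
  name <- match.arg(name, c("light", "heavy"))
  stopifnot(inherits(reagent, "chem_formula"), inherits(neutral_loss, "chem_formula"))
  structure(
    list(
      name = name,
      reagent = reagent,
      net_addition_mass = monoisotopic_mass(reagent) -
        monoisotopic_mass(water_formula()),
      charge_carrier_mass = charge_carrier_mass,
      neutral_loss_mass = monoisotopic_mass(neutral_loss)
    ),
    class = "labeling_scheme"
  )
}

#' Default DMED / d4-DMED labeling schemes
#'
#' Light: DMED (C4H12N2), net addition +70.0895 Da after water loss,
#' neutral loss dimethylamine + water (C2H9NO, 63.0684 Da).  Heavy:
#' d4-DMED (C4H8D4N2), +74.1146 Da, neutral loss C2H5D4NO (67.0935 Da).
#' The four deuteriums reside in the lost neutral, so light and heavy
#' product ions coincide while the precursors differ by 4.0251 Da.
#'
#' @return a named list with elements `light` and `heavy`.
#' @export
default_labeling_schemes <- function() {
  list(
    light = labeling_scheme(
      "light",
      reagent = chem_formula(c(C = 4L, H = 12L, N = 2L)),
      neutral_loss = chem_formula(c(C = 2L, H = 9L, N = 1L, O = 1L))
    ),
    heavy = labeling_scheme(
      "heavy",
      reagent = chem_formula(c(C = 4L, H = 8L, D = 4L, N = 2L)),
      neutral_loss = chem_formula(c(C = 2L, H = 5L, D = 4L, N = 1L, O = 1L))
    )
  )
}

# parse a family key "16:0-O-18:0" into its two chains
.parse_family_key <- function(key) {
  halves <- strsplit(key, "-O-", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("malformed family key '", key, "'")
  fa <- parse_shorthand(halves[1])
  chain <- parse_shorthand(halves[2])
  list(fa = fa, hfa_chain = chain)
}

#' Enumerate FAHFA families from building-block registries
#'
#' Forms the Cartesian product of the FA list and the HFA list, keyed by
#' family (FA composition x HFA base chain, ignoring the hydroxyl/ester
#' position), deduplicated, in deterministic order (FA carbons, FA double
#' bonds, HFA carbons, HFA double bonds).  23 FAs x 23 HFAs with distinct
#' chains give the full 529-family design.
#'
#' @param fas list of non-hydroxylated [fatty_acyl] (or a registry data
#'   frame).
#' @param hfas list of hydroxylated [fatty_acyl] (or a registry data frame).
#' @return data frame with columns `family`, `fa`, `hfa_chain`
#'   (abbreviations) -- one row per distinct family.
#' @export
enumerate_families <- function(fas = default_fa_registry(),
                               hfas = default_hfa_registry()) {
  if (is.data.frame(fas)) fas <- registry_acyls(fas)
  if (is.data.frame(hfas)) hfas <- registry_acyls(hfas)
  if (any(vapply(fas, is_hfa, logical(1)))) {
    stop("the FA list must contain only non-hydroxylated acyls")
  }
  if (length(fas) == 0L || length(hfas) == 0L) {
    return(data.frame(family = character(0), fa = character(0),
                      hfa_chain = character(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(i = seq_along(fas), j = seq_along(hfas))
  fa_c <- vapply(fas, `[[`, integer(1), "carbon")[grid$i]
  fa_d <- vapply(fas, `[[`, integer(1), "double_bonds")[grid$i]
  hfa_c <- vapply(hfas, `[[`, integer(1), "carbon")[grid$j]
  hfa_d <- vapply(hfas, `[[`, integer(1), "double_bonds")[grid$j]
  rows <- data.frame(
    family = sprintf("%d:%d-O-%d:%d", fa_c, fa_d, hfa_c, hfa_d),
    fa = sprintf("%d:%d", fa_c, fa_d),
    hfa_chain = sprintf("%d:%d", hfa_c, hfa_d),
    fa_c = fa_c, fa_d = fa_d, hfa_c = hfa_c, hfa_d = hfa_d,
    stringsAsFactors = FALSE
  )
  rows <- rows[!duplicated(rows$family), , drop = FALSE]
  rows <- rows[order(rows$fa_c, rows$fa_d, rows$hfa_c, rows$hfa_d), , drop = FALSE]
  rownames(rows) <- NULL
  rows[c("family", "fa", "hfa_chain")]
}

#' Precursor m/z of a labeled FAHFA family
#'
#' Mass of the neutral FAHFA (FA + hydroxy acid - H2O) plus the labeling
#' net addition plus the proton, singly charged.
#'
#' @param family a family key such as `"16:0-O-18:0"`.
#' @param scheme a [labeling_scheme].
#' @return m/z in Da.
#' @export
precursor_mz <- function(family, scheme) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  p <- .parse_family_key(family)
  hfa_acid <- fatty_acyl(p$hfa_chain$carbon, p$hfa_chain$double_bonds, 2L)
  neutral <- monoisotopic_mass(acyl_formula(p$fa)) +
    monoisotopic_mass(acyl_formula(hfa_acid)) -
    monoisotopic_mass(water_formula())
  neutral + scheme$net_addition_mass + scheme$charge_carrier_mass
}

#' Product m/z of a labeled FAHFA family
#'
#' The labeled, protonated HFA fragment minus the scheme's neutral loss.
#' Depends only on the HFA backbone; under the default schemes the light
#' and heavy product m/z coincide because the mass tag sits in the lost
#' neutral.
#'
#' @inheritParams precursor_mz
#' @return m/z in Da; values below 50 Da raise an error (nonphysical
#'   channel).
#' @export
product_mz <- function(family, scheme) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  p <- .parse_family_key(family)
  hfa_acid <- fatty_acyl(p$hfa_chain$carbon, p$hfa_chain$double_bonds, 2L)
  mz <- monoisotopic_mass(acyl_formula(hfa_acid)) +
    scheme$net_addition_mass + scheme$charge_carrier_mass -
    scheme$neutral_loss_mass
  if (mz < 50) {
    stop("product m/z ", round(mz, 4), " below 50 Da for family ", family)
  }
  mz
}

#' Build the light/heavy MRM transition list
#'
#' Emits exactly two transitions (one per labeling channel) for every
#' family, in stable family order then light before heavy.
#'
#' @param families data frame from [enumerate_families()] (or a character
#'   vector of family keys).
#' @param schemes list with `light` and `heavy` [labeling_scheme]s.
#' @param collision_energy collision energy recorded for every transition
#'   (eV); the instrument-optimized per-channel values can be supplied via
#'   a column on import instead.
#' @return data frame with columns `compound`, `channel`, `precursor_mz`,
#'   `product_mz`, `polarity`, `collision_energy`, `method_index`
#'   (`NA` until scheduled by [schedule_methods()]).
#' @export
build_transition_list <- function(families,
                                  schemes = default_labeling_schemes(),
                                  collision_energy = 35) {
  keys <- if (is.data.frame(families)) families$family else as.character(families)
  if (length(keys) == 0L) {
    return(data.frame(compound = character(0), channel = character(0),
                      precursor_mz = numeric(0), product_mz = numeric(0),
                      polarity = character(0), collision_energy = numeric(0),
                      method_index = integer(0), stringsAsFactors = FALSE))
  }
  # masses are computed once per distinct chain, then combined per family
  fa_keys <- sub("-O-.*$", "", keys)
  chain_keys <- sub("^.*-O-", "", keys)
  acid_mass <- function(k, hydroxyl = FALSE) {
    p <- parse_shorthand(k)
    monoisotopic_mass(acyl_formula(
      fatty_acyl(p$carbon, p$double_bonds, if (hydroxyl) 2L else NULL)))
  }
  fa_mass <- vapply(unique(fa_keys), acid_mass, numeric(1))
  hfa_mass <- vapply(unique(chain_keys), acid_mass, numeric(1), hydroxyl = TRUE)
  water <- monoisotopic_mass(water_formula())
  pre <- lapply(schemes[c("light", "heavy")], function(sch) {
    fa_mass[fa_keys] + hfa_mass[chain_keys] - water +
      sch$net_addition_mass + sch$charge_carrier_mass
  })
  prod <- lapply(schemes[c("light", "heavy")], function(sch) {
    hfa_mass[chain_keys] + sch$net_addition_mass + sch$charge_carrier_mass -
      sch$neutral_loss_mass
  })
  low <- pmin(prod$light, prod$heavy) < 50
  if (any(low)) {
    stop("family ", keys[low][1], ": product m/z ",
         round(pmin(prod$light, prod$heavy)[low][1], 4),
         " below 50 Da (nonphysical channel)")
  }
  out <- data.frame(
    compound = rep(keys, each = 2L),
    channel = rep(c("light", "heavy"), length(keys)),
    precursor_mz = as.numeric(rbind(pre$light, pre$heavy)),
    product_mz = as.numeric(rbind(prod$light, prod$heavy)),
    polarity = "positive",
    collision_energy = collision_energy,
    method_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Schedule transitions into acquisition methods
#'
#' Partitions the transition list into the smallest number of acquisition
#' methods such that no method exceeds `capacity` channels, the two
#' channels of one family always share a method (a split light/heavy pair
#' cannot be screened), and method loads are as even as possible: family
#' counts per method differ by at most one (channel counts by at most
#' two).  The default capacity of 54 channels (27 pairs) spreads the full
#' 1058-channel design over exactly 20 methods.
#'
#' @param transitions data frame from [build_transition_list()].
#' @param capacity maximum channels per method (>= 2).
#' @return the transition data frame with `method_index` filled in
#'   (0-based), carrying attribute `n_methods`.
#' @export
schedule_methods <- function(transitions, capacity = 54L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 2L) {
    stop("capacity must be at least 2 to co-locate a light/heavy pair")
  }
  n <- nrow(transitions)
  if (n == 0L) {
    attr(transitions, "n_methods") <- 0L
    return(transitions)
  }
  fams <- unique(transitions$compound)
  pairs_per_method <- capacity %/% 2L
  n_methods <- ceiling(length(fams) / pairs_per_method)
  # balanced contiguous split of the family sequence
  sizes <- rep(length(fams) %/% n_methods, n_methods)
  extra <- length(fams) %% n_methods
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  method_of <- rep(seq_len(n_methods) - 1L, times = sizes)
  names(method_of) <- fams
  transitions$method_index <- unname(method_of[transitions$compound])
  attr(transitions, "n_methods") <- as.integer(n_methods)
  transitions
}

#' Read / write an MRM transition list
#'
#' CSV with columns `compound`, `channel`, `precursor_mz`, `product_mz`,
#' `polarity`, `collision_energy`, `method_index`; one row per MRM event.
#' Write-then-read reproduces the table field-for-field.
#'
#' @param transitions transition data frame.
#' @param path CSV path.
#' @return `read_transition_list()` returns the data frame;
#'   `write_transition_list()` returns `path` invisibly.
#' @export
write_transition_list <- function(transitions, path) {
  utils::write.csv(transitions, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_transition_list
#' @export
read_transition_list <- function(path) {
  tl <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("compound", "channel", "precursor_mz", "product_mz",
              "polarity", "collision_energy", "method_index")
  missing <- setdiff(needed, names(tl))
  if (length(missing)) {
    stop("transition list ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  tl$method_index <- as.integer(tl$method_index)
  tl[needed]
}
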