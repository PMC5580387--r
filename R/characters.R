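# Trichotomous character states are stored as single-letter codes throughout
# the package and in the specimen-table schema:
#   "C" cervical, "X" transitional, "T" thoracic, "?" missing/unscorable.

#' Character state codes
#'
#' The four state codes used by the 12-character scoring scheme: `"C"`
#' (cervical), `"X"` (transitional), `"T"` (thoracic) and `"?"` (missing).
#' The three informative states are mutually exclusive; `"?"` never
#' contributes to any character count.
#'
#' @return Character vector of the four valid codes.
#' @export
ct_state_codes <- function() c("C", "X", "T", "?")

# Ordering used when collapsing per-side states: thoracic dominates.
# "?" maps to NA.
state_rank <- function(s) match(s, c("C", "X", "T"))

CHARACTER_IDS <- letters[1:12]

# Characters scored separately per side (paired structures and rib facets).
BILATERAL_IDS <- c("f", "h", "i", "j", "k", "l")

# Characters with a quantitative criterion (b only in juveniles).
QUANTITATIVE_IDS <- c("b", "d", "e", "f", "j")

#' The 12-character diagnostic scheme
#'
#' Dictionary of the twelve discrete osteological characters (ids `a`--`l`)
#' used to diagnose a vertebra as last cervical (C7), first thoracic (T1) or
#' transitional.  Each row gives the anatomical element, the view in which
#' the character is scored, the C7-state and T1-state criteria, and flags:
#' `quantitative` (a numeric ratio criterion exists), `bilateral` (scored
#' per side), `age_variant` (distinct adult and juvenile criteria; true only
#' for `b`, whose quantitative criterion applies to juveniles).
#'
#' The same table is shipped as a versioned delimited-text file under
#' `extdata/character_definitions.csv`.
#'
#' @return A data frame with 12 rows and columns `id`, `anatomical_element`,
#'   `view`, `c7_criterion`, `t1_criterion`, `quantitative`, `bilateral`,
#'   `age_variant`.
#' @export
#' @examples
#' defs <- character_definitions()
#' defs[defs$quantitative, "id"]
character_definitions <- function() {
  data.frame(
    id = CHARACTER_IDS,
    anatomical_element = c(
      "centrum", "centrum", "centrum", "centrum",
      "vertebral_foramen",
      "prezygapophysis", "prezygapophysis",
      "postzygapophysis", "postzygapophysis",
      "MPT_arch",
      "rib_facet", "rib_facet"
    ),
    view = c(
      "rostral", "caudal", "ventral", "ventral",
      "rostral",
      "rostral", "dorsal",
      "lateral", "caudal",
      "rostral",
      "lateral", "rostral"
    ),
    c7_criterion = c(
      "Anterior articular face oval, higher than wide, dorsal border convex",
      paste0(
        "Adult: dorsal width clearly exceeds ventral width, may have dimple ",
        "midway dorsally, ventrally convex. Juvenile: wider than high ",
        "(height at least 69% of width), ventrally rounded, shallow dorsal ",
        "dimple, indistinct trace of rib facets"
      ),
      "Ventral keel with single or bilateral median tubercle, strongly developed",
      "Anterior articular face deep and rounded, A-P length approx. 40-50% of centrum width",
      "Vertebral foramen wide (large), height/width ratio 75% or more",
      "Prezygapophyses widely spaced, shortest distance approx. 50% of total width at same level",
      "Prezygapophysis more anterior than transverse process",
      "Postzygapophyseal facet visible for greatest part in lateral view (latero-caudally directed)",
      "Postzygapophyseal facets widely spaced (inner side lateral of neural spine)",
      "MPT arch long, at least 85% of centrum height",
      "Rib facet at transverse process absent",
      "Rib facet at centrum absent"
    ),
    t1_criterion = c(
      "Anterior articular face heart-shaped, at least as wide as high, dorsal border approx. straight",
      paste0(
        "Adult: squarish, dorsal width approx. equals ventral width, ",
        "ventrally straight or tapering. Juvenile: wider than high (height ",
        "less than 64% of width), ventrally tapering, sharp dorsal dimple, ",
        "prominent impression of rib facets"
      ),
      "No ventral tubercles, keel at most very weakly developed",
      "Anterior articular face shallow and flat, A-P length approx. 25-35% of centrum width",
      "Vertebral foramen narrow (small), height/width ratio 73% or smaller",
      "Prezygapophyses narrowly spaced, shortest distance approx. 35% of total width at same level",
      "Prezygapophysis overhangs transverse process",
      "Postzygapophyseal facet at most minimally visible in lateral view (caudally directed)",
      "Postzygapophyseal facets narrowly spaced (inner side close to centre of neural spine)",
      "MPT arch short, at most 70% of centrum height",
      "Rib facet at transverse process present (large)",
      "Rib facet at centrum present (large)"
    ),
    quantitative = CHARACTER_IDS %in% QUANTITATIVE_IDS,
    bilateral = CHARACTER_IDS %in% BILATERAL_IDS,
    age_variant = CHARACTER_IDS == "b",
    stringsAsFactors = FALSE
  )
}

#' Raw-measurement container for the quantitative characters
#'
#' Holds the raw quantities from which the five quantitative character
#' states are derived.  All lengths must be strictly positive and share one
#' consistent unit (only ratios are ever used):
#' \describe{
#'   \item{e}{`foramen_height` / `foramen_width` (foramen H/W ratio).}
#'   \item{d}{`articular_AP_length` / `centrum_width`.}
#'   \item{f}{`prezyg_gap` / `total_width_at_level`.}
#'   \item{j}{`arch_length` / `centrum_height` (MPT arch vs centrum).}
#'   \item{b}{`posterior_height` / `posterior_width`, juveniles only.}
#' }
#'
#' @param foramen_height,foramen_width Vertebral foramen dimensions (e).
#' @param articular_AP_length,centrum_width Anterior articular face (d).
#' @param prezyg_gap,total_width_at_level Prezygapophyseal spacing (f).
#' @param arch_length,centrum_height MPT arch and centrum height (j).
#' @param posterior_height,posterior_width Posterior end of centrum (b).
#' @param age_class `"adult"`, `"juvenile"` or `"unknown"`; controls the
#'   age-dependent criterion of character `b`.
#' @return An object of class `measurement_set` (a named list).
#' @export
measurement_set <- function(foramen_height = NA_real_, foramen_width = NA_real_,
                            articular_AP_length = NA_real_, centrum_width = NA_real_,
                            prezyg_gap = NA_real_, total_width_at_level = NA_real_,
                            arch_length = NA_real_, centrum_height = NA_real_,
                            posterior_height = NA_real_, posterior_width = NA_real_,
                            age_class = c("adult", "juvenile", "unknown")) {
  age_class <- match.arg(age_class)
  m <- list(
    foramen_height = foramen_height, foramen_width = foramen_width,
    articular_AP_length = articular_AP_length, centrum_width = centrum_width,
    prezyg_gap = prezyg_gap, total_width_at_level = total_width_at_level,
    arch_length = arch_length, centrum_height = centrum_height,
    posterior_height = posterior_height, posterior_width = posterior_width,
    age_class = age_class
  )
  num <- unlist(m[names(m) != "age_class"])
  bad <- !is.na(num) & num <= 0
  if (any(bad)) {
    stop("invalid-measurement: non-positive value for ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  }
  structure(m, class = "measurement_set")
}

# (numerator, denominator) measurement fields per quantitative character.
.ratio_fields <- list(
  b = c("posterior_height", "posterior_width"),
  d = c("articular_AP_length", "centrum_width"),
  e = c("foramen_height", "foramen_width"),
  f = c("prezyg_gap", "total_width_at_level"),
  j = c("arch_length", "centrum_height")
)

# Threshold bands per quantitative character.  `hi` is the lower edge of the
# cervical band (ratio at or above -> "C"), `lo` the upper edge of the
# thoracic band; `lo_incl` says whether hitting `lo` exactly is thoracic.
# Ratios strictly inside the gap score "X" (transitional).  Characters d and
# f have disjoint printed bands whose beyond-band sides collapse onto these
# two thresholds.
.ratio_bands <- list(
  b = list(hi = 0.69, lo = 0.64, lo_incl = FALSE),  # juvenile criterion only
  d = list(hi = 0.40, lo = 0.35, lo_incl = TRUE),
  e = list(hi = 0.75, lo = 0.73, lo_incl = TRUE),
  f = list(hi = 0.50, lo = 0.35, lo_incl = TRUE),
  j = list(hi = 0.85, lo = 0.70, lo_incl = TRUE)
)

#' Derive a character state from raw measurements
#'
#' Maps the relevant measurement ratio of a quantitative character
#' (`b` juvenile, `d`, `e`, `f`, `j`) onto its trichotomous state.  A ratio
#' inside the printed C7 band (or beyond it, away from the T1 band) scores
#' `"C"`; inside or beyond the T1 band scores `"T"`; strictly between the
#' two bands scores `"X"` (transitional).  Missing inputs give `"?"`.
#'
#' Character `b` only has a quantitative criterion for juveniles; for
#' adults its state is a qualitative data-entry input.  With
#' `age_class = "unknown"` the adult criterion applies (with a warning),
#' which therefore also raises an unsupported-character error.
#'
#' @param char_id Single character id in `a`--`l`.
#' @param m A [measurement_set()].
#' @return One of `"C"`, `"X"`, `"T"`, `"?"`.
#' @export
#' @examples
#' state_from_measurement("e", measurement_set(foramen_height = 80, foramen_width = 100))
state_from_measurement <- function(char_id, m) {
  stopifnot(inherits(m, "measurement_set"))
  if (!char_id %in% CHARACTER_IDS) {
    stop("unsupported-character: unknown character id '", char_id, "'",
         call. = FALSE)
  }
  if (!char_id %in% QUANTITATIVE_IDS) {
    stop("unsupported-character: character '", char_id,
         "' has no quantitative criterion; its state is a data-entry input",
         call. = FALSE)
  }
  if (char_id == "b") {
    age <- m$age_class
    if (age == "unknown") {
      warning("age_class unknown for character 'b'; the adult criterion applies",
              call. = FALSE)
      age <- "adult"
    }
    if (age == "adult") {
      stop("unsupported-character: character 'b' is qualitative in adults; ",
           "the quantitative criterion applies to juveniles only",
           call. = FALSE)
    }
  }
  fields <- .ratio_fields[[char_id]]
  num <- m[[fields[1]]]
  den <- m[[fields[2]]]
  if (is.na(num) || is.na(den)) return("?")
  if (den <= 0) {
    stop("invalid-measurement: non-positive denominator ", fields[2],
         call. = FALSE)
  }
  ratio <- num / den
  band <- .ratio_bands[[char_id]]
  if (ratio >= band$hi) return("C")
  if (if (band$lo_incl) ratio <= band$lo else ratio < band$lo) return("T")
  "X"
}

#' Construct a character profile
#'
#' A character profile maps character ids (`a`--`l`) to state codes.  Each
#' entry is either a single code or, for bilateral characters, a named
#' length-2 vector `c(left = , right = )` of codes.  Characters absent from
#' the profile are treated as missing.
#'
#' @param ... Named entries, e.g. `a = "C"`, `k = c(left = "C", right = "X")`.
#' @param .states Alternatively, a named list of entries.
#' @return An object of class `character_profile`.
#' @export
#' @examples
#' character_profile(a = "C", k = c(left = "C", right = "T"))
character_profile <- function(..., .states = NULL) {
  p <- if (is.null(.states)) list(...) else .states
  if (length(p) && is.null(names(p))) stop("profile entries must be named")
  for (id in names(p)) {
    s <- p[[id]]
    if (!is.character(s) || !length(s) %in% 1:2 ||
        !all(s %in% ct_state_codes())) {
      stop("invalid state for character '", id, "': states must be codes ",
           paste(ct_state_codes(), collapse = "/"), call. = FALSE)
    }
    if (length(s) == 2 && !setequal(names(s), c("left", "right"))) {
      stop("per-side states for '", id,
           "' must be named 'left' and 'right'", call. = FALSE)
    }
  }
  structure(p, class = "character_profile")
}

#' Specimen-level state of one character
#'
#' Collapses a (possibly per-side) profile entry to the single state used in
#' character counts: for bilateral entries the more thoracic of the two
#' sides wins (`T` > `X` > `C`), since a one-sided rib facet still evidences
#' homeotic change.  Absent or all-missing entries give `"?"`.
#'
#' @param profile A [character_profile()].
#' @param char_id Character id.
#' @return One of `"C"`, `"X"`, `"T"`, `"?"`.
#' @export
profile_state <- function(profile, char_id) {
  s <- profile[[char_id]]
  if (is.null(s)) return("?")
  r <- state_rank(s)
  if (all(is.na(r))) return("?")
  c("C", "X", "T")[max(r, na.rm = TRUE)]
}

#' Validate a character profile
#'
#' Non-throwing structural checks: unknown character ids, per-side entries
#' on non-bilateral characters, invalid state codes, and profiles with no
#' informative character at all.  The input is never modified.
#'
#' @param p A profile (a `character_profile` or a bare named list).
#' @return Character vector of human-readable findings; empty when clean.
#' @export
validate_profile <- function(p) {
  findings <- character(0)
  ids <- names(p)
  if (length(p) && is.null(ids)) {
    return("profile entries are unnamed; expected character ids a-l")
  }
  unknown <- setdiff(ids, CHARACTER_IDS)
  for (id in unknown) {
    findings <- c(findings, paste0("unknown character id '", id, "'"))
  }
  for (id in intersect(ids, CHARACTER_IDS)) {
    s <- p[[id]]
    if (!is.character(s) || !all(s %in% ct_state_codes())) {
      findings <- c(findings, paste0("invalid state code for character '", id, "'"))
      next
    }
    if (length(s) > 1 && !id %in% BILATERAL_IDS) {
      findings <- c(findings, paste0(
        "per-side duplicate states for non-bilateral character '", id, "'"))
    }
  }
  informative <- vapply(intersect(ids, CHARACTER_IDS),
                        function(id) profile_state(p, id) != "?", logical(1))
  if (!any(informative)) {
    findings <- c(findings, "no informative characters")
  }
  findings
}
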