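# Vertebral identity assignment: rib-facet presence plus the >= 6
# cervical-or-transitional majority rule, with honest abstention
# (INDETERMINATE) when missing data make the threshold undecidable.

#' Construct a vertebra record
#'
#' One museum specimen: identity metadata plus its character profile and,
#' optionally, raw measurements and per-side rib-facet annotations.
#'
#' @param specimen_id Non-empty specimen identifier (e.g. museum number).
#' @param taxon Taxon name (free text).
#' @param age_class `"adult"`, `"juvenile"` or `"unknown"`.
#' @param locality Locality string, stored verbatim.
#' @param profile A [character_profile()] (keys within `a`--`l`).
#' @param measurements Optional [measurement_set()].
#' @param side_notes Optional list with elements `facet_left` / `facet_right`
#'   (size class, one of `"none"`, `"small"`, `"large"`) and/or
#'   `position_note` (free text) and `position_asymmetry` (logical).
#' @param provenance Optional free-text provenance label (e.g. the identity
#'   printed in a source inventory); never used by the classifier.
#' @return An object of class `vertebra_record`.
#' @export
vertebra_record <- function(specimen_id, taxon = "", age_class = "unknown",
                            locality = "", profile = character_profile(),
                            measurements = NULL, side_notes = NULL,
                            provenance = NULL) {
  if (!is.character(specimen_id) || length(specimen_id) != 1 ||
      is.na(specimen_id) || !nzchar(specimen_id)) {
    stop("specimen_id must be a non-empty string", call. = FALSE)
  }
  if (!age_class %in% c("adult", "juvenile", "unknown")) {
    stop("age_class must be adult/juvenile/unknown", call. = FALSE)
  }
  if (!inherits(profile, "character_profile")) {
    profile <- character_profile(.states = as.list(profile))
  }
  bad <- setdiff(names(profile), CHARACTER_IDS)
  if (length(bad)) {
    stop("profile keys outside a-l: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    specimen_id = specimen_id, taxon = taxon, age_class = age_class,
    locality = locality, profile = profile, measurements = measurements,
    side_notes = side_notes, provenance = provenance
  ), class = "vertebra_record")
}

#' Rib-facet presence
#'
#' A vertebra bears rib articulation facets when either facet character
#' (`k`, at the transverse process; `l`, at the centrum) is transitional or
#' thoracic on any side.  Both characters cervical (facets absent on all
#' preserved facet sites) gives `FALSE`; both entirely missing gives `NA`
#' (indeterminate, consumed by [classify()]).
#'
#' @param profile A [character_profile()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
rib_facets_present <- function(profile) {
  sk <- profile_state(profile, "k")
  sl <- profile_state(profile, "l")
  if (sk %in% c("X", "T") || sl %in% c("X", "T")) return(TRUE)
  if (sk == "?" && sl == "?") return(NA)
  FALSE
}

#' Classify a vertebra as C7, transitional C/T, T1 or indeterminate
#'
#' Applies the diagnostic rule: a vertebra without rib facets is a normal
#' last cervical (C7).  A facet-bearing vertebra with six or more of its 12
#' characters in a cervical or transitional state — i.e. at least 50%
#' cervical in morphology — is a transitional cervico-thoracic (C/T)
#' vertebra; with fewer it is a regular first thoracic (T1).  The threshold
#' is absolute (6 of 12): when missing characters leave it undecidable
#' (observed cervical+transitional below 6 but reachable if every missing
#' character were cervical), or when facet status itself is indeterminate,
#' the call is `INDETERMINATE`.
#'
#' @param v A [vertebra_record()].
#' @return An object of class `identity_call`: list with `identity`
#'   (`"C7"`, `"CT"`, `"T1"` or `"INDETERMINATE"`), the four state counts
#'   (summing to 12), `rib_facets_present` and `asymmetric`.
#' @export
#' @examples
#' v <- vertebra_record("demo", profile = character_profile(
#'   .states = stats::setNames(as.list(rep("C", 12)), letters[1:12])))
#' classify(v)$identity
classify <- function(v) {
  stopifnot(inherits(v, "vertebra_record"))
  p <- v$profile
  if (!inherits(p, "character_profile")) {
    # unvalidated bare profile: run the full structural check
    findings <- setdiff(validate_profile(p), "no informative characters")
    if (length(findings)) {
      stop("invalid profile for ", v$specimen_id, ": ",
           paste(findings, collapse = "; "), call. = FALSE)
    }
  }
  # collapse per-side entries to the more thoracic side, one pass
  ord <- c(C = 1L, X = 2L, T = 3L)
  states <- stats::setNames(rep("?", 12L), CHARACTER_IDS)
  for (id in names(p)) {
    s <- p[[id]]
    if (length(s) == 2L) {
      if (!id %in% BILATERAL_IDS) {
        stop("invalid profile for ", v$specimen_id,
             ": per-side duplicate states for non-bilateral character '",
             id, "'", call. = FALSE)
      }
      s <- s[s != "?"]
      if (!length(s)) next
      states[[id]] <- c("C", "X", "T")[max(ord[s])]
    } else if (s != "?") {
      states[[id]] <- s
    }
  }
  n_c <- sum(states == "C")
  n_x <- sum(states == "X")
  n_t <- sum(states == "T")
  n_m <- sum(states == "?")
  sk <- states[["k"]]; sl <- states[["l"]]
  facets <- if (sk %in% c("X", "T") || sl %in% c("X", "T")) TRUE
            else if (sk == "?" && sl == "?") NA
            else FALSE
  identity <- if (is.na(facets)) {
    "INDETERMINATE"
  } else if (!facets) {
    "C7"
  } else if (n_c + n_x >= 6) {
    "CT"
  } else if (n_c + n_x + n_m < 6) {
    "T1"
  } else {
    "INDETERMINATE"
  }
  structure(list(
    specimen_id = v$specimen_id, identity = identity,
    n_cervical = n_c, n_transitional = n_x, n_thoracic = n_t, n_missing = n_m,
    rib_facets_present = facets, asymmetric = asymmetry_flag(v)
  ), class = "identity_call")
}

#' Left-right asymmetry flag
#'
#' Transitional vertebrae often show left-right asymmetry in the extent of
#' the homeotic transformation (e.g. unequal rib facets).  The flag is
#' `TRUE` when any bilateral character carries differing informative
#' left/right states, when the recorded facet size classes differ between
#' sides, or when an explicit position asymmetry is annotated; `FALSE`
#' otherwise, including (with no signal available) records that carry no
#' per-side information at all.
#'
#' @param v A [vertebra_record()].
#' @return Logical flag.
#' @export
asymmetry_flag <- function(v) {
  stopifnot(inherits(v, "vertebra_record"))
  for (id in names(v$profile)[names(v$profile) %in% BILATERAL_IDS]) {
    s <- v$profile[[id]]
    if (length(s) == 2 && all(s != "?") && s[["left"]] != s[["right"]]) {
      return(TRUE)
    }
  }
  sn <- v$side_notes
  if (!is.null(sn)) {
    fl <- sn$facet_left
    fr <- sn$facet_right
    if (!is.null(fl) && !is.null(fr) && !is.na(fl) && !is.na(fr) &&
        fl != fr) {
      return(TRUE)
    }
    if (isTRUE(sn$position_asymmetry)) return(TRUE)
  }
  FALSE
}

#' Classify a set of vertebra records
#'
#' Deterministic, order-preserving classification of a dataset; one call per
#' record.  The result carries a per-identity summary as attribute
#' `"summary"`.
#'
#' @param records List of [vertebra_record()] objects with unique ids.
#' @return A data frame of class `identity_table` with columns
#'   `specimen_id`, `identity`, `n_cervical`, `n_transitional`,
#'   `n_thoracic`, `n_missing`, `rib_facets_present`, `asymmetric`.
#' @export
classify_dataset <- function(records) {
  ids <- vapply(records, function(r) r$specimen_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  calls <- lapply(records, classify)
  tab <- data.frame(
    specimen_id = ids,
    identity = vapply(calls, `[[`, character(1), "identity"),
    n_cervical = vapply(calls, `[[`, integer(1), "n_cervical"),
    n_transitional = vapply(calls, `[[`, integer(1), "n_transitional"),
    n_thoracic = vapply(calls, `[[`, integer(1), "n_thoracic"),
    n_missing = vapply(calls, `[[`, integer(1), "n_missing"),
    rib_facets_present = vapply(calls, `[[`, logical(1), "rib_facets_present"),
    asymmetric = vapply(calls, `[[`, logical(1), "asymmetric"),
    stringsAsFactors = FALSE
  )
  if (!nrow(tab)) {
    tab <- tab[0, , drop = FALSE]
  }
  summary <- table(factor(tab$identity,
                          levels = c("C7", "CT", "T1", "INDETERMINATE")))
  attr(tab, "summary") <- summary
  class(tab) <- c("identity_table", "data.frame")
  tab
}

#' @export
print.identity_table <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nIdentity summary:",
        paste(names(s), as.integer(s), sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' @export
print.identity_call <- function(x, ...) {
  cat(x$specimen_id, "->", x$identity,
      sprintf("(C=%d X=%d T=%d ?=%d; facets=%s; asymmetric=%s)\n",
              x$n_cervical, x$n_transitional, x$n_thoracic, x$n_missing,
              format(x$rib_facets_present), format(x$asymmetric)))
  invisible(x)
}
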