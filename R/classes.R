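## Domain types: enzyme profiles, modification states, rate parameters,
## model structures.  All are validated named numeric vectors (or, for
## structures, lists of TET subsets) so they can flow straight into the
## linear algebra without conversion.

check_levels <- function(x, what) {
  bad <- !is.finite(x)
  if (any(bad))
    stop(sprintf("%s: non-finite value for %s", what,
                 paste(names(x)[bad], collapse = ", ")), call. = FALSE)
  neg <- x < 0
  if (any(neg))
    stop(sprintf("%s: negative value for %s", what,
                 paste(names(x)[neg], collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Construct an enzyme profile for one cell line
#'
#' Relative transcript levels of the seven enzymes that drive the model
#' fluxes.  Levels are non-negative reals on a scale that is consistent
#' across cell lines; transcript abundance is used as a proxy for enzyme
#' activity.
#'
#' @param DNMT1,TET1,TET2,TET3,AID,SMUG1,TDG Non-negative relative levels.
#' @param cell_line Optional cell-line label.
#' @return A named numeric vector of class `"enzyme_profile"` in the
#'   canonical order `DNMT1, TET1, TET2, TET3, AID, SMUG1, TDG`.
#' @examples
#' enzyme_profile(DNMT1 = 0.092, TET1 = 0.065, TET2 = 0.614, TET3 = 0.0048,
#'                AID = 0.0098, SMUG1 = 1.196, TDG = 0.295,
#'                cell_line = "RAJI")
#' @export
enzyme_profile <- function(DNMT1, TET1, TET2, TET3, AID, SMUG1, TDG,
                           cell_line = NA_character_) {
  x <- c(DNMT1 = DNMT1, TET1 = TET1, TET2 = TET2, TET3 = TET3,
         AID = AID, SMUG1 = SMUG1, TDG = TDG)
  check_levels(x, "enzyme_profile")
  structure(x, cell_line = cell_line, class = "enzyme_profile")
}

as_enzyme_profile <- function(x, cell_line = NA_character_) {
  if (inherits(x, "enzyme_profile")) return(x)
  x <- unlist(x)
  missing <- setdiff(ENZYME_NAMES, names(x))
  if (length(missing))
    stop("enzyme profile is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[ENZYME_NAMES]
  check_levels(x, "enzyme_profile")
  structure(x, cell_line = cell_line, class = "enzyme_profile")
}

#' Construct a modification state
#'
#' The six state variables of the model: relative steady-state (or
#' instantaneous) levels of 5-mdC, 5-hmdC, 5-fdC, 5-cadC, 5-hmdU and dU,
#' on a common abundance scale.
#'
#' @param mdC,hmdC,fdC,cadC,hmdU,U Non-negative levels.
#' @return A named numeric vector of class `"modification_state"` in the
#'   canonical state order `mdC, hmdC, fdC, cadC, hmdU, U`.
#' @export
modification_state <- function(mdC = 0, hmdC = 0, fdC = 0, cadC = 0,
                               hmdU = 0, U = 0) {
  x <- c(mdC = mdC, hmdC = hmdC, fdC = fdC, cadC = cadC, hmdU = hmdU, U = U)
  check_levels(x, "modification_state")
  structure(x, class = "modification_state")
}

as_modification_state <- function(x, allow_na = FALSE) {
  if (inherits(x, "modification_state") && !anyNA(x)) return(x)
  x <- unlist(x)
  missing <- setdiff(STATE_NAMES, names(x))
  if (length(missing))
    stop("modification state is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- x[STATE_NAMES]
  if (allow_na) check_levels(x[!is.na(x)], "modification_state")
  else check_levels(x, "modification_state")
  structure(x, class = "modification_state")
}

#' Construct the model's rate parameters
#'
#' Proportionality coefficients (enzyme-substrate affinities) of the mass
#' action fluxes.  Coefficients coupled to an enzyme have units
#' 1/(enzyme-level x time); `k4` and `k5` (first-order removal of 5-fdC
#' and 5-cadC through base-excision repair) have units 1/time.  All
#' coefficients are non-negative; coefficients of TETs excluded by the
#' active model structure must be zero, which [compute_fluxes()] enforces
#' by masking.
#'
#' AID acts on two substrates (5-hmdC deamination and deamination of the
#' unmodified cytidine pool); the two affinities are kept as separate
#' fields `kAID_hmdC` and `kAID_C`, which estimation ties to a single
#' shared `kAID` by default (see [assemble_design()]).
#'
#' @param kDNMT1 Methylation influx coefficient.  The fitting convention
#'   fixes `kDNMT1 = 1` so that all other coefficients are expressed in
#'   units of the methylation influx.
#' @param k1TET1,k1TET2,k1TET3 5-mdC -> 5-hmdC oxidation coefficients.
#' @param k2TET1,k2TET2,k2TET3 5-hmdC -> 5-fdC oxidation coefficients.
#' @param k3TET1,k3TET2,k3TET3 5-fdC -> 5-cadC oxidation coefficients.
#' @param k4 5-fdC removal (TDG/BER) coefficient, 1/time.
#' @param k5 5-cadC removal (TDG/BER) coefficient, 1/time.
#' @param kAID_hmdC AID affinity for 5-hmdC (flux f7).
#' @param kAID_C AID affinity for unmodified cytidine (flux f10).
#' @param kSMUG SMUG1 affinity for 5-hmdU (flux f8).
#' @param kTDG TDG affinity for uracil (flux f9).
#' @return Named numeric vector of class `"rate_parameters"`.
#' @export
rate_parameters <- function(kDNMT1 = 1,
                            k1TET1 = 0, k1TET2 = 0, k1TET3 = 0,
                            k2TET1 = 0, k2TET2 = 0, k2TET3 = 0,
                            k3TET1 = 0, k3TET2 = 0, k3TET3 = 0,
                            k4 = 0, k5 = 0,
                            kAID_hmdC = 0, kAID_C = 0,
                            kSMUG = 0, kTDG = 0) {
  x <- c(kDNMT1 = kDNMT1,
         k1TET1 = k1TET1, k1TET2 = k1TET2, k1TET3 = k1TET3,
         k2TET1 = k2TET1, k2TET2 = k2TET2, k2TET3 = k2TET3,
         k3TET1 = k3TET1, k3TET2 = k3TET2, k3TET3 = k3TET3,
         k4 = k4, k5 = k5, kAID_hmdC = kAID_hmdC, kAID_C = kAID_C,
         kSMUG = kSMUG, kTDG = kTDG)
  check_levels(x, "rate_parameters")
  structure(x, class = "rate_parameters")
}

as_rate_parameters <- function(x) {
  if (inherits(x, "rate_parameters")) return(x)
  x <- unlist(x)
  missing <- setdiff(PARAM_NAMES, names(x))
  if (length(missing))
    stop("rate parameters missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  do.call(rate_parameters, as.list(x[PARAM_NAMES]))
}

#' Construct a model structure (TET assignment)
#'
#' A model structure assigns to each of the three oxidation reactions the
#' non-empty subset of TET enzymes assumed to catalyse it:
#' `s1` for 5-mdC -> 5-hmdC, `s2` for 5-hmdC -> 5-fdC, and `s3` for
#' 5-fdC -> 5-cadC.  With 7 non-empty subsets per reaction there are
#' `7^3 = 343` structures in total.
#'
#' @param s1,s2,s3 Character vectors, each a non-empty subset of
#'   `c("TET1", "TET2", "TET3")`.
#' @return An object of class `"model_structure"`.
#' @examples
#' full_structure()
#' model_structure(c("TET1", "TET2"), c("TET1", "TET3"), c("TET2", "TET3"))
#' @export
model_structure <- function(s1, s2, s3) {
  sets <- list(s1 = s1, s2 = s2, s3 = s3)
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    bad <- setdiff(s, TET_NAMES)
    if (length(bad))
      stop("unknown TET name: ", paste(bad, collapse = ", "), call. = FALSE)
    if (!length(s))
      stop("each oxidation reaction needs a non-empty TET subset",
           call. = FALSE)
    TET_NAMES[TET_NAMES %in% s]
  })
  structure(sets, class = "model_structure")
}

#' @rdname model_structure
#' @export
full_structure <- function() model_structure(TET_NAMES, TET_NAMES, TET_NAMES)

## 3 x 3 logical matrix: rows = reactions 1..3, cols = TET1..TET3.
structure_activity <- function(structure) {
  stopifnot(inherits(structure, "model_structure"))
  t(vapply(structure, function(s) TET_NAMES %in% s, logical(3)))
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cl <- attr(x, "cell_line")
  cat("Enzyme profile", if (!is.na(cl)) paste0("[", cl, "]"), "\n")
  print(unclass(`attributes<-`(x, list(names = names(x)))))
  invisible(x)
}

#' @export
print.modification_state <- function(x, ...) {
  cat("Modification state\n")
  print(unclass(`attributes<-`(x, list(names = names(x)))))
  invisible(x)
}

#' @export
print.model_structure <- function(x, ...) {
  cat("TET assignment:", describe_structure(x),
      sprintf("(code %d)\n", encode_structure(x)))
  invisible(x)
}
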