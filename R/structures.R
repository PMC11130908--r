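## Enumeration and encoding of the 343 candidate TET assignments.
##
## Each reaction's subset is a bitmask in 1..7 with TET1 as the least
## significant bit; a whole structure is encoded lexicographically as
## (mask1 - 1) * 49 + (mask2 - 1) * 7 + (mask3 - 1), an integer in 0..342.
## The full structure (all TETs everywhere) has masks (7, 7, 7) and is
## therefore the last element, code 342.

mask_to_tets <- function(mask) {
  if (!is.numeric(mask) || mask != as.integer(mask) || mask < 1 || mask > 7)
    stop("reaction bitmask must be an integer in 1..7", call. = FALSE)
  TET_NAMES[bitwAnd(as.integer(mask), c(1L, 2L, 4L)) != 0L]
}

tets_to_mask <- function(tets) {
  sum(c(1L, 2L, 4L)[TET_NAMES %in% tets])
}

#' Enumerate all 343 candidate model structures
#'
#' Generates every assignment of a non-empty subset of
#' \{TET1, TET2, TET3\} to each of the three oxidation reactions:
#' 7 options per reaction, hence `7^3 = 343` structures.  The order is
#' lexicographic ascending over the three subset bitmasks (TET1 = least
#' significant bit), so the full structure is the last element (code 342).
#'
#' @return A list of 343 [model_structure()] objects; element `i` has
#'   structure code `i - 1` (see [encode_structure()]).
#' @examples
#' length(enumerate_structures())
#' @export
enumerate_structures <- function() {
  grid <- expand.grid(m3 = 1:7, m2 = 1:7, m1 = 1:7)   # m1 varies slowest
  lapply(seq_len(nrow(grid)), function(i)
    model_structure(mask_to_tets(grid$m1[i]),
                    mask_to_tets(grid$m2[i]),
                    mask_to_tets(grid$m3[i])))
}

#' Encode / decode a model structure as an integer code
#'
#' Structures are in bijection with integers 0..342 via the three subset
#' bitmasks: `code = (mask1 - 1) * 49 + (mask2 - 1) * 7 + (mask3 - 1)`.
#'
#' @param structure A [model_structure()].
#' @return `encode_structure()`: an integer in 0..342.
#' @examples
#' encode_structure(full_structure())  # 342
#' decode_structure(0)                 # TET1 alone in every reaction
#' @export
encode_structure <- function(structure) {
  stopifnot(inherits(structure, "model_structure"))
  m <- vapply(structure, tets_to_mask, integer(1))
  as.integer((m[1] - 1L) * 49L + (m[2] - 1L) * 7L + (m[3] - 1L))
}

#' @rdname encode_structure
#' @param code Integer structure code in 0..342.
#' @export
decode_structure <- function(code) {
  if (!is.numeric(code) || code != as.integer(code) || code < 0 || code > 342)
    stop("structure code must be an integer in 0..342", call. = FALSE)
  code <- as.integer(code)
  m1 <- code %/% 49L
  m2 <- (code %% 49L) %/% 7L
  m3 <- code %% 7L
  model_structure(mask_to_tets(m1 + 1L), mask_to_tets(m2 + 1L),
                  mask_to_tets(m3 + 1L))
}

#' Render a structure as a dot pattern
#'
#' Produces the fixed-width nine-column dot pattern conventionally used to
#' display TET assignments (reaction-major, TET1..TET3 within each
#' reaction): a bullet marks an active TET, an underscore an inactive one.
#'
#' @param structure A [model_structure()].
#' @param dot,blank Symbols for active/inactive entries.
#' @return A single string, e.g. `"• • _ | • _ • | _ • •"`.
#' @export
describe_structure <- function(structure, dot = "•", blank = "_") {
  act <- structure_activity(structure)
  paste(apply(act, 1, function(r) paste(ifelse(r, dot, blank), collapse = " ")),
        collapse = " | ")
}

## Nine-element character vector of dot-pattern cells, for tabular output.
dot_pattern_cells <- function(structure, dot = "•", blank = "") {
  act <- as.vector(t(structure_activity(structure)))
  ifelse(act, dot, blank)
}

dot_pattern_colnames <- function() {
  reactions <- c("mdC.hmdC", "hmdC.fdC", "fdC.cadC")
  as.vector(t(outer(reactions, TET_NAMES, paste, sep = ".")))
}
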