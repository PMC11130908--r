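## Cell-line dataset container and tabular I/O.
##
## Canonical table dialect: UTF-8, tab-separated, header row, cell lines
## as rows.  The transposed layout (species as rows, cell lines as
## columns, as transcript-level tables are often printed) is auto-detected
## on read.  The missing-value token "NA" is allowed only in modification
## tables, marking unobserved state variables.

## Accepted aliases for the state columns.
STATE_ALIASES <- c("mdC" = "mdC", "5-mdC" = "mdC", "5mdC" = "mdC",
                   "hmdC" = "hmdC", "5-hmdC" = "hmdC", "5hmdC" = "hmdC",
                   "fdC" = "fdC", "5-fdC" = "fdC", "5fdC" = "fdC",
                   "cadC" = "cadC", "5-cadC" = "cadC", "5cadC" = "cadC",
                   "hmdU" = "hmdU", "5-hmdU" = "hmdU", "5hmdU" = "hmdU",
                   "U" = "U", "dU" = "U")
ENZYME_ALIASES <- c("DNMT1" = "DNMT1", "TET1" = "TET1", "TET2" = "TET2",
                    "TET3" = "TET3", "AID" = "AID", "SMUG1" = "SMUG1",
                    "SMUG" = "SMUG1", "TDG" = "TDG")

#' Assemble a cell-line dataset
#'
#' Couples, per cell line, an enzyme transcript profile with observed
#' steady-state modification levels.  At least two lines are required for
#' cross-validation.
#'
#' @param enzymes Data frame (rows = cell lines, row names = IDs) with the
#'   seven enzyme columns `DNMT1, TET1, TET2, TET3, AID, SMUG1, TDG`.
#' @param states Data frame with the same rows and up to six state columns
#'   `mdC, hmdC, fdC, cadC, hmdU, U`; `NA` marks an unobserved value.
#' @param observed Optional logical vector over the six states naming
#'   which are observed; defaults to the states present without `NA`s.
#' @return An object of class `"cell_line_dataset"`: a list with elements
#'   `enzymes`, `states` (both data frames in canonical column order),
#'   `observed` (named logical of length 6) and `cell_lines`.
#' @export
cell_line_dataset <- function(enzymes, states, observed = NULL) {
  enzymes <- as.data.frame(enzymes)
  states <- as.data.frame(states)
  missing_e <- setdiff(ENZYME_NAMES, names(enzymes))
  if (length(missing_e))
    stop("enzyme table is missing columns: ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  if (nrow(enzymes) < 2)
    stop("at least 2 cell lines are required", call. = FALSE)
  default_rn <- function(df)
    is.null(rownames(df)) ||
      identical(rownames(df), as.character(seq_len(nrow(df))))
  if (default_rn(enzymes)) {
    rownames(enzymes) <- sprintf("line%02d", seq_len(nrow(enzymes)))
    if (default_rn(states) && nrow(states) == nrow(enzymes))
      rownames(states) <- rownames(enzymes)
  }
  ids <- rownames(enzymes)
  if (!setequal(rownames(states), ids))
    stop("cell-line IDs of enzyme and modification tables do not match: ",
         paste(symdiff_ids(rownames(states), ids), collapse = ", "),
         call. = FALSE)
  states <- states[ids, , drop = FALSE]
  for (s in setdiff(STATE_NAMES, names(states))) states[[s]] <- NA_real_
  enzymes <- enzymes[, ENZYME_NAMES]
  states <- states[, STATE_NAMES]
  for (j in names(enzymes)) {
    bad <- which(!is.finite(enzymes[[j]]) | enzymes[[j]] < 0)
    if (length(bad))
      stop(sprintf("enzyme table: invalid (negative or missing) %s for %s",
                   j, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  for (j in names(states)) {
    bad <- which(!is.na(states[[j]]) & (!is.finite(states[[j]]) | states[[j]] < 0))
    if (length(bad))
      stop(sprintf("modification table: negative or non-finite %s for %s",
                   j, paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  if (is.null(observed)) observed <- !vapply(states, anyNA, logical(1))
  observed <- as.logical(observed)
  if (length(observed) != 6) stop("observed mask must have length 6")
  names(observed) <- STATE_NAMES
  out <- list(enzymes = enzymes, states = states, observed = observed,
              cell_lines = ids)
  class(out) <- "cell_line_dataset"
  out
}

symdiff_ids <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @export
print.cell_line_dataset <- function(x, ...) {
  cat(sprintf("Cell-line dataset: %d lines (%s); observed states: %s\n",
              length(x$cell_lines), paste(x$cell_lines, collapse = ", "),
              paste(STATE_NAMES[x$observed], collapse = ", ")))
  invisible(x)
}

enzyme_profile_of <- function(dataset, line) {
  as_enzyme_profile(dataset$enzymes[line, ], cell_line = line)
}

observed_state_of <- function(dataset, line) {
  as_modification_state(dataset$states[line, ], allow_na = TRUE)
}

## Read one delimited table, auto-detecting orientation: if the first
## column holds species names, the table is transposed so that cell lines
## end up as rows.
read_species_table <- function(path, aliases, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  rn_hit <- mean(rownames(tab) %in% names(aliases))
  cn_hit <- mean(colnames(tab) %in% names(aliases))
  if (rn_hit > cn_hit) tab <- as.data.frame(t(as.matrix(tab)))
  known <- colnames(tab) %in% names(aliases)
  if (!any(known))
    stop(sprintf("%s table %s: no recognised columns (found: %s)",
                 kind, path, paste(colnames(tab), collapse = ", ")),
         call. = FALSE)
  if (any(!known))
    stop(sprintf("%s table %s: unknown column(s): %s", kind, path,
                 paste(colnames(tab)[!known], collapse = ", ")), call. = FALSE)
  colnames(tab) <- aliases[colnames(tab)]
  for (j in colnames(tab)) tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Read an enzyme transcript-level table
#'
#' @param path Path to a TSV/CSV table with the seven enzymes either as
#'   columns (cell lines as rows) or as rows (cell lines as columns; the
#'   printed transcript-table layout), auto-detected.
#' @return Data frame, rows = cell lines, canonical enzyme columns.
#' @export
read_enzyme_table <- function(path) {
  tab <- read_species_table(path, ENZYME_ALIASES, "enzyme")
  missing <- setdiff(ENZYME_NAMES, names(tab))
  if (length(missing))
    stop("enzyme table ", path, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab[, ENZYME_NAMES]
}

#' Read a paired enzyme + modification dataset
#'
#' Reads the two delimited tables, validates them (non-negative finite
#' levels, matching cell-line IDs) and records which state variables are
#' observed (columns present and free of `NA`).
#'
#' @param enzyme_path,modification_path Paths to the two tables
#'   (TSV canonical, CSV accepted; either orientation).
#' @return A [cell_line_dataset()].
#' @export
read_dataset <- function(enzyme_path, modification_path) {
  enzymes <- read_enzyme_table(enzyme_path)
  states <- read_species_table(modification_path, STATE_ALIASES,
                               "modification")
  cell_line_dataset(enzymes, states)
}

#' Write a dataset as the canonical pair of TSV tables
#'
#' @param dataset A [cell_line_dataset()].
#' @param enzyme_path,modification_path Output paths (tab-separated,
#'   cell lines as rows, header row; unobserved states written as `NA`).
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, enzyme_path, modification_path) {
  stopifnot(inherits(dataset, "cell_line_dataset"))
  write_tsv_rownames(dataset$enzymes, enzyme_path, "cell_line")
  st <- dataset$states
  st[, !dataset$observed] <- NA_real_
  write_tsv_rownames(st, modification_path, "cell_line")
  invisible(c(enzyme_path, modification_path))
}

write_tsv_rownames <- function(df, path, id_col, comments = character()) {
  out <- data.frame(rownames(df), df, check.names = FALSE)
  names(out)[1] <- id_col
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to the packaged transcript-level fixture
#'
#' Location of the packaged table of relative transcript levels of AID,
#' SMUG1, TDG, DNMT1 and the three TETs in five human cell lines (Raji,
#' K562, HCT116, NHDF, Me45), in the printed species-as-rows layout.
#'
#' @return File path of the TSV fixture.
#' @examples
#' head(read_enzyme_table(transcript_levels_path()))
#' @export
transcript_levels_path <- function() {
  system.file("extdata", "transcript_levels.tsv", package = "tetflux",
              mustWork = TRUE)
}

#' Write a ranked structure table and companion prediction table
#'
#' Writes the structure-selection results in the conventional layout: one
#' row per structure with its cross-validation index and the nine
#' dot-pattern columns (three oxidation reactions x TET1..TET3), keeping
#' the `top_k` best structures plus the full structure and the worst
#' structure.  Optionally writes a per-cell-line predicted-vs-observed
#' table comparing, per state variable, the measurement with the
#' cross-validated predictions of the best and of the full structure.
#'
#' @param ranking A `"structure_ranking"` from [rank_structures()].
#' @param path Output TSV path for the ranked table.
#' @param top_k How many best structures to keep (1..343).
#' @param predictions_path Optional output TSV path for the
#'   predicted-vs-observed table.
#' @param dot,blank Symbols used in the pattern columns.
#' @return Invisibly, the ranked-table data frame that was written.
#' @export
write_ranked_results <- function(ranking, path, top_k = 10,
                                 predictions_path = NULL,
                                 dot = "•", blank = "") {
  stopifnot(inherits(ranking, "structure_ranking"))
  if (top_k < 1 || top_k > length(ranking$scores))
    stop("top_k must be in 1..", length(ranking$scores))
  scores <- ranking$scores
  codes <- vapply(scores, `[[`, integer(1), "code")
  full_pos <- which(codes == 342L)
  keep <- c(seq_len(top_k), full_pos, length(scores))
  role <- c(rep("top", top_k), "full", "worst")
  rows <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    sc <- scores[[i]]
    cells <- dot_pattern_cells(sc$structure, dot = dot, blank = blank)
    cbind(data.frame(role = role[j], rank = i, performance_index = sc$J_cv,
                     code = sc$code, stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(cells, dot_pattern_colnames())),
                        check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  comments <- c(sprintf("tetflux %s structure ranking",
                        as.character(utils::packageVersion("tetflux"))),
                "scale convention: kDNMT1 = 1, C = 1",
                sprintf("seed: %s", ranking$seed %||% "NA"),
                sprintf("cell lines: %s",
                        paste(ranking$cell_lines, collapse = ", ")))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(paste0("# ", comments), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(predictions_path)) {
    best <- scores[[1]]; full <- scores[[full_pos]]
    obs <- best$observations
    pv <- do.call(rbind, lapply(rownames(obs), function(line) {
      data.frame(cell_line = line, state = colnames(obs),
                 observed = as.numeric(obs[line, ]),
                 best_prediction = as.numeric(best$predictions[line, ]),
                 full_prediction = as.numeric(full$predictions[line, ]),
                 stringsAsFactors = FALSE)
    }))
    con <- file(predictions_path, "w", encoding = "UTF-8")
    writeLines(paste0("# ", comments[1:3]), con)
    utils::write.table(pv, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
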