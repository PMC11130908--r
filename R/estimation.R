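## Estimation: steady-state flux balances -> linear-in-parameters design,
## non-negative least squares fit, hold-out prediction.
##
## Scale convention.  The balance system is homogeneous in the rate
## coefficients (doubling all k's leaves every balance satisfied), so an
## unconstrained fit would return the zero vector.  The scale is fixed by
## the convention kDNMT1 = 1 and C = 1: the methylation influx
## C * DNMT1_m becomes a known right-hand side of the f1 = f2 row, and all
## other coefficients are expressed in units of that influx.

## Balance rows, their flux identities, the states each row needs, and
## the (candidate) free-parameter columns each touches.
BALANCE_ROWS <- list(
  r1 = list(label = "f1=f2",    needs = "mdC"),
  r2 = list(label = "f2=f3+f7", needs = c("mdC", "hmdC")),
  r3 = list(label = "f3=f4+f5", needs = c("hmdC", "fdC")),
  r4 = list(label = "f4=f6",    needs = c("fdC", "cadC")),
  r5 = list(label = "f7=f8",    needs = c("hmdC", "hmdU")),
  r6 = list(label = "f9=f10",   needs = "U"))

free_parameter_columns <- function(structure, tie_aid = TRUE) {
  act <- structure_activity(structure)
  cols <- c(paste0("k1", TET_NAMES[act[1, ]]),
            paste0("k2", TET_NAMES[act[2, ]]),
            paste0("k3", TET_NAMES[act[3, ]]),
            "k4", "k5",
            if (tie_aid) "kAID" else c("kAID_hmdC", "kAID_C"),
            "kSMUG", "kTDG")
  cols
}

#' Assemble the steady-state flux-balance design system
#'
#' Turns the six steady-state balance equations
#' `f1 = f2, f2 = f3 + f7, f3 = f4 + f5, f4 = f6, f7 = f8, f9 = f10`,
#' written for every cell line with its measured modification levels and
#' enzyme levels substituted in, into one linear system `A k ~ b` in the
#' free rate coefficients.  Under the scale convention `kDNMT1 = 1`, the
#' methylation influx `C * DNMT1` is the only inhomogeneous term and forms
#' the right-hand side of each line's `f1 = f2` row.  Rows whose
#' modification levels are not observed (per the dataset's observed mask)
#' are dropped; with all six states observed each line contributes six
#' rows.
#'
#' @param dataset A [cell_line_dataset()].
#' @param structure The candidate [model_structure()]; coefficients of
#'   masked TETs get no column.
#' @param C Exogenous cytidine pool (default 1, the fitting convention).
#' @param tie_aid If `TRUE` (default) AID's two affinities are tied to a
#'   single shared coefficient `kAID`, which couples the uracil balance to
#'   the deamination branch and makes the system identifiable; if `FALSE`
#'   they are separate columns `kAID_hmdC`, `kAID_C` (the `f9 = f10` row
#'   is then homogeneous and the uracil branch is not identifiable).
#' @param lines Optional subset of cell-line IDs (used for
#'   cross-validation folds).
#' @return A list of class `"design_system"`: `A` (matrix), `b`, `columns`
#'   (parameter names), `rows` (labels `line:balance`), plus the
#'   convention fields.
#' @export
assemble_design <- function(dataset, structure, C = 1, tie_aid = TRUE,
                            lines = NULL) {
  stopifnot(inherits(dataset, "cell_line_dataset"),
            inherits(structure, "model_structure"))
  lines <- lines %||% dataset$cell_lines
  obs <- dataset$observed
  cols <- free_parameter_columns(structure, tie_aid)
  aid_hm <- if (tie_aid) "kAID" else "kAID_hmdC"
  aid_c  <- if (tie_aid) "kAID" else "kAID_C"
  act <- structure_activity(structure)
  use_row <- vapply(BALANCE_ROWS, function(r) all(obs[r$needs]), logical(1))
  if (!any(use_row))
    stop("no balance equation is estimable under the observed-state mask",
         call. = FALSE)
  A <- NULL; b <- NULL; row_labels <- character()
  for (line in lines) {
    e <- enzyme_profile_of(dataset, line)
    d <- observed_state_of(dataset, line)
    rows <- matrix(0, 6, length(cols), dimnames = list(NULL, cols))
    rhs <- numeric(6)
    k1 <- paste0("k1", TET_NAMES[act[1, ]])
    k2 <- paste0("k2", TET_NAMES[act[2, ]])
    k3 <- paste0("k3", TET_NAMES[act[3, ]])
    ## f1 = f2 : sum k1 * mdC * TET = C * DNMT1
    rows[1, k1] <- d[["mdC"]] * e[TET_NAMES[act[1, ]]]
    rhs[1] <- C * e[["DNMT1"]]
    ## f2 = f3 + f7
    rows[2, k1] <- d[["mdC"]] * e[TET_NAMES[act[1, ]]]
    rows[2, k2] <- rows[2, k2] - d[["hmdC"]] * e[TET_NAMES[act[2, ]]]
    rows[2, aid_hm] <- rows[2, aid_hm] - d[["hmdC"]] * e[["AID"]]
    ## f3 = f4 + f5
    rows[3, k2] <- d[["hmdC"]] * e[TET_NAMES[act[2, ]]]
    rows[3, k3] <- rows[3, k3] - d[["fdC"]] * e[TET_NAMES[act[3, ]]]
    rows[3, "k4"] <- -d[["fdC"]]
    ## f4 = f6
    rows[4, k3] <- d[["fdC"]] * e[TET_NAMES[act[3, ]]]
    rows[4, "k5"] <- -d[["cadC"]]
    ## f7 = f8
    rows[5, aid_hm] <- d[["hmdC"]] * e[["AID"]]
    rows[5, "kSMUG"] <- -d[["hmdU"]] * e[["SMUG1"]]
    ## f9 = f10
    rows[6, "kTDG"] <- d[["U"]] * e[["TDG"]]
    rows[6, aid_c] <- rows[6, aid_c] - C * e[["AID"]]
    rows[is.na(rows)] <- 0   # unobserved-state rows are dropped below
    A <- rbind(A, rows[use_row, , drop = FALSE])
    b <- c(b, rhs[use_row])
    row_labels <- c(row_labels,
                    paste0(line, ":", vapply(BALANCE_ROWS[use_row],
                                             `[[`, "", "label")))
  }
  rownames(A) <- row_labels
  out <- list(A = A, b = b, columns = cols, rows = row_labels,
              structure = structure, tie_aid = tie_aid, C = C)
  class(out) <- "design_system"
  out
}

#' Fit the rate coefficients by non-negative least squares
#'
#' Solves `min ||A k - b||_2` subject to `k >= 0` (affinities cannot be
#' negative) with the Lawson-Hanson active-set solver
#' (`pracma::lsqnonneg`).  Returns the full parameter vector on the
#' `kDNMT1 = 1` scale, with masked TET coefficients exactly zero.
#'
#' @param design A `"design_system"` from [assemble_design()].
#' @param warn_rank_deficient Emit a conditioning warning when the design
#'   matrix has numerically deficient column rank (e.g. all cell lines
#'   share proportional enzyme profiles).
#' @return A list of class `"fit_result"`: `params`
#'   ([rate_parameters()]), `coefficients` (the free coefficients as
#'   fitted), `residual_norm` (`||A k - b||_2`; values below 1e-12 are
#'   reported as 0), `rank`, `n_columns`, `rank_deficient`.
#' @export
fit_nnls <- function(design, warn_rank_deficient = TRUE) {
  stopifnot(inherits(design, "design_system"))
  A <- design$A; b <- design$b
  if (all(A == 0)) stop("degenerate design: all coefficients are zero",
                        call. = FALSE)
  rk <- qr(A)$rank
  deficient <- rk < ncol(A)
  if (deficient && warn_rank_deficient)
    warning(sprintf(paste0("design matrix is rank-deficient (rank %d < %d ",
                           "columns); parameters are not all identifiable"),
                    rk, ncol(A)), call. = FALSE)
  sol <- pracma::lsqnonneg(A, b)
  k <- stats::setNames(sol$x, design$columns)
  resid <- sqrt(sum((A %*% k - b)^2))
  if (resid < 1e-12) resid <- 0
  params <- rate_parameters()  # all zero except kDNMT1 = 1
  if (design$tie_aid && "kAID" %in% design$columns) {
    params[["kAID_hmdC"]] <- params[["kAID_C"]] <- k[["kAID"]]
    rest <- setdiff(design$columns, "kAID")
  } else rest <- design$columns
  rest <- intersect(rest, names(params))
  params[rest] <- k[rest]
  out <- list(params = params, coefficients = k, residual_norm = resid,
              rank = rk, n_columns = ncol(A), rank_deficient = deficient)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("NNLS fit:", x$n_columns, "free coefficients, residual",
      format(x$residual_norm, digits = 6), "\n")
  print(round(x$coefficients, 10))
  invisible(x)
}

#' Predict the steady state of a held-out cell line
#'
#' Given coefficients fitted on the training lines (same `kDNMT1 = 1`
#' scale), the prediction for a held-out line is simply the closed-form
#' [steady_state()] at that line's enzyme levels.  If the fit left a
#' species without a removal channel (a coefficient at the non-negativity
#' boundary), that species' prediction is `NA`.
#'
#' @param params Fitted [rate_parameters()].
#' @param enzymes The held-out line's [enzyme_profile()].
#' @param structure The candidate [model_structure()].
#' @param C Cytidine pool constant, as used in fitting.
#' @return A [modification_state()], possibly with `NA` components.
#' @export
predict_holdout <- function(params, enzymes, structure, C = 1) {
  steady_state(enzymes, params, structure, C = C, partial = TRUE)
}

#' Cross-validation performance index
#'
#' One half of the summed squared prediction errors over all folds and
#' observed state variables:
#' `J = 1/2 * sum_m sum_n (x_nm - d_nm)^2`, where `x_nm` is the predicted
#' and `d_nm` the measured level of state `n` in held-out line `m`.
#' `NA` predictions (undefined steady state) are scored against the
#' observation as if the prediction were zero.
#'
#' @param predictions,observations Matrices (folds x states) or lists of
#'   [modification_state()]s of equal length.
#' @param observed Logical mask over the six states; only observed states
#'   contribute.
#' @return Non-negative scalar; zero iff every prediction equals every
#'   observation.
#' @export
performance_index <- function(predictions, observations,
                              observed = rep(TRUE, 6)) {
  P <- as_state_matrix(predictions)
  D <- as_state_matrix(observations)
  if (!all(dim(P) == dim(D)))
    stop("predictions and observations differ in shape", call. = FALSE)
  P <- P[, observed, drop = FALSE]
  D <- D[, observed, drop = FALSE]
  P[is.na(P)] <- 0
  0.5 * sum((P - D)^2)
}

as_state_matrix <- function(x) {
  if (is.matrix(x)) return(x[, STATE_NAMES, drop = FALSE])
  do.call(rbind, lapply(x, function(s) unclass(as_modification_state(s, TRUE))))
}
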