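# Independent oracles and fixture builders.  Every oracle re-derives its
# quantity from first principles (literal flux expressions, brute-force
# subset enumeration, matrix exponentials) without touching the package's
# own code paths.

state_names <- c("mdC", "hmdC", "fdC", "cadC", "hmdU", "U")

# Literal term-by-term evaluation of the ten flux expressions.
oracle_fluxes <- function(state, enzymes, k, s1, s2, s3, C = 1) {
  on <- function(tet, s) as.numeric(tet %in% s)
  c(f1 = k[["kDNMT1"]] * C * enzymes[["DNMT1"]],
    f2 = (on("TET1", s1) * k[["k1TET1"]] * enzymes[["TET1"]] +
          on("TET2", s1) * k[["k1TET2"]] * enzymes[["TET2"]] +
          on("TET3", s1) * k[["k1TET3"]] * enzymes[["TET3"]]) * state[["mdC"]],
    f3 = (on("TET1", s2) * k[["k2TET1"]] * enzymes[["TET1"]] +
          on("TET2", s2) * k[["k2TET2"]] * enzymes[["TET2"]] +
          on("TET3", s2) * k[["k2TET3"]] * enzymes[["TET3"]]) * state[["hmdC"]],
    f4 = (on("TET1", s3) * k[["k3TET1"]] * enzymes[["TET1"]] +
          on("TET2", s3) * k[["k3TET2"]] * enzymes[["TET2"]] +
          on("TET3", s3) * k[["k3TET3"]] * enzymes[["TET3"]]) * state[["fdC"]],
    f5 = k[["k4"]] * state[["fdC"]],
    f6 = k[["k5"]] * state[["cadC"]],
    f7 = k[["kAID_hmdC"]] * state[["hmdC"]] * enzymes[["AID"]],
    f8 = k[["kSMUG"]] * state[["hmdU"]] * enzymes[["SMUG1"]],
    f9 = k[["kTDG"]] * state[["U"]] * enzymes[["TDG"]],
    f10 = k[["kAID_C"]] * C * enzymes[["AID"]])
}

# Brute-force NNLS: enumerate every support set, solve the unconstrained
# least-squares problem restricted to it, keep the feasible minimum.
# Exact for well-posed problems because the NNLS optimum is the
# unconstrained minimizer on its own support (KKT stationarity).
oracle_nnls <- function(A, b) {
  n <- ncol(A)
  best <- list(x = rep(0, n), obj = sum(b^2))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    xs <- tryCatch(qr.solve(A[, S, drop = FALSE], b), error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    x <- rep(0, n); x[S] <- pmax(xs, 0)
    obj <- sum((A %*% x - b)^2)
    if (obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  best
}

unit_enzymes <- function(level = 1)
  enzyme_profile(DNMT1 = level, TET1 = level, TET2 = level, TET3 = level,
                 AID = level, SMUG1 = level, TDG = level)

unit_params <- function(value = 1)
  do.call(rate_parameters,
          as.list(stats::setNames(rep(value, 16), names(rate_parameters()))))

rand_enzymes <- function()
  as_enzyme_profile(stats::setNames(exp(stats::runif(7, log(1e-3), log(10))),
                                    c("DNMT1", "TET1", "TET2", "TET3",
                                      "AID", "SMUG1", "TDG")))

rand_params <- function(lo = 1e-4, hi = 1) {
  v <- exp(stats::runif(16, log(lo), log(hi)))
  do.call(rate_parameters, as.list(stats::setNames(v, names(rate_parameters()))))
}

rand_state <- function()
  do.call(modification_state,
          as.list(stats::setNames(exp(stats::runif(6, log(1e-2), log(1e2))),
                                  state_names)))

rand_structure <- function() decode_structure(sample(0:342, 1))

# A design_system wrapper for raw (A, b) systems, so fit_nnls can be
# exercised on arbitrary small test matrices.
raw_design <- function(A, b) {
  cols <- paste0("c", seq_len(ncol(A)))
  colnames(A) <- cols
  structure(list(A = A, b = b, columns = cols,
                 rows = paste0("r", seq_len(nrow(A))),
                 structure = full_structure(), tie_aid = FALSE, C = 1),
            class = "design_system")
}

# Coefficient vector of the generating parameters in design-column order.
truth_in_columns <- function(params, columns) {
  k <- unclass(params)
  out <- numeric(length(columns))
  names(out) <- columns
  for (j in columns)
    out[j] <- if (j == "kAID") k[["kAID_hmdC"]] else k[[j]]
  out
}
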