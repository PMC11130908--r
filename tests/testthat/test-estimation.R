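noiseless_dataset <- function(seed = 42)
  generate_dataset(generator_config(cv = 0, seed = seed))

test_that("design assembly: shape and row content follow the balance equations", {
  ds <- noiseless_dataset()
  # one training line, full structure, all six states observed:
  # 6 balance rows, 14 free coefficients (9 TET + k4, k5, kAID, kSMUG, kTDG)
  des <- assemble_design(ds, full_structure(), lines = ds$cell_lines[1])
  expect_equal(dim(des$A), c(6, 14))
  expect_equal(which(des$b != 0), 1L)   # influx only in the f1 = f2 row
  expect_equal(des$b[1], ds$enzymes[1, "DNMT1"])

  # f2 = f3 + f7 row by direct substitution
  enz <- data.frame(DNMT1 = c(1, 1), TET1 = c(1, 1), TET2 = c(1, 1),
                    TET3 = c(1, 1), AID = c(2, 2), SMUG1 = c(1, 1),
                    TDG = c(1, 1))
  st <- data.frame(mdC = c(2, 2), hmdC = c(3, 3), fdC = c(1, 1),
                   cadC = c(1, 1), hmdU = c(1, 1), U = c(1, 1))
  tiny <- cell_line_dataset(enz, st)
  des2 <- assemble_design(tiny, full_structure(), lines = tiny$cell_lines[1])
  r2 <- des2$A[2, ]
  expect_equal(unname(r2[c("k1TET1", "k1TET2", "k1TET3")]), rep(2, 3))
  expect_equal(unname(r2[c("k2TET1", "k2TET2", "k2TET3")]), rep(-3, 3))
  expect_equal(unname(r2[["kAID"]]), -3 * 2)
  expect_equal(unname(r2[c("k4", "k5", "kSMUG", "kTDG")]), rep(0, 4))
  expect_equal(des2$b[2], 0)

  # untied AID: 15 columns, homogeneous uracil row
  des3 <- assemble_design(tiny, full_structure(), tie_aid = FALSE,
                          lines = tiny$cell_lines[1])
  expect_equal(ncol(des3$A), 15)
  expect_true(all(c("kAID_hmdC", "kAID_C") %in% des3$columns))
})

test_that("noiseless synthetic data lie exactly in the assembler's feasible set", {
  ds <- noiseless_dataset()
  gt <- ground_truth(ds)
  des <- assemble_design(ds, gt$structure)
  k_true <- truth_in_columns(gt$params, des$columns)
  resid <- des$A %*% k_true - des$b
  expect_lt(max(abs(resid)) / max(abs(des$b)), 1e-10)
})

test_that("NNLS solves the textbook cases", {
  # clipping at the non-negativity boundary
  fit <- fit_nnls(raw_design(diag(2), c(1, -1)))
  expect_equal(unname(fit$coefficients), c(1, 0))
  expect_equal(fit$residual_norm, 1)

  # interior solution equals ordinary least squares
  A <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  fit2 <- fit_nnls(raw_design(A, c(1, 1, 3)))
  expect_equal(unname(fit2$coefficients), c(4 / 3, 4 / 3))

  expect_error(fit_nnls(raw_design(matrix(0, 2, 2), c(1, 1))), "degenerate")
})

test_that("NNLS matches the brute-force active-set oracle on random systems", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:4, 1)
    m <- n + sample(1:3, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    fit <- fit_nnls(raw_design(A, b))
    oracle <- oracle_nnls(A, b)
    expect_equal(fit$residual_norm, sqrt(oracle$obj), tolerance = 1e-8)
    expect_equal(unname(fit$coefficients), oracle$x, tolerance = 1e-6)
  }
})

test_that("proportional enzyme profiles give a rank-deficient design with a warning", {
  prof <- rand_enzymes()
  enz <- as.data.frame(rbind(unclass(prof) * 1, unclass(prof) * 2,
                             unclass(prof) * 0.5))
  gt_s <- default_true_structure()
  st <- as.data.frame(t(vapply(seq_len(3), function(i)
    unclass(steady_state(as_enzyme_profile(enz[i, ]), default_true_params(),
                         gt_s)), numeric(6))))
  ds <- cell_line_dataset(enz, st)
  des <- assemble_design(ds, full_structure())
  expect_warning(fit_nnls(des), "rank-deficient")
})

test_that("noiseless parameter recovery is exact under the true structure", {
  ds <- noiseless_dataset(7)
  gt <- ground_truth(ds)
  fit <- resubstitution_fit(ds, gt$structure)
  k_true <- truth_in_columns(gt$params, names(fit$coefficients))
  expect_lt(max(abs(fit$coefficients - k_true) / k_true), 1e-6)
  expect_equal(fit$residual_norm, 0)      # below the 1e-12 reporting floor
  expect_lt(fit$train_mse, 1e-12)
  # full parameter vector: masked TETs stay exactly zero
  act <- structure_activity(gt$structure)
  masked <- c(paste0("k1", TET_NAMES[!act[1, ]]),
              paste0("k2", TET_NAMES[!act[2, ]]),
              paste0("k3", TET_NAMES[!act[3, ]]))
  expect_true(all(unclass(fit$params)[masked] == 0))
})

test_that("hold-out prediction is the closed-form steady state and scales covariantly", {
  ds <- noiseless_dataset(9)
  gt <- ground_truth(ds)
  fit <- resubstitution_fit(ds, gt$structure)
  line <- ds$cell_lines[3]
  enz <- enzyme_profile_of(ds, line)
  pred <- predict_holdout(fit$params, enz, gt$structure)
  expect_equal(unclass(pred), unclass(observed_state_of(ds, line)),
               tolerance = 1e-8)

  # agreement with the long-time limit of the integrator
  r <- -diag(system_matrix(enz, fit$params, gt$structure))
  traj <- simulate_model(modification_state(), enz, fit$params, gt$structure,
                         horizon = 50 / min(r), n_points = 3)
  expect_equal(as.numeric(traj[3, names(pred)]), unname(unclass(pred)),
               tolerance = 1e-6)

  # doubling all enzyme levels doubles the methylation influx; the
  # closed-form cascade responds by leaving ratio-driven levels covariant
  enz2 <- as_enzyme_profile(unclass(enz) * 2)
  pred2 <- predict_holdout(fit$params, enz2, gt$structure)
  # oxidation/removal rates all double while the influx doubles too, so
  # enzyme-removed species keep their levels except those with the
  # first-order channels k4, k5 in the denominator
  expect_equal(pred2[["mdC"]], pred[["mdC"]], tolerance = 1e-12)
  expect_equal(pred2[["hmdC"]], pred[["hmdC"]], tolerance = 1e-12)
  expect_equal(pred2[["U"]], pred[["U"]], tolerance = 1e-12)
})

test_that("performance index is half the summed squared error over observed states", {
  obs <- list(modification_state(1, 1, 1, 1, 1, 1),
              modification_state(2, 2, 2, 2, 2, 2))
  expect_equal(performance_index(obs, obs), 0)
  pred <- list(modification_state(3, 1, 1, 1, 1, 1),
               modification_state(2, 2, 2, 2, 2, 2))
  expect_equal(performance_index(pred, obs), 2)    # 1/2 * 2^2
  # M folds, N states, all residuals r: J = M*N*r^2/2
  M <- 5; r <- 0.3
  P <- matrix(1 + r, M, 6, dimnames = list(NULL, state_names))
  D <- matrix(1, M, 6, dimnames = list(NULL, state_names))
  expect_equal(performance_index(P, D), M * 6 * r^2 / 2)
  expect_error(performance_index(P[1:2, ], D), "shape")
})

test_that("cross-validation: M folds, zero index on noiseless data, order invariance", {
  ds <- noiseless_dataset(13)
  gt <- ground_truth(ds)
  sc <- cross_validate_structure(ds, gt$structure)
  expect_equal(sc$M, 5)
  expect_length(sc$folds, 5)
  expect_equal(sc$N, 6)
  expect_lt(sc$J_cv, 1e-12)

  # permuting the cell lines leaves J unchanged
  perm <- rev(ds$cell_lines)
  ds_perm <- cell_line_dataset(ds$enzymes[perm, ], ds$states[perm, ])
  sc_perm <- cross_validate_structure(ds_perm, gt$structure)
  expect_equal(sc_perm$J_cv, sc$J_cv, tolerance = 1e-6)
})

test_that("ranking: complete, sorted, stable ties, noiseless recovery at rank one", {
  ds <- noiseless_dataset(17)
  gt <- ground_truth(ds)
  rk <- rank_structures(ds)
  J <- vapply(rk$scores, `[[`, numeric(1), "J_cv")
  codes <- vapply(rk$scores, `[[`, integer(1), "code")
  expect_length(rk$scores, 343)
  expect_true(all(diff(J) >= 0))
  # ties broken by ascending structure code
  for (i in which(diff(J) == 0)) expect_lt(codes[i], codes[i + 1])
  # the generating structure attains the minimum; among the (near-)zero
  # scores it is first of the structures that nest it
  true_code <- encode_structure(gt$structure)
  pos <- which(codes == true_code)
  expect_lt(J[pos], 1e-12)
  expect_equal(J[pos], J[1], tolerance = 1e-10)
})

test_that("resubstitution training objective is monotone under structure nesting", {
  ds <- generate_dataset(generator_config(cv = 0.05, seed = 23))
  full_fit <- resubstitution_fit(ds, full_structure())
  subs <- list(default_true_structure(),
               model_structure("TET1", "TET2", "TET3"),
               model_structure(c("TET1", "TET2"), "TET1", "TET2"))
  for (s in subs) {
    sub_fit <- resubstitution_fit(ds, s)
    expect_lte(full_fit$residual_norm, sub_fit$residual_norm + 1e-10)
  }
})

test_that("resubstitution index is optimistic relative to cross-validation", {
  for (seed in c(3, 5, 8)) {
    ds <- generate_dataset(generator_config(cv = 0.05, seed = seed))
    gt <- ground_truth(ds)
    fit <- resubstitution_fit(ds, gt$structure)
    sc <- cross_validate_structure(ds, gt$structure)
    cv_mse <- 2 * sc$J_cv / (sc$M * sc$N)   # per-term analogue of J
    expect_lte(fit$train_mse, cv_mse)
  }
})
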