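planted_clock_obs <- function(n_per_study = 20, n_decoy = 200, seed = 30,
                              studies = c("sA", "sB", "sC")) {
  set.seed(seed)
  n <- n_per_study * length(studies)
  g1 <- rnorm(n, 0, 3)
  g2 <- rnorm(n, 0, 3)
  ages <- 20 + 3 * g1 - 2 * g2
  decoys <- matrix(rnorm(n * n_decoy), n)
  expr <- cbind(g1 = g1, g2 = g2, decoys)
  colnames(expr) <- c("g1", "g2", sprintf("d%03d", seq_len(n_decoy)))
  meta <- data.frame(study = rep(studies, each = n_per_study),
                     sample_id = paste0("smp", seq_len(n)),
                     cell_class = rep_len(c("A", "B"), n),
                     age_weeks = ages, n_cells = 50L)
  make_obs(expr, meta)
}

test_that("build_observations composes pseudobulk with per-mode normalization", {
  pbs <- small_pbs()
  universe <- small_obs()$genes
  obs <- small_obs("log")
  # log rows equal lognormalize of the aggregate restricted to the universe
  pb1 <- pbs[[1]]
  expect_equal(unname(obs$expr[1, ]),
               unname(lognormalize(pb1$counts[universe, , drop = FALSE])[, 1]),
               tolerance = 1e-12)
  # row count = sum over studies of samples x classes present
  oracle_rows <- sum(vapply(pbs, function(pb) ncol(pb$counts), integer(1)))
  expect_equal(nrow(obs$expr), oracle_rows)
  # rank mode is invariant to scaling one profile's counts
  pb_scaled <- pb1
  pb_scaled$counts[, 3] <- pb_scaled$counts[, 3] * 7
  r1 <- build_observations(list(pb1), universe, "rank")
  r2 <- build_observations(list(pb_scaled), universe, "rank")
  expect_identical(r1$expr[3, ], r2$expr[3, ])
  # unknown gene in the universe errors
  expect_error(build_observations(pbs, c(universe, "missing_gene"), "log"),
               "universe")
})

test_that("equal_weights balances classes within studies and studies overall", {
  meta <- data.frame(study = "s1", sample_id = paste0("m", 1:4),
                     cell_class = c("A", "A", "A", "B"),
                     age_weeks = 10, n_cells = 10L)
  obs <- make_obs(matrix(0, 4, 2, dimnames = list(NULL, c("x", "y"))), meta)
  w <- equal_weights(obs)
  expect_equal(w, c(4 / 6, 4 / 6, 4 / 6, 2), tolerance = 1e-12)
  expect_equal(as.vector(tapply(w, meta$cell_class, sum)), c(2, 2))

  # uniform multiplicity gives unit weights
  meta2 <- expand.grid(study = c("s1", "s2"), cell_class = c("A", "B"),
                       rep = 1:3, stringsAsFactors = FALSE)
  meta2$sample_id <- paste0("m", seq_len(nrow(meta2)))
  meta2$age_weeks <- 10
  obs2 <- make_obs(matrix(0, nrow(meta2), 2,
                          dimnames = list(NULL, c("x", "y"))), meta2)
  expect_equal(equal_weights(obs2), rep(1, nrow(meta2)))

  # random design: accumulation oracle for the totals
  set.seed(31)
  meta3 <- data.frame(study = sample(c("s1", "s2", "s3"), 60, TRUE),
                      cell_class = sample(c("A", "B", "C", "D"), 60, TRUE),
                      sample_id = paste0("m", 1:60), age_weeks = 10)
  obs3 <- make_obs(matrix(0, 60, 2, dimnames = list(NULL, c("x", "y"))), meta3)
  w3 <- equal_weights(obs3)
  expect_equal(sum(w3), 60, tolerance = 1e-9)
  study_tot <- tapply(w3, meta3$study, sum)
  expect_equal(unname(diff(range(study_tot))), 0, tolerance = 1e-9)
  for (s in unique(meta3$study)) {
    cls_tot <- tapply(w3[meta3$study == s], meta3$cell_class[meta3$study == s],
                      sum)
    expect_equal(unname(diff(range(cls_tot))), 0, tolerance = 1e-9)
  }
})

test_that("fit_clock recovers a planted sparse linear age signal", {
  obs <- planted_clock_obs()
  model <- fit_clock(obs, alphas = c(0.5, 1))
  expect_true(all(c("g1", "g2") %in% names(model$coef)))
  held <- planted_clock_obs(seed = 33)
  mae <- mean(abs(predict(model, held) - held$meta$age_weeks))
  expect_lt(mae, 0.5)
})

test_that("a constant age target yields an intercept-only clock", {
  obs <- planted_clock_obs()
  obs$meta$age_weeks <- rep(21, nrow(obs$expr))
  model <- fit_clock(obs, alphas = 1)
  expect_length(model$coef, 0)
  expect_equal(predict(model, obs), rep(21, nrow(obs$expr)), tolerance = 1e-6)
})

test_that("lasso shares load across a perfectly collinear pair", {
  # for exact duplicates the lasso objective depends only on the summed
  # coefficient; any same-sign split is optimal, so assert the sum matches
  # the non-duplicated fit and predictions are unchanged
  obs <- planted_clock_obs(n_decoy = 30)
  expr <- cbind(obs$expr, g1_copy = obs$expr[, "g1"])
  obs2 <- make_obs(expr, obs$meta)
  lam <- 0.2
  m1 <- fit_clock(obs, alphas = 1, lambda = lam)
  m2 <- fit_clock(obs2, alphas = 1, lambda = lam)
  b <- c(m2$coef["g1"], m2$coef["g1_copy"])
  b[is.na(b)] <- 0
  expect_equal(unname(sum(b)), unname(m1$coef["g1"]), tolerance = 1e-3)
  expect_true(prod(b) >= 0)  # never opposite signs
  expect_equal(predict(m2, obs2), predict(m1, obs), tolerance = 1e-3)
})

test_that("near-unpenalized fit approaches the weighted OLS closed form", {
  set.seed(34)
  n <- 40
  expr <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("g", 1:5)))
  ages <- 15 + expr %*% c(2, -1, 0.5, 0, 1) + rnorm(n, 0, 0.1)
  meta <- data.frame(study = rep(c("s1", "s2"), each = n / 2),
                     sample_id = paste0("m", 1:n),
                     cell_class = "A", age_weeks = as.vector(ages))
  obs <- make_obs(expr, meta)
  w <- runif(n, 0.5, 2)
  model <- fit_clock(obs, w, alphas = 0.01, lambda = 1e-8)
  X <- cbind(1, expr)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * ages))
  expect_equal(model$intercept, beta[1], tolerance = 1e-4)
  full <- setNames(numeric(5), paste0("g", 1:5))
  full[names(model$coef)] <- model$coef
  expect_equal(unname(full), unname(beta[-1, 1]), tolerance = 1e-4)
})

test_that("sparsity is monotone non-increasing in lambda at fixed alpha", {
  obs <- planted_clock_obs(n_decoy = 100)
  lambdas <- c(0.01, 0.1, 0.5, 1, 3)
  nz <- vapply(lambdas, function(l)
    length(fit_clock(obs, alphas = 1, lambda = l)$coef), integer(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("predict validates modes, genes and computes exact dot products", {
  genes <- c("a", "b", "c", "d", "e")
  cf <- c(a = 1.5, b = 0.25, c = -2, d = 0.5, e = -0.75)
  model <- structure(list(mode = "log", genes = genes, coef = cf,
                          intercept = 12.5, alpha = 1, lambda = 0.1,
                          provenance = list()),
                     class = "clock_model")
  set.seed(35)
  x <- matrix(runif(3 * 5, 0, 4), 3, dimnames = list(NULL, genes))
  oracle <- vapply(1:3, function(i) {
    acc <- 12.5
    for (g in genes) acc <- acc + cf[[g]] * x[i, g]
    acc
  }, numeric(1))
  expect_equal(predict(model, x), oracle, tolerance = 1e-10)

  # zero-coefficient model predicts the intercept everywhere
  m0 <- model
  m0$coef <- numeric(0)
  expect_equal(predict(m0, x), rep(12.5, 3))

  # mode mismatch errors
  obs_rank <- make_obs(x, data.frame(study = "s", sample_id = c("1", "2", "3"),
                                     cell_class = "A", age_weeks = 1:3),
                       mode = "rank")
  expect_error(predict(model, obs_rank), "mode mismatch")

  # missing model genes: error by default; <= 20% imputed at zero under the
  # flag; more than 20% missing always errors
  x2 <- x[, c("a", "b", "c", "d"), drop = FALSE]
  expect_error(predict(model, x2), "missing")
  expect_message(p2 <- predict(model, x2, allow_missing = TRUE), "imputed")
  expect_equal(p2, oracle - cf[["e"]] * x[, "e"], ignore_attr = TRUE,
               tolerance = 1e-10)
  x3 <- x[, c("a", "b"), drop = FALSE]
  expect_error(predict(model, x3, allow_missing = TRUE), "20%")
})

test_that("rank-mode predictions are bit-identical under per-profile scaling", {
  obs <- small_obs("rank")
  model <- fit_clock(obs, equal_weights(obs), alphas = 0.5)
  counts <- small_pbs()[[1]]$counts
  scaled <- counts %*% diag(seq(1, 7, length.out = ncol(counts)))
  dimnames(scaled) <- dimnames(counts)
  p1 <- predict(model, t(rank_normalize(counts)))
  p2 <- predict(model, t(rank_normalize(scaled)))
  expect_identical(p1, p2)
})

subset_obs_one_study <- function(obs) {
  idx <- obs$meta$study == obs$meta$study[1]
  structure(list(expr = obs$expr[idx, , drop = FALSE],
                 meta = obs$meta[idx, , drop = FALSE],
                 mode = obs$mode, genes = obs$genes),
            class = "observation_table")
}

test_that("LOSO covers each observation once per held-out study", {
  obs <- small_obs("log")
  cv <- loso_cv(obs, alphas = 0.5)
  expect_equal(sort(unique(cv$rows$fold)), sort(unique(obs$meta$study)))
  expect_equal(nrow(cv$rows), nrow(obs$expr))
  expect_false(any(is.na(cv$rows$pred)))
  expect_equal(cv$rows$fold, as.character(obs$meta$study))
  expect_error(loso_cv(subset_obs_one_study(obs)), "2 groups")
})

test_that("LOCO folds are classes and cover every row", {
  obs <- small_obs("log")
  cv <- loco_cv(obs, alphas = 0.5)
  expect_equal(sort(unique(cv$rows$fold)),
               sort(unique(obs$meta$cell_class)))
  expect_equal(nrow(cv$rows), nrow(obs$expr))
  expect_false(any(is.na(cv$rows$pred)))
})

test_that("held-out predictions ignore held-out age labels entirely", {
  obs <- small_obs("log")
  cv1 <- loso_cv(obs, alphas = 0.5)
  obs_perm <- obs
  idx <- which(obs$meta$study == "study1")
  obs_perm$meta$age_weeks[idx] <- rev(obs$meta$age_weeks[idx])
  cv2 <- loso_cv(obs_perm, alphas = 0.5)
  expect_identical(cv1$rows$pred[idx], cv2$rows$pred[idx])

  cl <- obs$meta$cell_class[1]
  cc1 <- loco_cv(obs, alphas = 0.5)
  obs_perm2 <- obs
  jdx <- which(obs$meta$cell_class == cl)
  obs_perm2$meta$age_weeks[jdx] <- rev(obs$meta$age_weeks[jdx])
  cc2 <- loco_cv(obs_perm2, alphas = 0.5)
  expect_identical(cc1$rows$pred[jdx], cc2$rows$pred[jdx])
})

test_that("per-class clocks skip single-study classes with a warning", {
  obs <- small_obs("log")
  idx <- !(obs$meta$cell_class == "Vascular" & obs$meta$study != "study1")
  sub <- structure(list(expr = obs$expr[idx, , drop = FALSE],
                        meta = obs$meta[idx, , drop = FALSE],
                        mode = obs$mode, genes = obs$genes),
                   class = "observation_table")
  expect_warning(models <- fit_celltype_clocks(sub, alphas = 0.5), "Vascular")
  expect_false("Vascular" %in% names(models))
  expect_true(all(vapply(models, inherits, logical(1), "clock_model")))
})

test_that("restrict_orthologs validates bijections and renames namespaces", {
  obs <- planted_clock_obs(n_decoy = 10)
  id_map <- data.frame(source = obs$genes, target = paste0("mmu-", obs$genes))
  same <- restrict_orthologs(obs, data.frame(source = obs$genes,
                                             target = obs$genes))
  expect_equal(sort(same$genes), sort(obs$genes))
  expect_equal(same$expr[, obs$genes[1]], obs$expr[, obs$genes[1]])

  # foreign namespace is renamed into the source namespace
  foreign <- obs
  colnames(foreign$expr) <- paste0("mmu-", obs$genes)
  foreign$genes <- colnames(foreign$expr)
  back <- restrict_orthologs(foreign, id_map)
  expect_setequal(back$genes, obs$genes)
  expect_equal(back$expr[, "g1"], obs$expr[, "g1"])

  bad <- data.frame(source = c("g1", "g2"), target = c("m1", "m1"))
  expect_error(restrict_orthologs(obs, bad), "m1")
  none <- data.frame(source = "zz", target = "yy")
  expect_error(restrict_orthologs(obs, none), "no overlap")
})

test_that("clock models serialize round-trip through JSON", {
  obs <- planted_clock_obs(n_decoy = 20)
  model <- fit_clock(obs, alphas = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  m2 <- read_model_json(path)
  expect_identical(m2$coef, model$coef)
  expect_identical(m2$intercept, model$intercept)
  expect_identical(m2$mode, model$mode)
  expect_equal(predict(m2, obs), predict(model, obs))
})
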