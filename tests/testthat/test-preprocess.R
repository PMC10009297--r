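make_ds <- function(resp, age = NULL, group = NULL) {
  n <- nrow(resp)
  if (is.null(colnames(resp))) {
    colnames(resp) <- paste0("V", seq_len(ncol(resp)))
  }
  comm <- setNames(rep(c("A", "B"), length.out = ncol(resp)),
                   colnames(resp))
  structure(list(responses = resp,
                 group = group %||% rep("g", n),
                 age = age %||% rep(25L, n),
                 sex = rep("female", n), community = comm),
            class = "survey_dataset")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("straight-liner filtering removes exactly the constant rows", {
  resp <- rbind(c(1, 2, 3, 4), c(3, 3, 3, 3), c(2, 2, 1, 2))
  out <- filter_straightliners(make_ds(resp))
  expect_identical(out$n_excluded, 1L)
  expect_identical(unname(out$data$responses), resp[c(1, 3), ])

  none <- filter_straightliners(make_ds(resp[c(1, 3), ]))
  expect_identical(none$n_excluded, 0L)
  expect_identical(none$data$responses, make_ds(resp[c(1, 3), ])$responses)

  all_const <- filter_straightliners(make_ds(rbind(c(1, 1, 1), c(5, 5, 5))))
  expect_identical(all_const$n_excluded, 2L)
  expect_identical(nrow(all_const$data$responses), 0L)

  # idempotence
  twice <- filter_straightliners(out$data)
  expect_identical(twice$n_excluded, 0L)
})

test_that("age filtering is a closed interval and validates bounds", {
  resp <- matrix(3, 4, 3) + diag(3)[c(1, 2, 3, 1), ]
  ds <- make_ds(resp, age = c(19L, 20L, 29L, 30L))
  out <- filter_age(ds, 20, 29)
  expect_identical(out$data$age, c(20L, 29L))
  expect_identical(out$n_excluded, 2L)
  expect_identical(filter_age(ds, 0, 100)$n_excluded, 0L)
  expect_identical(nrow(filter_age(ds, 50, 60)$data$responses), 0L)
  expect_error(filter_age(ds, 30, 20), "min_age")
})

test_that("score rescaling maps the attainable range onto 0-100", {
  expect_equal(rescale_scores(17, 17, 85), 0)
  expect_equal(rescale_scores(85, 17, 85), 100)
  expect_equal(rescale_scores(51, 17, 85), 50)
  expect_error(rescale_scores(10, 17, 85), "outside")
  expect_error(rescale_scores(50, 85, 17), "max_possible")
})

test_that("Cronbach's alpha matches its closed form and invariances", {
  # two standardized items with sample correlation exactly 0.5: alpha = 2/3
  n <- 400
  z <- with_seed_test(1, {
    x <- as.numeric(scale(rnorm(n)))
    e <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))
    cbind(x, 0.5 * x + sqrt(0.75) * e)
  })
  expect_equal(cor(z)[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(z), 2 / 3, tolerance = 1e-10)

  # uncorrelated items: alpha near 0 at large n
  un <- with_seed_test(2, matrix(rnorm(20000 * 5), ncol = 5))
  expect_lt(abs(cronbach_alpha(un)), 0.05)

  # duplicated item: alpha = 1
  x <- with_seed_test(3, rnorm(50))
  expect_equal(cronbach_alpha(cbind(x, x)), 1)

  # invariant to item order and constant shifts
  items <- with_seed_test(4, matrix(sample(1:5, 200, TRUE), ncol = 4))
  expect_equal(cronbach_alpha(items), cronbach_alpha(items[, 4:1]))
  expect_equal(cronbach_alpha(items), cronbach_alpha(items + 10))

  expect_error(cronbach_alpha(matrix(1, 5, 3)), "variance")
})

test_that("topological overlap flags duplicates but spares distinct profiles", {
  X <- with_seed_test(5, matrix(rnorm(500 * 9), ncol = 9))
  X <- cbind(X, X[, 1])  # duplicate item
  colnames(X) <- paste0("I", 1:10)
  flagged <- detect_topological_overlap(X)
  expect_identical(nrow(flagged), 1L)
  expect_setequal(c(flagged$item_i, flagged$item_j), c("I1", "I10"))
  expect_equal(flagged$prop_unique, 0)

  # near-uncorrelated items: no pair reaches the r threshold
  expect_identical(nrow(detect_topological_overlap(X[, 1:9])), 0L)

  expect_error(detect_topological_overlap(X[, 1:2]), "at least 3")
})

test_that("high-r pair with distinct external profiles is not flagged", {
  # items A and B correlate .8, but A correlates .4 with five background
  # items while B is uncorrelated with them
  p <- 7
  R <- diag(p)
  R[1, 2] <- R[2, 1] <- 0.8
  for (k in 3:7) {
    R[1, k] <- R[k, 1] <- 0.4
    R[k, 3:7] <- 0.5
  }
  diag(R) <- 1
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  X <- with_seed_test(6, matrix(rnorm(1000 * p), ncol = p) %*% chol(R))
  colnames(X) <- c("A", "B", paste0("C", 1:5))
  flagged <- detect_topological_overlap(X)
  expect_false(any(flagged$item_i == "A" & flagged$item_j == "B"))

  # symmetric in the pair's column order
  X2 <- X[, c(2, 1, 3:7)]
  f2 <- detect_topological_overlap(X2)
  expect_identical(nrow(f2), nrow(flagged))
})

test_that("clean_survey chains the cleaning steps and accounts for every row", {
  spec <- true_network_spec(seed = 10)
  ds <- generate_study(list(group_spec("g", spec, 400,
                                       straightliner_rate = 0.05)),
                       age_range = c(16, 29), seed = 2)
  out <- clean_survey(ds)
  rep <- out$report
  expect_identical(rep$n_input,
                   rep$n_final + rep$n_excluded_straightline +
                     rep$n_excluded_age)
  expect_gte(rep$n_excluded_straightline, 20L)  # 20 planted, chance extras
  expect_true(all(out$data$age >= 20 & out$data$age <= 29))
  expect_true(all(unlist(rep$alpha_by_scale) > 0))
})
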