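test_that("enumeration covers {1,2}^4 exactly once, in canonical order", {
  st <- dugong_studies()
  grid <- enumerate_permutations(st$original, st$replication)

  expect_equal(nrow(grid), 16)
  expect_equal(grid$study, 1:16)
  # bijection onto the version hypercube
  keys <- paste(grid$spre, grid$model, grid$spost, grid$dstruct)
  expect_equal(anyDuplicated(keys), 0L)
  # canonical order: spre slowest-varying, dstruct fastest
  expect_equal(grid$spre, rep(1:2, each = 8))
  expect_equal(grid$model, rep(rep(1:2, each = 4), 2))
  expect_equal(grid$spost, rep(rep(1:2, each = 2), 4))
  expect_equal(grid$dstruct, rep(1:2, 8))
  # exhaustive-enumeration oracle: fixing any one component leaves 2^3 cells
  for (comp in permutable_roles()) {
    expect_equal(sum(grid[[comp]] == 1), 8)
    expect_equal(sum(grid[[comp]] == 2), 8)
  }
})

test_that("assemble picks components by version and is idempotent", {
  st <- dugong_studies()
  same <- assemble(c(1, 1, 1, 1), st$original, st$replication)
  for (field in c("pre_data", "model", "post_data", "data_structure")) {
    expect_identical(same[[field]], st$original[[field]])
  }
  cross <- assemble(c(1, 2, 1, 2), st$original, st$replication)
  expect_identical(cross$pre_data, st$original$pre_data)
  expect_identical(cross$model, st$replication$model)
  expect_identical(cross$post_data, st$original$post_data)
  expect_identical(cross$data_structure, st$replication$data_structure)
  # idempotent: same version vector, same spec
  expect_identical(cross, assemble(c(1, 2, 1, 2), st$original, st$replication))
  expect_error(assemble(c(1, 2, 3, 1), st$original, st$replication),
               "1 or 2")
})

test_that("permutability: missing predictors and prior transfer rules", {
  st <- dugong_studies()
  # parents of an admissible pair are always performable
  expect_true(as.logical(is_permutable(st$original)))
  expect_true(as.logical(is_permutable(st$replication)))

  # linear model needs weight; the age-only design cannot feed it
  bad <- assemble(c(2, 1, 1, 1), st$original, st$replication)
  flag <- is_permutable(bad)
  expect_false(as.logical(flag))
  expect_match(attr(flag, "reason"), "weight")
  expect_match(attr(flag, "reason"), "age only")

  # the full design feeds the age-only model: extra information is ignored
  ok <- assemble(c(1, 2, 1, 1), st$original, st$replication)
  expect_true(as.logical(is_permutable(ok)))

  # vague priors transfer to any model's parameters
  bayes_on_linear <- assemble(c(1, 1, 2, 1), st$original, st$replication)
  expect_true(as.logical(is_permutable(bayes_on_linear)))

  # informative priors declared for the nonlinear parameterization do not
  inf <- experiment_spec(
    "informative", predictor_design(c("age", "weight")),
    linear_growth_model(),
    bayesian_method(priors = informative_priors(
      declared_for = c("alpha", "beta3", "gamma", "tau"))),
    data_structure(20))
  flag2 <- is_permutable(inf)
  expect_false(as.logical(flag2))
  expect_match(attr(flag2, "reason"), "informative priors")
})

test_that("the dugong grid flags exactly studies 9-12 as non-permutable", {
  st <- dugong_studies()
  grid <- enumerate_permutations(st$original, st$replication)
  expect_equal(grid$study[!grid$valid], 9:12)
  # the invalid block is precisely the (Spre=2, M=1) stratum
  expect_true(all(grid$spre[!grid$valid] == 2 & grid$model[!grid$valid] == 1))
})

test_that("a self-pair enumerates 16 valid identical cells", {
  st <- dugong_studies()
  grid <- enumerate_permutations(st$original, st$original)
  expect_true(all(grid$valid))
  specs <- lapply(1:16, function(i) {
    assemble(unlist(grid[i, c("spre", "model", "spost", "dstruct")]),
             st$original, st$original)
  })
  for (i in 2:16) {
    expect_identical(specs[[i]]$model, specs[[1]]$model)
    expect_identical(specs[[i]]$data_structure, specs[[1]]$data_structure)
  }
})

test_that("the permutation axiom rejects a pair with no performable cell", {
  # both parents pair an age-only design with the weight-requiring model,
  # so every assembled cell is non-performable
  bad <- experiment_spec("bad", predictor_design("age"),
                         linear_growth_model(), least_squares_method(),
                         data_structure(20))
  expect_error(enumerate_permutations(bad, bad), "axiom")
})
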