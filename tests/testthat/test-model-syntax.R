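test_that("model syntax parses into variables, roles and terms", {
  m <- sem_model("energy =~ mass_resid + ratio")
  expect_s3_class(m, "sem_model")
  expect_equal(sort(m$variables$name), c("energy", "mass_resid", "ratio"))
  expect_equal(m$variables$role[m$variables$name == "energy"], "latent")
  expect_equal(sum(m$terms$op == "=~"), 2L)

  # composite definition pins the residual variance to zero at parse time
  m2 <- sem_model("condition <~ m + bc")
  expect_equal(m2$variables$role[m2$variables$name == "condition"], "composite")
  expect_equal(sum(m2$terms$op == "<~"), 2L)
  dvar <- m2$terms[m2$terms$op == "~~" & m2$terms$lhs == "condition", ]
  expect_equal(dvar$fixed, 0)

  # fixed values and labels on right-hand terms
  m3 <- sem_model("f =~ 1*x1 + lam*x2 + x3")
  expect_equal(m3$terms$fixed[m3$terms$rhs == "x1"], 1)
  expect_equal(m3$terms$label[m3$terms$rhs == "x2"], "lam")

  # comments and blank lines are ignored
  m4 <- sem_model("# a comment\n\ny ~ x # trailing\n")
  expect_equal(nrow(m4$terms), 1L)
})

test_that("malformed syntax fails with the offending line number", {
  expect_error(sem_model("x =~"), "line 1")
  expect_error(sem_model("y ~ x\nx =~ + z"), "line 2")
  expect_error(sem_model("y ~ x\nnonsense line"), "line 2")
  expect_error(sem_model("f =~ 2*x1\nf =~ 3*x1"), "conflicting fixed")
  expect_error(sem_model("   \n  "), "empty model")
})

test_that("covariance terms are order-insensitive and deduplicated", {
  m <- sem_model("a ~~ b\nb ~~ a")
  expect_equal(sum(m$terms$op == "~~"), 1L)
})

test_that("cyclic directed structures are rejected", {
  expect_error(sem_model("a ~ b\nb ~ c\nc ~ a"), "cycle")
})

test_that("identification fixes scales and completes variance terms", {
  # default scale-setting: first free loading fixed to 1
  m <- apply_identification(sem_model("f =~ x1 + x2 + x3"))
  loads <- m$terms[m$terms$op == "=~", ]
  expect_equal(loads$fixed, c(1, NA, NA))
  # residual variances for all indicators plus the factor variance
  expect_true(all(paste0("x", 1:3) %in%
                    m$terms$lhs[m$terms$op == "~~" & m$terms$lhs == m$terms$rhs]))

  # user-fixed loading elsewhere suppresses the default
  m2 <- apply_identification(sem_model("f =~ x1 + 1*x2"))
  loads2 <- m2$terms[m2$terms$op == "=~", ]
  expect_equal(loads2$fixed[loads2$rhs == "x1"], NA_real_)

  # std_lv scales by the factor variance instead
  m3 <- apply_identification(sem_model("f =~ x1 + x2 + x3"), std_lv = TRUE)
  expect_true(all(is.na(m3$terms$fixed[m3$terms$op == "=~"])))
  fvar <- m3$terms[m3$terms$op == "~~" & m3$terms$lhs == "f", ]
  expect_equal(fvar$fixed, 1)

  # MIMIC latent: single indicator loading fixed to 1, residual free
  m4 <- apply_identification(sem_model("scm =~ mass\nscm ~ tarsus + head"))
  expect_equal(m4$terms$fixed[m4$terms$op == "=~"], 1)
  mass_var <- m4$terms[m4$terms$op == "~~" & m4$terms$lhs == "mass", ]
  expect_true(is.na(mass_var$fixed))

  # composite: first weight fixed to 1, residual variance 0
  m5 <- apply_identification(sem_model("C <~ a + b + c\ny ~ C"))
  w <- m5$terms[m5$terms$op == "<~", ]
  expect_equal(w$fixed, c(1, NA, NA))
  expect_equal(m5$terms$fixed[m5$terms$op == "~~" & m5$terms$lhs == "C"], 0)

  # exogenous observed variables covary freely
  expect_true(any(m5$terms$op == "~~" & m5$terms$lhs == "a" & m5$terms$rhs == "b"))

  # latent with no indicators and no covariate regressions is an error
  m6 <- sem_model("f =~ x1\ny ~ x1")
  m6$terms <- m6$terms[m6$terms$op == "~", ]
  expect_error(apply_identification(m6), "no indicators")
})

test_that("identification is idempotent", {
  for (txt in c("f =~ x1 + x2 + x3",
                "C <~ a + b\ny ~ C",
                "scm =~ mass\nscm ~ tarsus + head + wing")) {
    m1 <- apply_identification(sem_model(txt))
    m2 <- apply_identification(m1)
    expect_equal(term_key_set(m1), term_key_set(m2), info = txt)
  }
})

test_that("serialize and re-parse is the identity on canonical models", {
  for (txt in c("f =~ x1 + x2 + x3\nf ~ z",
                "C <~ a + b + c\ny ~ C",
                "a ~~ b\na ~~ a")) {
    m1 <- apply_identification(sem_model(txt))
    m2 <- apply_identification(sem_model(serialize_model(m1)))
    expect_equal(term_key_set(m1), term_key_set(m2), info = txt)
    expect_equal(sort(m1$variables$name), sort(m2$variables$name))
  }
})

test_that("model degrees of freedom match hand counts", {
  # saturated observed block: p = 3, all moments free
  m_sat <- apply_identification(sem_model("a ~~ b\na ~~ c\nb ~~ c"))
  expect_equal(model_df(m_sat), 0L)

  # 1 factor, 3 indicators, first loading fixed:
  # 2 loadings + factor var + 3 residuals = 6 free vs 6 moments
  m1 <- apply_identification(sem_model("f =~ x1 + x2 + x3"))
  expect_equal(model_df(m1), 0L)

  # 1 factor, 2 indicators: 4 free vs 3 moments, under-identified
  m2 <- apply_identification(sem_model("f =~ x1 + x2"))
  expect_error(model_df(m2), "under-identified")

  # multi-group doubles both moments and (unconstrained) parameters
  m3 <- apply_identification(sem_model("f =~ x1 + x2 + x3", groups = "g"))
  expect_equal(model_df(m3, n_groups = 2L), 0L)
})
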