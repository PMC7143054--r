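test_that("expert model parses with the documented structure", {
  m <- udp_glcnac_expert_model()
  expect_equal(m$k, 6)
  expect_length(m$moieties, 4)
  expect_equal(m$capacity, 16)
  # uracil contributes three free parameters by sum-to-one
  uracil <- m$moieties[[4]]
  expect_length(uracil$counts, 4)
  expect_equal(sum(m$param_map[[4]] > 0), 3)
})

test_that("parse_model reads the JSON schema and validates it", {
  doc <- list(
    name = "expert",
    moieties = list(
      list(name = "glucose", states = list(
        list(label = "g0", isotope_count = 0),
        list(label = "g6", isotope_count = 6))),
      list(name = "ribose", states = list(
        list(label = "r0", isotope_count = 0),
        list(label = "r5", isotope_count = 5))),
      list(name = "acetyl", states = list(
        list(label = "a0", isotope_count = 0),
        list(label = "a2", isotope_count = 2))),
      list(name = "uracil", states = list(
        list(label = "u0", isotope_count = 0),
        list(label = "u1", isotope_count = 1),
        list(label = "u2", isotope_count = 2),
        list(label = "u3", isotope_count = 3)))))
  m <- parse_model(doc)
  expect_s3_class(m, "moiety_model")
  expect_equal(m$k, 6)

  # one sharing constraint merging two one-parameter moieties' labeled
  # states removes one free parameter
  doc$sharing <- list(list(c("glucose", "g6"), c("ribose", "r5")))
  expect_equal(parse_model(doc)$k, 5)

  # single moiety with two states: one parameter, capacity 1
  single <- parse_model(list(name = "s", moieties = list(
    list(name = "s", states = list(
      list(label = "s0", isotope_count = 0),
      list(label = "s1", isotope_count = 1))))))
  expect_equal(single$k, 1)
  expect_equal(single$capacity, 1)

  # schema violations name the offending field
  expect_error(parse_model(list(moieties = list())), "name")
  expect_error(parse_model(list(name = "x")), "moieties")
  doc_bad <- doc
  doc_bad$moieties[[1]]$states[[2]]$label <- "g0"
  expect_error(parse_model(doc_bad), "duplicate")
})

test_that("model JSON round-trips through write_model/parse_model", {
  m <- udp_glcnac_expert_model()
  m2 <- parse_model(write_model(m))
  expect_equal(m2$k, m$k)
  expect_equal(m2$capacity, m$capacity)
  expect_equal(m2$param_names, m$param_names)

  shared <- moiety_model("sh", list(
    list(name = "a", states = c(a0 = 0, a1 = 1)),
    list(name = "b", states = c(b0 = 0, b1 = 1))),
    sharing = list(list(c("a", "a1"), c("b", "b1"))))
  sh2 <- parse_model(write_model(shared))
  expect_equal(sh2$k, 1)
})

test_that("expand_parameters enforces sum-to-one and the clamp rule", {
  m <- udp_glcnac_expert_model()
  a <- expand_parameters(m, c(1, 1, 1, 0, 0, 0))
  expect_equal(unname(a$glucose), c(0, 1))
  expect_equal(unname(a$ribose), c(0, 1))
  expect_equal(unname(a$acetyl), c(0, 1))
  expect_equal(unname(a$uracil), c(1, 0, 0, 0))

  tri <- toy_three_state()
  expect_equal(unname(expand_parameters(tri, c(0.3, 0.2))$s),
               c(0.5, 0.3, 0.2))
  # free parameters summing above 1: dependent state clamps to 0 and the
  # moiety renormalizes by its sum
  over <- expand_parameters(tri, c(0.8, 0.6))
  expect_equal(unname(over$s), c(0, 0.8 / 1.4, 0.6 / 1.4))
  expect_equal(sum(over$s), 1)

  expect_error(expand_parameters(m, c(0.5, 0.5)), "6 free parameters")
  expect_error(expand_parameters(m, c(0.5, 0.5, 0.5, 0.5, 0.5, 1.5)),
               "\\[0, 1\\]")
})

test_that("shared states receive one common value", {
  shared <- moiety_model("sh", list(
    list(name = "a", states = c(a0 = 0, a1 = 1)),
    list(name = "b", states = c(b0 = 0, b1 = 1))),
    sharing = list(list(c("a", "a1"), c("b", "b1"))))
  expect_equal(shared$k, 1)
  a <- expand_parameters(shared, 0.3)
  expect_equal(unname(a$a), c(0.7, 0.3))
  expect_equal(unname(a$b), c(0.7, 0.3))
})

test_that("enumerate_combinations lists the full Cartesian product", {
  m <- udp_glcnac_expert_model()
  cmb <- enumerate_combinations(m)
  expect_equal(nrow(cmb), 32)               # 2*2*2*4
  expect_equal(max(cmb$isotope_content), 16)  # 6+5+2+3
  expect_equal(min(cmb$isotope_content), 0)

  two <- toy_two_moiety()
  cmb2 <- enumerate_combinations(two)
  expect_equal(nrow(cmb2), 4)
  expect_equal(sort(cmb2$isotope_content), c(0, 1, 1, 2))
})

test_that("calc_isotopologues matches hand-computed products", {
  two <- toy_two_moiety()
  # p = 0.4, q = 0.3: ((1-p)(1-q), p(1-q)+(1-p)q, pq)
  I <- calc_isotopologues(two, c(0.4, 0.3))
  expect_equal(unname(I), c(0.42, 0.46, 0.12), tolerance = 1e-12)

  # unlabeled limit: all mass at x = 0
  m <- udp_glcnac_expert_model()
  I0 <- calc_isotopologues(m, rep(0, 6))
  expect_equal(unname(I0[1]), 1)
  expect_equal(sum(I0[-1]), 0)

  # unreachable isotope contents are exactly zero, as found by enumeration
  reach <- sort(unique(enumerate_combinations(m)$isotope_content))
  unreach <- setdiff(0:16, reach)
  a <- expand_parameters(m, c(0.3, 0.3, 0.3, 0.2, 0.2, 0.2))
  I <- calc_isotopologues(m, a)
  expect_true(all(I[unreach + 1L] == 0))
  expect_true(all(I[reach + 1L] > 0))
})

test_that("intensity vector matches the brute-force oracle on random models", {
  set.seed(1)
  for (i in 1:200) {
    model <- random_model()
    free <- random_free(model)
    a <- expand_parameters(model, free)
    expect_equal(unname(calc_isotopologues(model, a)),
                 brute_force_isotopologues(model, a),
                 tolerance = 1e-12)
  }
})

test_that("normalization, permutation invariance, degenerate sharpness", {
  set.seed(2)
  for (i in 1:25) {
    model <- random_model()
    a <- expand_parameters(model, random_free(model))
    I <- calc_isotopologues(model, a)
    expect_equal(sum(I), 1, tolerance = 1e-10)
  }
  # moiety order does not matter
  m1 <- moiety_model("fwd", list(
    list(name = "a", states = c(a0 = 0, a2 = 2)),
    list(name = "b", states = c(b0 = 0, b1 = 1, b3 = 3))))
  m2 <- moiety_model("rev", list(
    list(name = "b", states = c(b0 = 0, b1 = 1, b3 = 3)),
    list(name = "a", states = c(a0 = 0, a2 = 2))))
  I1 <- calc_isotopologues(m1, c(0.4, 0.2, 0.3))
  I2 <- calc_isotopologues(m2, c(0.2, 0.3, 0.4))
  expect_equal(unname(I1), unname(I2), tolerance = 1e-14)
  # every moiety pinned to one state concentrates all mass on one x
  pin <- calc_isotopologues(m1, c(1, 0, 1))
  expect_equal(sum(pin == 1), 1)
  expect_equal(unname(pin["5"]), 1)
})

test_that("invalid model structures are rejected", {
  expect_error(moiety_model("x", list(
    list(name = "a", states = c(a0 = 0)))), "at least 2 states")
  expect_error(moiety_model("x", list(
    list(name = "a", states = c(a0 = 0, a1 = 0)))), "distinct")
  expect_error(moiety_model("x", list(
    list(name = "a", states = c(a0 = -1, a1 = 1)))), "non-negative")
  # sharing with unknown member or dependent state
  expect_error(moiety_model("x", list(
    list(name = "a", states = c(a0 = 0, a1 = 1)),
    list(name = "b", states = c(b0 = 0, b1 = 1))),
    sharing = list(list(c("a", "a1"), c("c", "c1")))), "unknown moiety")
  expect_error(moiety_model("x", list(
    list(name = "a", states = c(a0 = 0, a1 = 1)),
    list(name = "b", states = c(b0 = 0, b1 = 1))),
    sharing = list(list(c("a", "a0"), c("b", "b1")))), "dependent")
})
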