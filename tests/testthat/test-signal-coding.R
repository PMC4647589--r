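test_that("classify_compound places known compounds in their biosynthetic class", {
  cases <- c(
    "pentacosane" = "linear alkane",
    "3-methylpentacosane" = "branched alkane",
    "(Z)-9-tricosene" = "alkene",
    "6,9-tricosadiene" = "alkadiene",
    "hexadecanal" = "aldehyde",
    "hexacosanol" = "alcohol",
    "hexadecanoic acid" = "fatty acid",
    "(Z)-9-octadecenoic acid" = "fatty acid",
    "9-ODA" = "keto acid",
    "9-oxo-decenoic acid" = "keto acid",
    "decyl decanoate" = "ester",
    "hexadecanoic acid methyl ester" = "ester",
    "squalene" = "terpene",
    "geraniol" = "terpene alcohol",
    "hexadecanolide" = "lactone"
  )
  expect_equal(classify_compound(names(cases), quiet = TRUE), unname(cases))
})

test_that("unknowns are surfaced, never guessed or dropped", {
  expect_message(out <- classify_compound(c("mystery-42", "pentacosane")),
                 "unclassifiable")
  expect_equal(out, c("unknown", "linear alkane"))
})

test_that("descriptor rules resolve conflicts by end-group chemistry", {
  # unsaturated acid is a fatty acid, not an alkene
  rec <- compound_record(chain_length = 18, saturation = "ene",
                         functional_group = "acid")
  expect_equal(classify_compound(rec), "fatty acid")
  # methyl-branched alkene is an alkene
  rec <- compound_record(chain_length = 25, saturation = "ene",
                         functional_group = "hydrocarbon", methyl_branches = 1)
  expect_equal(classify_compound(rec), "alkene")
  rec <- compound_record(chain_length = 25, saturation = "none",
                         functional_group = "hydrocarbon", methyl_branches = 2)
  expect_equal(classify_compound(rec), "branched alkane")
  expect_error(compound_record(), "name or a functional-group")
})

test_that("qualitative rule: present in fertile caste, absent in workers", {
  prof <- make_profile(fertile = rep(10, 5), nonfertile = rep(0, 5))
  expect_true(call_fertility_linked(prof, "pentacosane"))
  # identical distributions are not fertility-linked
  prof2 <- make_profile(fertile = c(3, 4, 5, 6), nonfertile = c(3, 4, 5, 6))
  expect_false(call_fertility_linked(prof2, "pentacosane"))
  # absent from both groups: FALSE with a warning
  expect_warning(
    expect_false(call_fertility_linked(prof, "nonexistent compound")),
    "not detected")
  # single-individual groups fall back to the qualitative rule, flagged
  prof3 <- make_profile(fertile = 10, nonfertile = 1)
  expect_warning(expect_false(call_fertility_linked(prof3, "pentacosane")),
                 "single-individual")
  prof4 <- make_profile(fertile = 10, nonfertile = 0)
  expect_true(call_fertility_linked(prof4, "pentacosane"))
})

test_that("the call is invariant to global rescaling of abundances", {
  set.seed(71)
  for (i in 1:10) {
    f <- rlnorm(8, log(100) + sample(c(0, 1.4), 1), 0.75)
    n <- rlnorm(8, log(100), 0.75)
    base <- call_fertility_linked(make_profile(fertile = f, nonfertile = n),
                                  "pentacosane")
    scaled <- call_fertility_linked(
      make_profile(fertile = f * 1e6, nonfertile = n * 1e6), "pentacosane")
    expect_identical(base, scaled)
  }
})

test_that("default criterion detects 4-fold overproduction and rejects the null", {
  set.seed(2024)
  nrep <- 150
  hit4 <- hit1 <- 0
  for (r in seq_len(nrep)) {
    n <- rlnorm(8, log(100), 0.75)
    f4 <- rlnorm(8, log(400), 0.75)
    f1 <- rlnorm(8, log(100), 0.75)
    if (call_fertility_linked(make_profile(fertile = f4, nonfertile = n),
                              "pentacosane")) hit4 <- hit4 + 1
    if (call_fertility_linked(make_profile(fertile = f1, nonfertile = n),
                              "pentacosane")) hit1 <- hit1 + 1
  }
  expect_gte(hit4 / nrep, 0.90)
  expect_lte(hit1 / nrep, 0.10)
})

test_that("build_character_matrix codes presence, absence and missing correctly", {
  # species whose only fertility-linked compound is pentacosane:
  # linear alkane = 1, other assayed classes 0, unassayed classes ?
  prof <- rbind(
    make_profile(fertile = rep(10, 4), nonfertile = rep(0, 4),
                 compound = "pentacosane"),
    make_profile(fertile = rep(5, 4), nonfertile = rep(5, 4),
                 compound = "squalene")
  )
  m <- build_character_matrix(prof)
  expect_equal(m["sp", "linear alkane"], 1)
  expect_equal(m["sp", "terpene"], 0)
  expect_true(is.na(m["sp", "ester"])) # esters never assayed
  # empty input: 0 x 12 matrix
  m0 <- build_character_matrix(prof[0, ])
  expect_equal(dim(m0), c(0L, 12L))
})

test_that("coding recovers the generator's truth exactly in the qualitative regime", {
  cfg <- simulation_config(n_tips = 6, fold_change = Inf, n_individuals = 5,
                           seed = 42)
  sim <- simulate_chem_profiles(cfg)
  m <- build_character_matrix(sim$profiles)
  expect_equal(m[rownames(sim$truth), colnames(sim$truth)], sim$truth)
})

test_that("matrix coding is order-independent in its cells", {
  cfg <- simulation_config(n_tips = 5, fold_change = Inf, n_individuals = 4,
                           seed = 7)
  sim <- simulate_chem_profiles(cfg)
  m1 <- build_character_matrix(sim$profiles)
  set.seed(1)
  perm <- sim$profiles[sample(nrow(sim$profiles)), ]
  m2 <- build_character_matrix(perm)
  expect_equal(m2[rownames(m1), colnames(m1)], m1, ignore_attr = TRUE)
})

test_that("inconsistent profiles are rejected", {
  prof <- make_profile(fertile = 1:3, nonfertile = 1:3)
  bad <- prof
  bad$group[1] <- "mature_female" # eusocial species with solitary group label
  expect_error(validate_profiles(bad), "inconsistent")
  bad2 <- rbind(prof, transform(prof, sociality = "solitary",
                                group = sub("queen", "mature_female",
                                            sub("worker", "virgin_female", group))))
  expect_error(validate_profiles(bad2), "conflicting sociality")
})
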