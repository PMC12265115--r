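test_that("synchronous stepping updates all nodes at once, inputs frozen", {
  m <- logicalModel(c(A = "A"))
  expect_equal(syncStep(m, c(A = 1)), c(A = 1))

  m <- logicalModel(c(A = "B", B = "A"))
  expect_equal(syncStep(m, c(A = 0, B = 1)), c(A = 1, B = 0))

  m <- logicalModel(c(I = "INPUT", A = "!I"))
  expect_equal(syncStep(m, c(I = 1, A = 1)), c(I = 1, A = 0))

  # applying the step twice equals composing the map with itself
  m <- logicalModel(c(A = "B", B = "A & !C", C = "A | C"))
  for (code in 0:7) {
    s <- decodeState(code, c("A", "B", "C"))[1, ]
    twice <- syncStep(m, syncStep(m, s))
    composed <- syncStep(m, s)
    composed <- syncStep(m, composed)
    expect_equal(twice, composed)
  }
})

test_that("asynchronous successors flip exactly one unstable node", {
  m <- logicalModel(c(A = "A"))
  expect_length(asyncSuccessors(m, c(A = 1)), 0)

  m <- logicalModel(c(A = "B", B = "A"))
  succ <- asyncSuccessors(m, c(A = 0, B = 1))
  keys <- sort(vapply(succ, paste, "", collapse = ""))
  expect_equal(keys, c("00", "11"))
  expect_length(asyncSuccessors(m, c(A = 0, B = 0)), 0)
  expect_length(asyncSuccessors(m, c(A = 1, B = 1)), 0)
  expect_length(asyncSuccessors(m, c(A = 1, B = 0)), 2)
})

test_that("mutual activation: sync gives 00, 11 and the {01,10} cycle; async drops the cycle", {
  m <- logicalModel(c(A = "B", B = "A"))
  s <- attractors(m, "synchronous")
  expect_length(s, 3)
  expect_equal(attractorKeys(s), c("0", "1,2", "3"))
  kinds <- vapply(s@attractors, function(a) a@kind, "")
  expect_equal(sort(kinds), c("cyclic", "fixed_point", "fixed_point"))

  a <- attractors(m, "asynchronous")
  expect_length(a, 2)
  expect_equal(attractorKeys(a), c("0", "3"))
  expect_true(all(vapply(a@attractors, function(x) x@kind, "") ==
                  "fixed_point"))
})

test_that("negative feedback loop: one 4-state asynchronous cyclic attractor", {
  m <- logicalModel(c(A = "!B", B = "A"))
  a <- attractors(m, "asynchronous")
  expect_length(a, 1)
  expect_equal(a[[1]]@kind, "cyclic")
  expect_equal(nrow(a[[1]]@states), 4)
})

test_that("attractors carry labels, canonical order, and input context", {
  m <- logicalModel(c(I = "INPUT", A = "I"), modelId = "Q")
  a <- attractors(m, "asynchronous")
  expect_length(a, 2)  # one fixed point per input value
  expect_equal(vapply(a@attractors, function(x) x@label, ""),
               c("Q1", "Q2"))
  ctx <- vapply(a@attractors, function(x) x@inputContext[["I"]], integer(1))
  expect_setequal(ctx, c(0L, 1L))
  tab <- attractorTable(a)
  expect_true(all(c("attractor", "state", "kind", "scheme", "inputs",
                    "A", "I") %in% names(tab)))
  expect_equal(nrow(tab), 2)
})

test_that("exact mode refuses oversized models; sampling recovers attractors", {
  m <- randomModel(8, kRegulators = 2, seed = 5)
  expect_error(attractors(m, "synchronous", cap = 6), "cap")
  exact <- attractors(m, "synchronous")
  set.seed(1)
  sampled <- attractors(m, "synchronous", mode = "sampling", nStarts = 200)
  expect_equal(sampled@completeness, "unknown")
  expect_true(all(attractorKeys(sampled) %in% attractorKeys(exact)))
  expect_equal(attractorKeys(sampled), attractorKeys(exact))

  exactA <- attractors(m, "asynchronous")
  set.seed(2)
  sampledA <- attractors(m, "asynchronous", mode = "sampling", nStarts = 60,
                         maxSteps = 200)
  expect_true(all(attractorKeys(sampledA) %in% attractorKeys(exactA)))
})

test_that("fixed points agree between schemes on random models", {
  for (seed in 1:20) {
    m <- randomModel(sample(3:7, 1), kRegulators = 3, seed = seed,
                     pInput = 0.15)
    fpS <- Filter(function(a) a@kind == "fixed_point",
                  attractors(m, "synchronous")@attractors)
    fpA <- Filter(function(a) a@kind == "fixed_point",
                  attractors(m, "asynchronous")@attractors)
    nodes <- sort(nodeIds(m))
    keyOf <- function(a) paste(encodeState(a@states, nodes), collapse = ",")
    expect_equal(sort(vapply(fpS, keyOf, "")), sort(vapply(fpA, keyOf, "")))
  }
})

test_that("synchronous basins partition the state space", {
  m <- randomModel(6, kRegulators = 3, seed = 3)
  nodes <- sort(nodeIds(m))
  aset <- attractors(m, "synchronous")
  akeys <- attractorKeys(aset)
  reached <- character(64)
  for (code in 0:63) {
    st <- decodeState(code, nodes)[1, ]
    seen <- integer(0)
    repeat {
      c2 <- encodeState(st, nodes)
      if (c2 %in% seen) break
      seen <- c(seen, c2)
      st[] <- as.integer(syncStep(m, st))
    }
    cyc <- seen[which(seen == encodeState(st, nodes))[1]:length(seen)]
    hit <- which(akeys == paste(sort(cyc), collapse = ","))
    expect_length(hit, 1)
    reached[code + 1] <- akeys[hit]
  }
  expect_true(all(nzchar(reached)))
})

test_that("activation frequency follows the declared weighting", {
  m <- logicalModel(c(A = "B", B = "A"))
  s <- attractors(m, "synchronous")
  # attractors {00}, {11}, cycle {01,10}: uniform per attractor
  f <- activationFrequency(s, "uniform_attractor")
  expect_equal(unname(f["A"]), (0 + 1 + 0.5) / 3)
  f2 <- activationFrequency(s, "uniform_state")
  expect_equal(unname(f2["A"]), 0.5)

  one <- attractors(logicalModel(c(A = "1", B = "!A")), "asynchronous")
  expect_length(one, 1)
  expect_equal(activationFrequency(one), c(A = 1, B = 0))
})

test_that("clamping replaces rules by constants and reshapes attractors", {
  m <- logicalModel(c(A = "B", B = "A"))
  lof <- clampModel(m, data.frame(gene = "A", effect = "LoF"))
  expect_equal(ruleToString(nodeRule(lof, "A")), "0")
  a <- attractors(lof, "asynchronous")
  expect_length(a, 1)
  expect_equal(unname(a[[1]]@states[1, ]), c(0L, 0L))

  expect_equal(nodeIds(clampModel(m, data.frame(gene = character(0),
                                                effect = character(0)))),
               nodeIds(m))

  gof <- clampModel(m, data.frame(gene = "A", effect = "GoF"))
  ag <- attractors(gof, "asynchronous")
  expect_true(all(vapply(ag@attractors, function(x) all(x@states[, "A"] == 1),
                         logical(1))))
  expect_equal(unname(activationFrequency(ag)["A"]), 1)

  expect_error(clampModel(m, data.frame(gene = "ZZ", effect = "LoF")), "ZZ")
  expect_error(clampModel(m, data.frame(gene = "A", effect = "up")), "GoF")
})

test_that("mutation profile TSVs split per patient", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgene\teffect",
               "p1\tFLT3\tGoF", "p1\tNPM1\tLoF", "p2\tFLT3\tGoF",
               "p3\t\t"), f)
  profs <- readMutationProfiles(f)
  expect_length(profs, 3)
  expect_equal(nrow(profs$p1), 2)
  expect_equal(nrow(profs$p3), 0)
})

test_that("state encoding and decoding are inverse bijections", {
  nodes <- c("A", "B", "C", "D")
  codes <- 0:15
  m <- decodeState(codes, nodes)
  expect_equal(encodeState(m, nodes), as.numeric(codes))
  expect_equal(dim(m), c(16L, 4L))
})
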