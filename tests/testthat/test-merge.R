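test_that("combiners match their pointwise definitions on worked cases", {
  # OR of ["A", "!B"] equals A | !B on all 4 states
  vars <- c("A", "B")
  r <- lapply(c("A", "!B"), parseRule)
  expect_equal(pkgColumn(combineOR(r), vars),
               oracleMergedColumn(c("A", "!B"), vars, "OR"))
  expect_equal(pkgColumn(combineAND(r), vars),
               oracleMergedColumn(c("A", "!B"), vars, "AND"))

  # single-rule combinations are the identity
  one <- list(parseRule("A"))
  expect_true(exprsEquivalent(combineOR(one), parseRule("A")))
  expect_true(exprsEquivalent(combineAND(one), parseRule("A")))

  # absorption and contradiction
  expect_true(exprsEquivalent(combineOR(lapply(c("A", "A & B"), parseRule)),
                              parseRule("A")))
  expect_true(exprsEquivalent(combineAND(lapply(c("A", "!A"), parseRule)),
                              bConst(0)))
})

test_that("Inhibitor Wins zeroes states with any pooled inhibitor active", {
  # rules ["A", "!B"]: B inhibits, so the merged rule is 0 whenever B=1,
  # else A | !B = 1; i.e. equivalent to !B
  r <- lapply(c("A", "!B"), parseRule)
  iw <- combineIW(r)
  expect_true(exprsEquivalent(iw, parseRule("!B")))
  expect_equal(attr(iw, "inhibitors"), "B")
  expect_equal(pkgColumn(iw, c("A", "B")),
               oracleMergedColumn(c("A", "!B"), c("A", "B"), "IW"))

  # no inhibitors anywhere: IW reduces to OR
  r <- lapply(c("A", "B"), parseRule)
  expect_true(exprsEquivalent(combineIW(r), parseRule("A | B")))

  # ["A & !C", "B"]: C inhibits; result is !C & (A | B) on all 8 states
  r <- lapply(c("A & !C", "B"), parseRule)
  iw <- combineIW(r)
  expect_true(exprsEquivalent(iw, parseRule("!C & (A | B)")))
  expect_equal(pkgColumn(iw, c("A", "B", "C")),
               oracleMergedColumn(c("A & !C", "B"), c("A", "B", "C"), "IW"))
})

test_that("dual-signed regulators are treated as inhibitors with a warning", {
  r <- lapply(c("A & !B | !A & B", "A"), parseRule)
  expect_warning(iw <- combineIW(r), "dual")
  expect_setequal(attr(iw, "inhibitors"), c("A", "B"))
})

test_that("disjoint models merge to their union with rules unchanged", {
  a <- logicalModel(c(A = "INPUT", B = "A"), modelId = "a")
  b <- logicalModel(c(X = "INPUT", Y = "X & !Y"), modelId = "b")
  res <- mergeModels(list(a, b))
  expect_setequal(nodeIds(res$model), c("A", "B", "X", "Y"))
  expect_true(exprsEquivalent(nodeRule(res$model, "Y"), nodeRule(b, "Y")))
  expect_true(all(res$report$strategy %in% c("single", "input")))
})

test_that("self-merge under OR and AND preserves rules and fixed points", {
  for (seed in 1:10) {
    m <- randomModel(6, kRegulators = 3, seed = seed, pInput = 0.2)
    for (strat in c("OR", "AND")) {
      res <- mergeModels(list(m, m), mergeConfig(strat))
      for (id in setdiff(nodeIds(m), inputNodes(m)))
        expect_true(exprsEquivalent(nodeRule(res$model, id),
                                    nodeRule(m, id)))
      fpOrig <- attractorKeys(attractors(m, "asynchronous"))
      fpMerged <- attractorKeys(attractors(res$model, "asynchronous"))
      expect_equal(fpMerged, fpOrig)
    }
  }
})

test_that("merging is commutative in the model list up to equivalence", {
  set.seed(99)
  for (seed in 1:10) {
    p <- overlappingPair(nA = 5, nB = 6, overlap = 3, divergence = 0.5,
                         seed = seed)
    for (strat in c("OR", "AND", "IW")) {
      ab <- mergeModels(list(p$a, p$b), mergeConfig(strat))$model
      ba <- mergeModels(list(p$b, p$a), mergeConfig(strat))$model
      expect_setequal(nodeIds(ab), nodeIds(ba))
      for (id in setdiff(nodeIds(ab), inputNodes(ab)))
        expect_true(exprsEquivalent(nodeRule(ab, id), nodeRule(ba, id)))
    }
  }
})

test_that("three-way merging equals the direct n-ary formula", {
  rules <- c("A", "!B", "A & B")
  ms <- lapply(seq_along(rules), function(i)
    logicalModel(stats::setNames(c("INPUT", "INPUT", rules[i]),
                                 c("A", "B", "T")),
                 modelId = paste0("m", i)))
  vars <- c("A", "B")
  for (strat in c("OR", "AND", "IW")) {
    merged <- mergeModels(ms, mergeConfig(strat))$model
    expect_equal(pkgColumn(nodeRule(merged, "T"), vars),
                 oracleMergedColumn(rules, vars, strat))
  }
})

test_that("INPUT-vs-regulated conflicts resolve to the regulated rule", {
  a <- logicalModel(c(A = "INPUT", B = "A"), modelId = "a")
  b <- logicalModel(c(A = "!B", B = "INPUT"), modelId = "b")
  res <- mergeModels(list(a, b))
  expect_true(exprsEquivalent(nodeRule(res$model, "A"), parseRule("!B")))
  expect_true(exprsEquivalent(nodeRule(res$model, "B"), parseRule("A")))
  expect_true(all(res$report$input_conflict[res$report$node %in% c("A", "B")]))
  expect_equal(res$report$strategy[res$report$node == "A"], "single")
})

test_that("per-node overrides apply and unknown keys are rejected", {
  a <- logicalModel(c(X = "INPUT", T = "X"), modelId = "a")
  b <- logicalModel(c(Y = "INPUT", T = "!Y"), modelId = "b")
  cfg <- mergeConfig("OR", perNode = c(T = "AND"))
  res <- mergeModels(list(a, b), cfg)
  expect_true(exprsEquivalent(nodeRule(res$model, "T"),
                              parseRule("X & !Y")))
  expect_equal(res$report$strategy[res$report$node == "T"], "AND")
  expect_error(mergeModels(list(a, b), mergeConfig("OR", c(NOPE = "IW"))),
               "NOPE")
})

test_that("merge configuration reads from JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"default": "or", "per_node": {"TP53": "IW"},
               "inhibitor_detection": "semantic"}', f)
  cfg <- readMergeConfig(f)
  expect_equal(cfg@defaultStrategy, "OR")
  expect_equal(unname(cfg@perNode["TP53"]), "IW")
  expect_error(mergeConfig("XOR"), "OR, AND, IW")
})

test_that("IW and AND never exceed OR pointwise", {
  set.seed(17)
  for (i in 1:30) {
    vars <- c("A", "B", "C")
    texts <- replicate(2, randomRuleText(vars, depth = 2))
    rules <- lapply(texts, parseRule)
    co <- pkgColumn(combineOR(rules), vars)
    ca <- pkgColumn(combineAND(rules), vars)
    ci <- pkgColumn(suppressWarnings(combineIW(rules)), vars)
    expect_true(all(ci <= co))
    expect_true(all(ca <= co))
  }
})

test_that("AND <= IW <= OR holds for inhibitor-dominant template rules", {
  # for rules of the form (OR of activators) & !(OR of inhibitors), an
  # active inhibitor forces its own rule off, so the full ordering holds
  set.seed(23)
  vars <- c("A", "B", "C", "D")
  for (i in 1:20) {
    mkTemplate <- function() {
      act <- sample(vars, sample(1:2, 1))
      inh <- sample(setdiff(vars, act), sample(0:2, 1))
      a <- do.call(bOr, lapply(act, bVar))
      if (length(inh) == 0) a
      else bAnd(a, bNot(do.call(bOr, lapply(inh, bVar))))
    }
    rules <- list(mkTemplate(), mkTemplate())
    co <- pkgColumn(combineOR(rules), vars)
    ca <- pkgColumn(combineAND(rules), vars)
    ci <- pkgColumn(suppressWarnings(combineIW(rules)), vars)
    expect_true(all(ca <= ci))
    expect_true(all(ci <= co))
  }
})

test_that("an active inhibitor zeroes IW even where every source rule is on", {
  # the hard-dominance semantics: rules (A | B) and (!A | B) both evaluate
  # to 1 at A=1,B=1, yet A inhibits the second rule, so IW forces 0 there
  # while AND stays 1 -- inhibition overrides unanimous activation
  rules <- lapply(c("A | B", "!A | B"), parseRule)
  iw <- combineIW(rules)
  expect_equal(attr(iw, "inhibitors"), "A")
  st <- c(A = 1, B = 1)
  expect_equal(evalRule(iw, st), 0L)
  expect_equal(evalRule(combineAND(rules), st), 1L)
})
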