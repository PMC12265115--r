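test_that("parser builds trees with ! > & > | precedence", {
  e <- parseRule("A & B")
  expect_equal(e$op, "and")
  expect_equal(evalRule(e, c(A = 1, B = 1)), 1L)
  expect_equal(evalRule(e, c(A = 1, B = 0)), 0L)

  expect_equal(parseRule("A")$op, "var")
  expect_equal(evalRule(parseRule("A"), c(A = 0)), 0L)

  # A & !B | C parses as (A & !B) | C: verify the full 8-row truth table
  # against an evaluator going through R's own parser
  e <- parseRule("A & !B | C")
  expect_equal(e$op, "or")
  vars <- c("A", "B", "C")
  expect_equal(pkgColumn(e, vars), oracleTruthTable("A & !B | C", vars))

  # parentheses override precedence
  expect_equal(pkgColumn(parseRule("A & (B | C)"), vars),
               oracleTruthTable("A & (B | C)", vars))
})

test_that("parser rejects malformed input with a position", {
  expect_error(parseRule(""), "empty")
  expect_error(parseRule("   "), "empty")
  expect_error(parseRule("A &"), "position")
  expect_error(parseRule("A @ B"), "position 3")
  expect_error(parseRule("(A | B"), "\\)")
  expect_error(parseRule("A B"), "trailing")
})

test_that("constants 0 and 1 are part of the grammar", {
  expect_equal(evalRule(parseRule("0"), c()), 0L)
  expect_equal(evalRule(parseRule("1 & A"), c(A = 0)), 0L)
  expect_equal(evalRule(parseRule("0 | A"), c(A = 1)), 1L)
})

test_that("evaluation enforces a total assignment and Boolean output", {
  e <- bAnd(bVar("A"), bNot(bVar("B")))
  expect_equal(evalRule(e, c(A = 1, B = 0)), 1L)
  expect_equal(evalRule(bOr(bVar("A"), bNot(bVar("A"))), c(A = 0)), 1L)
  expect_equal(evalRule(bOr(bVar("A"), bNot(bVar("A"))), c(A = 1)), 1L)
  expect_equal(evalRule(bConst(0), c()), 0L)
  expect_error(evalRule(e, c(A = 1)), "'B'.*not assigned")
})

test_that("And/Or children stay flattened", {
  e <- bAnd(bAnd(bVar("A"), bVar("B")), bVar("C"))
  expect_length(e$children, 3)
  expect_true(all(vapply(e$children, function(k) k$op, "") == "var"))
  e2 <- parseRule("A | B | C")
  expect_length(e2$children, 3)
})

test_that("semantic support excludes absorbed and cancelled variables", {
  expect_setequal(exprSupport(parseRule("A & B")), c("A", "B"))
  expect_length(exprSupport(parseRule("A & !A")), 0)   # contradiction
  expect_equal(exprSupport(parseRule("A | A & B")), "A")  # B absorbed
  expect_length(exprSupport(bConst(1)), 0)
})

test_that("support is a subset of the syntactic variables", {
  set.seed(42)
  vars <- c("A", "B", "C", "D")
  for (i in 1:50) {
    tx <- randomRuleText(vars)
    e <- parseRule(tx)
    expect_true(all(exprSupport(e) %in% all.vars(parse(text = tx)[[1]])))
  }
})

test_that("sign inference classifies activator, inhibitor, dual, none", {
  s <- inferSigns(parseRule("!B"), "T")
  expect_equal(s$sign, "inhibitor")
  expect_equal(s$regulator, "B")

  s <- inferSigns(parseRule("A & !B"), "T")
  expect_equal(s$sign[s$regulator == "A"], "activator")
  expect_equal(s$sign[s$regulator == "B"], "inhibitor")

  # XOR: both regulators dual
  s <- inferSigns(parseRule("A & !B | !A & B"), "T")
  expect_equal(s$sign, c("dual", "dual"))

  # absorbed regulator has no effect
  s <- inferSigns(parseRule("A | A & B"), "T")
  expect_equal(s$sign[s$regulator == "B"], "none")
})

test_that("sign inference recovers the signs of known literal structure", {
  set.seed(7)
  vars <- sprintf("V%d", 1:6)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    regs <- sample(vars, k)
    neg <- stats::runif(k) < 0.5
    lits <- mapply(function(r, n) if (n) paste0("!", r) else r, regs, neg)
    e <- parseRule(paste(lits, collapse = " & "))
    s <- inferSigns(e, "T")
    expect_equal(s$sign[match(regs, s$regulator)],
                 ifelse(neg, "inhibitor", "activator"))
  }
})

test_that("sign inference agrees with the brute-force flip oracle", {
  set.seed(11)
  vars <- c("A", "B", "C")
  for (i in 1:40) {
    tx <- randomRuleText(vars)
    present <- all.vars(parse(text = tx)[[1]])
    s <- inferSigns(parseRule(tx), "T")
    o <- oracleSigns(tx, present)
    expect_equal(stats::setNames(s$sign, s$regulator)[present], o[present])
  }
})

test_that("the cap error points at the syntactic fallback, which works", {
  big <- paste(sprintf("V%d", 1:18), collapse = " & ")
  expect_error(inferSigns(parseRule(big), "T", cap = 16), "syntactic")
  s <- inferSigns(parseRule("A & !B & !B"), "T", method = "syntactic")
  expect_equal(s$sign[s$regulator == "A"], "activator")
  expect_equal(s$sign[s$regulator == "B"], "inhibitor")
  s <- inferSigns(parseRule("A & !A"), "T", method = "syntactic")
  expect_equal(s$sign, "dual")  # syntactic view: appears in both polarities
})

test_that("equivalence checking is exhaustive over the union support", {
  expect_true(exprsEquivalent(parseRule("A | A"), parseRule("A")))
  expect_true(exprsEquivalent(parseRule("A & B"), parseRule("B & A")))
  expect_false(exprsEquivalent(parseRule("A | !B"), parseRule("!B")))
  expect_error(
    exprsEquivalent(parseRule(paste(sprintf("W%d", 1:21), collapse = " | ")),
                    bConst(0)),
    "cap")
})

test_that("serialize-parse round trip preserves equivalence (1000 cases)", {
  set.seed(123)
  vars <- c("A", "B", "C", "D", "E")
  for (i in 1:1000) {
    e <- parseRule(randomRuleText(vars))
    e2 <- parseRule(ruleToString(e))
    expect_true(exprsEquivalent(e, e2))
  }
})

test_that("serialization emits minimal parentheses with the same precedence", {
  expect_equal(ruleToString(parseRule("(A & B) | C")), "A & B | C")
  expect_equal(ruleToString(parseRule("A & (B | C)")), "A & (B | C)")
  expect_equal(ruleToString(parseRule("!(A | B)")), "!(A | B)")
  expect_equal(ruleToString(parseRule("!A & B")), "!A & B")
})
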