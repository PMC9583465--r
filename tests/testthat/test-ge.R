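# Brute-force derivation oracle for tiny grammars: expands the leftmost
# non-terminal, consuming codons (mod #productions) only at rules with
# two or more productions, without wrapping (genomes here are sized to
# need none).
oracle_derive <- function(genome, rules, start) {
  sentence <- list(list(type = "nt", value = start))
  used <- 0L
  for (step in 1:200) {
    i <- Position(function(t) t$type == "nt", sentence)
    if (is.na(i)) break
    prods <- rules[[sentence[[i]]$value]]
    choice <- if (length(prods) >= 2L) {
      used <- used + 1L
      if (used > length(genome)) return(NULL)
      (genome[used] %% length(prods)) + 1L
    } else 1L
    sentence <- append(sentence[-i], prods[[choice]], after = i - 1L)
  }
  if (any(vapply(sentence, `[[`, "", "type") == "nt")) return(NULL)
  paste(vapply(sentence, `[[`, "", "value"), collapse = "")
}

toy_grammar_text <- c(
  "<e> ::= f(<e>) | <t>",
  "<t> ::= a | b"
)
# token form of the same grammar for the oracle
toy_rules <- list(
  "<e>" = list(list(list(type = "t", value = "f("),
                    list(type = "nt", value = "<e>"),
                    list(type = "t", value = ")")),
               list(list(type = "nt", value = "<t>"))),
  "<t>" = list(list(list(type = "t", value = "a")),
               list(list(type = "t", value = "b")))
)

test_that("mapping matches exhaustive hand derivation on a toy grammar", {
  g <- read_grammar(text = toy_grammar_text)
  # all 16 genomes over codons {0, 1} of length 4
  combos <- expand.grid(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  for (r in seq_len(nrow(combos))) {
    genome <- as.integer(combos[r, ])
    got <- map_genotype(genome, g, wrap_limit = 0L, depth_cap = 10L,
                        dialect = NULL)
    want <- oracle_derive(genome, toy_rules, "<e>")
    expect_identical(got, want)
  }
  # a hand-worked case: 0 -> f(<e>), 1 -> <t>, 0 -> a
  expect_identical(map_genotype(c(0L, 1L, 0L), g, dialect = NULL), "f(a)")
})

test_that("single-production rules consume no codons", {
  g <- read_grammar(text = c("<s> ::= x(<a>,<a>)", "<a> ::= p | q"))
  # only <a> consumes: two codons decide everything
  expect_identical(map_genotype(c(0L, 1L), g, dialect = NULL), "x(p,q)")
  # a grammar with one production everywhere ignores the genome entirely
  g1 <- read_grammar(text = c("<s> ::= k(<a>)", "<a> ::= z"))
  for (genome in list(5L, c(200L, 13L), 0:9))
    expect_identical(map_genotype(genome, g1, dialect = NULL), "k(z)")
})

test_that("the codon stream wraps and the budget bounds the derivation", {
  g <- read_grammar(text = toy_grammar_text)
  # single codon 0 keeps choosing f(<e>): wrapping allows 1 + wrap_limit
  # consumptions before the mapping is declared invalid
  expect_null(map_genotype(0L, g, wrap_limit = 3L, dialect = NULL))
  # codon 0 then 1,0 terminates within one wrap: f(<e>) -> <t> -> a
  expect_identical(map_genotype(c(0L, 1L, 0L), g, wrap_limit = 0L,
                                dialect = NULL), "f(a)")
  # depth cap: 0,0,0,...,1,0 needs depth > cap
  deep <- c(rep(0L, 6), 1L, 0L)
  expect_identical(map_genotype(deep, g, depth_cap = 12L, dialect = NULL),
                   "f(f(f(f(f(f(a))))))")
  expect_null(map_genotype(deep, g, depth_cap = 3L, dialect = NULL))
})

test_that("mapping is a pure function of genome and grammar", {
  g <- bundled_grammar("arithmetic")
  set.seed(14)
  for (i in 1:50) {
    genome <- sample(0:255, 40, replace = TRUE)
    a <- map_genotype(genome, g, dialect = "arithmetic")
    b <- map_genotype(genome, g, dialect = "arithmetic")
    if (is.null(a)) {
      expect_null(b)
    } else {
      expect_identical(render_tree(a), render_tree(b))
      expect_true(validate_tree(a))
    }
  }
})

test_that("bundled grammars generate valid trees of their dialect", {
  set.seed(15)
  for (dialect in c("arithmetic", "fuzzy")) {
    g <- bundled_grammar(dialect)
    n_valid <- 0L
    for (i in 1:120) {
      genome <- sample(0:255, 100, replace = TRUE)
      tr <- map_genotype(genome, g, dialect = dialect)
      if (!is.null(tr)) {
        expect_true(validate_tree(tr))
        n_valid <- n_valid + 1L
      }
    }
    # invalid fraction stays below one half at default budgets
    expect_gt(n_valid / 120, 0.5)
  }
})

test_that("grammar parsing rejects malformed input", {
  expect_error(read_grammar(text = "<a> := x"), "malformed")
  expect_error(read_grammar(text = "<a> ::= <zzz>"), "undefined")
  expect_error(map_genotype(300L, bundled_grammar("arithmetic"),
                            dialect = NULL), "0..255")
})

test_that("GE evolution solves a separable problem deterministically", {
  toy <- separable_toy(seed = 12)
  g <- make_grammar(c("x1", "x2"), "arithmetic")
  cfg <- ge_config(population_size = 100, generations = 20, seed = 3)
  m1 <- evolve_ge(toy[c("x1", "x2")], toy$y, cfg, grammar = g)
  expect_equal(m1$fitness, 1.0)
  m2 <- evolve_ge(toy[c("x1", "x2")], toy$y, cfg, grammar = g)
  expect_identical(m1$expression, m2$expression)
  # the champion phenotype parses and scores within [0, 1]
  tr <- parse_expression(m1$expression, "arithmetic")
  s <- evaluate_tree(tr, toy[c("x1", "x2")])
  expect_true(all(s >= 0 & s <= 1))
  expect_lt(m1$invalid_fraction, 0.5)
})

test_that("GE in the fuzzy dialect yields pattern trees", {
  toy <- separable_toy(seed = 7)
  m <- evolve_ge(toy[c("x1", "x2")], toy$y,
                 ge_config(population_size = 60, generations = 8, seed = 2),
                 dialect = "fuzzy",
                 grammar = make_grammar(c("x1", "x2"), "fuzzy"))
  expect_false(grepl("add|sub|mul|div", m$expression))
  expect_true(all(predict(m, toy[c("x1", "x2")]) >= 0))
})
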