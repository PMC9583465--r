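# Grammatical evolution: integer-codon genomes decoded through a BNF
# grammar into the same expression dialects the tree-GP engine evolves.

#' Read a BNF grammar
#'
#' One rule per line, `<nonterminal> ::= production | production | ...`;
#' non-terminals are `<...>` tokens, everything else in a production is
#' literal text. The first rule's head is the start symbol. Two grammars
#' ship with the package (see [bundled_grammar()]): an arithmetic one over
#' the 16 crisp features and a fuzzy-pattern-tree one over the 48
#' membership features.
#'
#' @param path path to a BNF text file.
#' @param text alternatively, the grammar as a character vector of lines.
#' @return An object of class `ge_grammar`.
#' @export
read_grammar <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "::=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_oscml("malformed BNF rule (expected '<head> ::= ...'): ", ln)
    head_sym <- trimws(parts[1])
    if (!grepl("^<[^>]+>$", head_sym))
      stop_oscml("rule head must be a <nonterminal>: ", ln)
    prods <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
    rules[[head_sym]] <- lapply(trimws(prods), tokenize_production)
  }
  if (length(rules) == 0L) stop_oscml("empty grammar")
  heads <- names(rules)
  for (r in rules) for (p in r) for (tok in p)
    if (tok$type == "nt" && !(tok$value %in% heads))
      stop_oscml("undefined non-terminal ", tok$value)
  structure(list(rules = rules, start = heads[1]), class = "ge_grammar")
}

tokenize_production <- function(prod) {
  toks <- list()
  rest <- prod
  while (nzchar(rest)) {
    m <- regexpr("<[^>]+>", rest)
    if (m == -1L) {
      toks[[length(toks) + 1L]] <- list(type = "t", value = rest)
      break
    }
    if (m > 1L)
      toks[[length(toks) + 1L]] <-
        list(type = "t", value = substr(rest, 1L, m - 1L))
    toks[[length(toks) + 1L]] <-
      list(type = "nt",
           value = substr(rest, m, m + attr(m, "match.length") - 1L))
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  toks
}

#' @rdname read_grammar
#' @param dialect which bundled grammar to load.
#' @export
bundled_grammar <- function(dialect = c("arithmetic", "fuzzy")) {
  dialect <- match.arg(dialect)
  read_grammar(system.file("grammars", paste0(dialect, ".bnf"),
                           package = "oscml", mustWork = TRUE))
}

#' Build a grammar over a custom terminal set
#'
#' Same rule structure as the bundled grammars but with the `<feature>`
#' production list replaced by the given names; used when a classifier is
#' trained on a feature subset (e.g. after feature elimination).
#'
#' @param features terminal feature names.
#' @param dialect expression dialect.
#' @return A `ge_grammar`.
#' @export
make_grammar <- function(features, dialect = c("arithmetic", "fuzzy")) {
  dialect <- match.arg(dialect)
  feats <- paste(features, collapse = " | ")
  text <- if (dialect == "arithmetic") c(
    "<expr> ::= <binop>(<expr>, <expr>) | <term>",
    "<binop> ::= add | sub | mul | div",
    "<term> ::= <feature> | <const>",
    "<const> ::= 0.1 | 0.2 | 0.3 | 0.4 | 0.5 | 0.6 | 0.7 | 0.8 | 0.9",
    paste("<feature> ::=", feats)
  ) else c(
    "<fexpr> ::= <fop> | <feature>",
    paste("<fop> ::= max(<fexpr>, <fexpr>) | min(<fexpr>, <fexpr>)",
          "| WA(<fexpr>, <fexpr>, <w>) | OWA(<fexpr>, <fexpr>, <w>)",
          "| dilator(<fexpr>) | concentrator(<fexpr>)"),
    "<w> ::= 0.1 | 0.2 | 0.3 | 0.4 | 0.5 | 0.6 | 0.7 | 0.8 | 0.9",
    paste("<feature> ::=", feats)
  )
  read_grammar(text = text)
}

#' Map a genome to a phenotype expression
#'
#' Standard leftmost-derivation genotype-to-phenotype mapping: at every
#' non-terminal whose rule has two or more productions the next codon is
#' consumed and production `codon mod n` chosen; single-production rules
#' consume no codon. The codon stream wraps around at the end, at most
#' `wrap_limit` times; a derivation-depth cap bounds phenotype size before
#' the wrap budget is spent. If non-terminals remain when the budget runs
#' out the individual is *invalid*, which is a value (`NULL`), not an
#' error.
#'
#' @param genome integer vector of codons in 0..255.
#' @param grammar a `ge_grammar`.
#' @param wrap_limit maximum number of wraps through the genome.
#' @param depth_cap maximum derivation depth.
#' @param dialect dialect used to parse the derived string into an
#'   `expression_tree`; `NULL` returns the raw string instead.
#' @return An `expression_tree` (or derivation string), or `NULL` when the
#'   mapping is invalid.
#' @examples
#' g <- read_grammar(text = c("<e> ::= a | b"))
#' map_genotype(1L, g, dialect = NULL)
#' @export
map_genotype <- function(genome, grammar, wrap_limit = 3L, depth_cap = 12L,
                         dialect = c("arithmetic", "fuzzy")) {
  stopifnot(inherits(grammar, "ge_grammar"))
  genome <- as.integer(genome)
  if (length(genome) < 1L) stop_oscml("genome must hold at least one codon")
  if (any(genome < 0L | genome > 255L))
    stop_oscml("codons must lie in 0..255")
  budget <- length(genome) * (1L + as.integer(wrap_limit))
  used <- 0L
  invalid <- FALSE
  next_codon <- function() {
    if (used >= budget) { invalid <<- TRUE; return(0L) }
    codon <- genome[(used %% length(genome)) + 1L]
    used <<- used + 1L
    codon
  }
  expand <- function(symbol, depth) {
    if (invalid) return("")
    if (depth > depth_cap) { invalid <<- TRUE; return("") }
    prods <- grammar$rules[[symbol]]
    choice <- if (length(prods) >= 2L) {
      (next_codon() %% length(prods)) + 1L
    } else 1L
    if (invalid) return("")
    out <- ""
    for (tok in prods[[choice]]) {
      piece <- if (tok$type == "t") tok$value
               else expand(tok$value, depth + 1L)
      if (invalid) return("")
      out <- paste0(out, piece)
    }
    out
  }
  phenotype <- expand(grammar$start, 0L)
  if (invalid) return(NULL)
  if (is.null(dialect)) return(phenotype)
  parse_expression(phenotype, match.arg(dialect))
}

#' Evolution configuration for the GE engine
#'
#' @param population_size genomes per generation.
#' @param generations GA loop count.
#' @param genome_length codons per initial genome.
#' @param wrap_limit,depth_cap mapping budget (see [map_genotype()]).
#' @param tournament_size selection tournament size.
#' @param p_crossover probability of variable one-point crossover.
#' @param p_codon_mutation per-codon mutation probability.
#' @param seed integer seed.
#' @return List of class `ge_config`.
#' @export
ge_config <- function(population_size = 100L, generations = 20L,
                      genome_length = 100L, wrap_limit = 3L,
                      depth_cap = 12L, tournament_size = 2L,
                      p_crossover = 0.9, p_codon_mutation = 0.01,
                      seed = 7L) {
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 genome_length = as.integer(genome_length),
                 wrap_limit = as.integer(wrap_limit),
                 depth_cap = as.integer(depth_cap),
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover,
                 p_codon_mutation = p_codon_mutation,
                 seed = as.integer(seed)),
            class = "ge_config")
}

ge_crossover <- function(a, b) {
  i <- sample.int(length(a), 1L)
  j <- sample.int(length(b), 1L)
  list(c(a[seq_len(i)], b[-seq_len(j)])[],
       c(b[seq_len(j)], a[-seq_len(i)])[])
}

ge_mutate <- function(genome, p) {
  hit <- runif(length(genome)) < p
  if (any(hit)) genome[hit] <- sample(0:255, sum(hit), replace = TRUE)
  genome
}

#' Evolve an interpretable classifier by grammatical evolution
#'
#' Genetic algorithm over integer-codon genomes: tournament selection,
#' variable one-point crossover, per-codon mutation. Each genome is mapped
#' through the dialect's BNF grammar ([map_genotype()]); invalid phenotypes
#' receive the worst fitness. Fitness of a valid phenotype is the training
#' AUC of its scores (sigmoid-wrapped in the arithmetic dialect, direct in
#' the fuzzy dialect). The best-ever phenotype is returned with its
#' rendering; the run is a pure function of the seed.
#'
#' @inheritParams evolve_gp
#' @param config a [ge_config()].
#' @param grammar a `ge_grammar`; defaults to the bundled grammar of the
#'   dialect.
#' @return An `expression_model` with `engine = "GE"` and the champion
#'   `genome`; `invalid_fraction` records the share of invalid mappings in
#'   the initial population.
#' @export
evolve_ge <- function(data, labels, config = ge_config(),
                      dialect = c("arithmetic", "fuzzy"),
                      grammar = NULL) {
  dialect <- match.arg(dialect)
  data <- as.data.frame(data)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop_oscml("training labels contain a single class")
  grammar <- grammar %||% bundled_grammar(dialect)
  set.seed(derive_seed(config$seed, "evolve_ge"))

  fitness_of <- function(genome) {
    tree <- map_genotype(genome, grammar, config$wrap_limit,
                         config$depth_cap, dialect)
    if (is.null(tree)) return(list(fit = -1, tree = NULL))
    list(fit = auc_score(evaluate_tree(tree, data), y), tree = tree)
  }

  pop <- lapply(seq_len(config$population_size), function(i)
    sample(0:255, config$genome_length, replace = TRUE))
  evals <- lapply(pop, fitness_of)
  fit <- vapply(evals, `[[`, 0, "fit")
  invalid_fraction <- mean(fit < 0)
  best_i <- which.max(fit)
  champ <- list(genome = pop[[best_i]], tree = evals[[best_i]]$tree,
                fit = fit[best_i])

  for (gen in seq_len(config$generations)) {
    newpop <- vector("list", config$population_size)
    i <- 1L
    while (i <= config$population_size) {
      pa <- pop[[tournament_select(fit, config$tournament_size)]]
      pb <- pop[[tournament_select(fit, config$tournament_size)]]
      kids <- if (runif(1) < config$p_crossover) ge_crossover(pa, pb)
              else list(pa, pb)
      for (kid in kids) {
        if (i > config$population_size) break
        newpop[[i]] <- ge_mutate(kid, config$p_codon_mutation)
        i <- i + 1L
      }
    }
    pop <- newpop
    evals <- lapply(pop, fitness_of)
    fit <- vapply(evals, `[[`, 0, "fit")
    if (max(fit) > champ$fit) {
      best_i <- which.max(fit)
      champ <- list(genome = pop[[best_i]], tree = evals[[best_i]]$tree,
                    fit = fit[best_i])
    }
  }

  if (is.null(champ$tree))
    stop_oscml("no valid phenotype was found; check the grammar and budget")
  structure(list(tree = champ$tree, expression = render_tree(champ$tree),
                 dialect = dialect, fitness = champ$fit,
                 engine = "GE", genome = champ$genome,
                 invalid_fraction = invalid_fraction),
            class = "expression_model")
}
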