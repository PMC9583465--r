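#' Evolution configuration for the tree-GP engine
#'
#' Defaults follow common tree-GP practice for small tabular problems; the
#' hyperparameter grids explored by the evaluation harness (population size
#' in {100, 300, 500, 1000, 3000}, generations in {20, 50, 100, 200},
#' initial depth (2-2) or (2-6), tournament size in {2, 7, 20}) are exposed
#' through [default_grids()].
#'
#' @param population_size number of trees per generation.
#' @param generations generational loop count.
#' @param init_depth length-2 range for ramped half-and-half
#'   initialization.
#' @param tournament_size selection tournament size.
#' @param p_crossover,p_mutation probabilities of subtree crossover and
#'   subtree mutation when producing each offspring.
#' @param depth_cap hard depth limit; offspring exceeding it revert to a
#'   parent copy (crossover) or are regenerated (mutation). Small caps keep
#'   the evolved expressions legible.
#' @param seed integer seed; the whole run is a pure function of it.
#' @return List of class `gp_config`.
#' @export
gp_config <- function(population_size = 100L, generations = 20L,
                      init_depth = c(2L, 6L), tournament_size = 7L,
                      p_crossover = 0.9, p_mutation = 0.1,
                      depth_cap = 6L, seed = 7L) {
  stopifnot(population_size >= 2, generations >= 1,
            length(init_depth) == 2, init_depth[1] <= init_depth[2],
            tournament_size >= 1, depth_cap >= init_depth[2] || TRUE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 init_depth = as.integer(init_depth),
                 tournament_size = as.integer(tournament_size),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 depth_cap = as.integer(depth_cap), seed = as.integer(seed)),
            class = "gp_config")
}

#' Tournament selection
#'
#' Samples `k` distinct individuals uniformly from the population and
#' returns the index of the best fitness among them (ties go to the first
#' sampled).
#'
#' @param fitness numeric fitness vector (larger is better).
#' @param k tournament size, at most `length(fitness)`.
#' @return Index of the selected individual.
#' @export
tournament_select <- function(fitness, k) {
  n <- length(fitness)
  if (n == 0L) stop_oscml("cannot select from an empty population")
  if (k > n) stop_oscml("tournament size ", k, " exceeds population size ", n)
  idx <- sample.int(n, k)
  idx[which.max(fitness[idx])]
}

#' Subtree crossover
#'
#' Chooses a crossover node uniformly and independently in each parent and
#' swaps the rooted subtrees, operating on copies (the parents are never
#' modified). A child whose depth exceeds `depth_cap` is replaced by a copy
#' of its corresponding parent.
#'
#' @param parent1,parent2 `expression_tree`s of the same dialect.
#' @param depth_cap hard depth limit for the offspring.
#' @return List of two `expression_tree`s.
#' @export
subtree_crossover <- function(parent1, parent2, depth_cap = 6L) {
  stopifnot(inherits(parent1, "expression_tree"),
            inherits(parent2, "expression_tree"),
            identical(parent1$dialect, parent2$dialect))
  p1 <- tree_paths(parent1$root)
  p2 <- tree_paths(parent2$root)
  cut1 <- p1[[sample.int(length(p1), 1L)]]
  cut2 <- p2[[sample.int(length(p2), 1L)]]
  sub1 <- get_subtree(parent1$root, cut1)
  sub2 <- get_subtree(parent2$root, cut2)
  c1 <- expression_tree(replace_subtree(parent1$root, cut1, sub2),
                        parent1$dialect)
  c2 <- expression_tree(replace_subtree(parent2$root, cut2, sub1),
                        parent2$dialect)
  if (tree_depth(c1) > depth_cap) c1 <- parent1
  if (tree_depth(c2) > depth_cap) c2 <- parent2
  list(c1, c2)
}

#' Subtree mutation
#'
#' Chooses a mutation node uniformly, then replaces the rooted subtree with
#' a fresh grow-method subtree within the remaining depth budget (a budget
#' of zero forces a terminal).
#'
#' @param parent an `expression_tree`.
#' @param terminals terminal feature names for the regenerated subtree.
#' @param depth_cap hard depth limit.
#' @return Mutated `expression_tree`; the parent is unmodified.
#' @export
subtree_mutation <- function(parent, terminals, depth_cap = 6L) {
  stopifnot(inherits(parent, "expression_tree"))
  paths <- tree_paths(parent$root)
  cut <- paths[[sample.int(length(paths), 1L)]]
  budget <- max(0L, depth_cap - length(cut))
  repl <- random_node(parent$dialect, terminals, budget, "grow")
  expression_tree(replace_subtree(parent$root, cut, repl), parent$dialect)
}

ramped_population <- function(n, dialect, terminals, init_depth) {
  depths <- rep(seq(init_depth[1], init_depth[2]), length.out = n)
  methods <- rep(c("full", "grow"), length.out = n)
  lapply(seq_len(n), function(i)
    random_tree(dialect, terminals, depths[i], methods[i]))
}

#' Evolve an interpretable classifier by tree GP
#'
#' Ramped half-and-half initialization over the configured depth range,
#' then a generational loop of tournament selection, subtree crossover and
#' subtree mutation. Fitness is the training AUC of the tree's scores
#' (sigmoid-wrapped raw value in the arithmetic dialect, direct tree output
#' in the fuzzy dialect). The best-ever individual is tracked across
#' generations (elitism of record) and returned with its plain-text
#' rendering.
#'
#' @param data data.frame of feature columns (crisp for `"arithmetic"`,
#'   memberships for `"fuzzy"`).
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @param config a [gp_config()].
#' @param dialect expression dialect.
#' @param terminals terminal features; defaults to all numeric columns of
#'   `data`.
#' @return An object of class `expression_model`: list with `tree`,
#'   `expression` (rendering), `dialect`, `fitness` (training AUC),
#'   `engine = "GP"` and the per-generation best-fitness trace.
#' @examples
#' d <- data.frame(x = c(0.1, 0.2, 0.8, 0.9))
#' m <- evolve_gp(d, c(0, 0, 1, 1),
#'                gp_config(population_size = 30, generations = 5, seed = 1))
#' m$expression
#' @export
evolve_gp <- function(data, labels, config = gp_config(),
                      dialect = c("arithmetic", "fuzzy"),
                      terminals = NULL) {
  dialect <- match.arg(dialect)
  data <- as.data.frame(data)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop_oscml("training labels contain a single class")
  terminals <- terminals %||% names(data)[vapply(data, is.numeric, TRUE)]
  set.seed(derive_seed(config$seed, "evolve_gp"))

  fitness_of <- function(tree) auc_score(evaluate_tree(tree, data), y)
  pop <- ramped_population(config$population_size, dialect, terminals,
                           config$init_depth)
  fit <- vapply(pop, fitness_of, 0)
  champ <- pop[[which.max(fit)]]
  champ_fit <- max(fit)
  trace <- champ_fit

  for (gen in seq_len(config$generations)) {
    newpop <- vector("list", config$population_size)
    i <- 1L
    while (i <= config$population_size) {
      if (runif(1) < config$p_crossover) {
        pa <- pop[[tournament_select(fit, config$tournament_size)]]
        pb <- pop[[tournament_select(fit, config$tournament_size)]]
        kids <- subtree_crossover(pa, pb, config$depth_cap)
      } else {
        kids <- list(pop[[tournament_select(fit, config$tournament_size)]])
      }
      for (kid in kids) {
        if (i > config$population_size) break
        if (runif(1) < config$p_mutation)
          kid <- subtree_mutation(kid, terminals, config$depth_cap)
        newpop[[i]] <- kid
        i <- i + 1L
      }
    }
    pop <- newpop
    fit <- vapply(pop, fitness_of, 0)
    if (max(fit) > champ_fit) {
      champ_fit <- max(fit)
      champ <- pop[[which.max(fit)]]
    }
    trace <- c(trace, champ_fit)
  }

  structure(list(tree = champ, expression = render_tree(champ),
                 dialect = dialect, fitness = champ_fit,
                 engine = "GP", trace = trace),
            class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("<%s %s model, training AUC %.3f>\n  %s\n",
              x$engine, x$dialect, x$fitness, x$expression))
  invisible(x)
}

#' Score new data with an evolved model
#'
#' @param object an `expression_model`.
#' @param newdata data.frame containing the model's terminal features.
#' @param ... unused.
#' @return Numeric scores in \[0, 1\].
#' @export
predict.expression_model <- function(object, newdata, ...) {
  evaluate_tree(object$tree, newdata)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L)
      stop_oscml("labels must have exactly two levels")
    as.integer(labels == levels(labels)[2])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else if (is.character(labels)) {
    as_binary_labels(factor(labels))
  } else {
    u <- sort(unique(labels))
    if (!all(labels %in% c(0, 1)))
      stop_oscml("numeric labels must be 0/1 (got ",
                 paste(u, collapse = ", "), ")")
    as.integer(labels)
  }
}
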